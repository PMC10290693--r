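#' Classifier-filter configuration
#'
#' Controls the post-processing step in which each detection of a filtered
#' class is center-cropped and passed to an external image classifier; a
#' detection is removed when the classifier's probability for the class is
#' below the threshold (strictly `< 0.5` by default, so a probability of
#' exactly 0.5 is kept).
#'
#' @param crop_size side of the square crop fed to the classifier
#'   (default 256 px).
#' @param classifier_threshold removal cutoff on the class probability
#'   (default 0.5).
#' @param classes_filtered classes the filter applies to (default `"caa"`,
#'   the class the workflow filters; other classes pass through untouched).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(crop_size = 256, classifier_threshold = 0.5,
                          classes_filtered = "caa") {
  assert_that(classifier_threshold >= 0 && classifier_threshold <= 1,
              "classifier_threshold must be in [0, 1]")
  assert_that(crop_size > 0, "crop_size must be positive")
  structure(list(crop_size = as.integer(crop_size),
                 classifier_threshold = classifier_threshold,
                 classes_filtered = classes_filtered),
            class = "filter_config")
}

#' VOC-style TP/FP assignment of ranked detections
#'
#' Detections of the given class are ranked by descending confidence
#' (stable: ties keep input order) and assigned greedily: a detection is a
#' true positive when it attains IOU at least `iou_threshold` with a
#' not-yet-claimed label of the same image, claiming the highest-IOU such
#' label; otherwise it is a false positive. Among multiple detections of
#' one label, the highest-confidence detection is thus the TP and the rest
#' are FPs.
#'
#' @param detections a detection box data frame (confidences required).
#' @param labels a label box data frame.
#' @param class_label class under evaluation.
#' @param iou_threshold minimum IOU for a true positive (default 0.50).
#' @return A data frame in ranked order with columns `index` (row in
#'   `detections`), `image_id`, `confidence`, `iou` (IOU with the claimed
#'   label, 0 for FPs) and logical `tp`.
#' @export
assign_detections <- function(detections, labels, class_label = "cored",
                              iou_threshold = 0.5) {
  detections <- validate_box_set(detections, "detections")
  labels <- validate_box_set(labels, "labels")
  di <- which(detections$class_label == class_label)
  assert_that(all(!is.na(detections$confidence[di])),
              "detections must carry confidences")
  li <- which(labels$class_label == class_label)
  ord <- di[order(-detections$confidence[di])]  # order() is stable
  lab <- labels[li, , drop = FALSE]
  claimed <- logical(length(li))
  res <- data.frame(index = ord,
                    image_id = detections$image_id[ord],
                    confidence = detections$confidence[ord],
                    iou = rep(0, length(ord)), tp = rep(FALSE, length(ord)))
  for (k in seq_along(ord)) {
    d <- detections[ord[k], , drop = FALSE]
    open <- which(!claimed & lab$image_id == d$image_id)
    if (length(open) == 0L) next
    ious <- iou_matrix(d, lab[open, , drop = FALSE])[1, ]
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      claimed[open[best]] <- TRUE
      res$tp[k] <- TRUE
      res$iou[k] <- ious[best]
    }
  }
  res
}

#' PASCAL-VOC average precision from ranked TP/FP flags
#'
#' Accumulates precision-recall along the confidence ranking and integrates
#' the all-points interpolated curve (the precision envelope: precision at
#' each recall is replaced by the maximum precision at any equal-or-higher
#' recall). The 11-point interpolation used by early VOC protocols is
#' available behind `eleven_point`.
#'
#' @param flags logical vector of TP (`TRUE`) / FP (`FALSE`) flags in
#'   descending-confidence order, e.g. the `tp` column of
#'   [assign_detections()].
#' @param n_labels number of ground-truth labels of the class. With zero
#'   labels the AP is undefined and `NA` is returned (a detector evaluated
#'   against nothing has no precision-recall curve).
#' @param eleven_point use the 11-point recall grid instead of the
#'   all-points envelope.
#' @return AP in `[0, 1]`, or `NA_real_` when undefined.
#' @examples
#' average_precision(c(TRUE, FALSE, TRUE), n_labels = 2)  # 0.8333
#' @export
average_precision <- function(flags, n_labels, eleven_point = FALSE) {
  if (n_labels == 0L) return(NA_real_)
  assert_that(n_labels >= 1, "n_labels must be >= 0")
  if (length(flags) == 0L) return(0)
  tp <- cumsum(flags)
  recall <- tp / n_labels
  precision <- tp / seq_along(flags)
  if (eleven_point) {
    grid <- seq(0, 1, by = 0.1)
    p_at <- vapply(grid, function(r) {
      ok <- recall >= r
      if (any(ok)) max(precision[ok]) else 0
    }, numeric(1))
    return(mean(p_at))
  }
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' AP across classes and IOU thresholds
#'
#' @inheritParams assign_detections
#' @param thresholds IOU thresholds to evaluate (default the 0.5-0.9 grid).
#' @param classes classes to evaluate (default both pathology classes).
#' @param eleven_point passed to [average_precision()].
#' @return A data frame with columns `class_label`, `iou_threshold`, `ap`
#'   (NA where undefined) and `n_labels`.
#' @export
ap_over_thresholds <- function(detections, labels,
                               thresholds = seq(0.5, 0.9, by = 0.1),
                               classes = pathology_classes(),
                               eleven_point = FALSE) {
  assert_that(all(thresholds > 0 & thresholds <= 1),
              "IOU thresholds must lie in (0, 1]")
  rows <- list()
  for (cls in classes) {
    n_lab <- sum(labels$class_label == cls)
    for (thr in thresholds) {
      flags <- assign_detections(detections, labels, cls, thr)$tp
      rows[[length(rows) + 1L]] <- data.frame(
        class_label = cls, iou_threshold = thr,
        ap = average_precision(flags, n_lab, eleven_point),
        n_labels = n_lab)
    }
  }
  do.call(rbind, rows)
}

#' Cross-expert precision band
#'
#' Estimates the ceiling performance attainable against human variability:
#' each annotator in turn is fixed as ground truth and every other
#' annotator's labels are scored against it as if they were predictions.
#' Annotator boxes carry no confidences, so each ordered comparison yields
#' a single-point precision, congruous matches divided by the number of
#' predicted boxes. With 4 annotators this gives 12 ordered comparisons.
#'
#' @param annotators named list of annotation box data frames.
#' @inheritParams match_congruous
#' @return A list with `mean`, `sd` and `precisions`, a data frame of the
#'   ordered comparisons (`truth`, `predictor`, `precision`). Comparisons
#'   whose predictor has no boxes of the class are excluded with a warning.
#' @export
cross_expert_precision <- function(annotators, class_label = "cored",
                                   iou_threshold = 0.5) {
  assert_that(length(annotators) >= 2L, "need at least 2 annotators")
  nm <- annotator_names(annotators)
  rows <- list()
  for (i in seq_along(annotators)) {
    for (j in seq_along(annotators)) {
      if (i == j) next
      truth <- annotators[[i]]
      pred <- annotators[[j]]
      n_pred <- sum(pred$class_label == class_label)
      if (n_pred == 0L) {
        warning(sprintf(
          "annotator %s has no '%s' boxes; comparison vs %s undefined, excluded",
          nm[j], class_label, nm[i]), call. = FALSE)
        next
      }
      matches <- 0L
      imgs <- union(unique(truth$image_id), unique(pred$image_id))
      for (img in imgs) {
        m <- match_congruous(truth[truth$image_id == img, , drop = FALSE],
                             pred[pred$image_id == img, , drop = FALSE],
                             class_label, iou_threshold)
        matches <- matches + nrow(m$pairs)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        truth = nm[i], predictor = nm[j], precision = matches / n_pred)
    }
  }
  prec <- do.call(rbind, rows)
  list(mean = mean(prec$precision), sd = stats::sd(prec$precision),
       precisions = prec)
}

#' Classifier-based detection filtering
#'
#' Post-processes merged detections: each detection of a filtered class is
#' center-cropped from its image and handed to the classifier; the
#' detection is removed when the returned class probability falls below
#' the threshold. Other classes pass through untouched. Callers apply
#' [merge_boxes()] first, matching the workflow's merge-then-filter order.
#' A classifier failure keeps the detection (fail-open) with a warning, so
#' infrastructure faults never silently drop detections.
#'
#' @param detections a merged detection box data frame.
#' @param image the RGB image array the detections refer to, a named list
#'   of such arrays keyed by `image_id`, or `NULL` when the classifier
#'   does not need pixels (crops are then `NULL`).
#' @param classifier a function `(crop, box) -> named probabilities`, one
#'   entry per class; see [oracle_classifier()] for the synthetic stand-in.
#' @param config a [filter_config()].
#' @param image_w,image_h image dimensions used for crop geometry when
#'   `image` is `NULL` (default 1536, the workflow's field size).
#' @return The surviving subset of `detections`.
#' @export
filter_detections <- function(detections, image = NULL, classifier,
                              config = filter_config(),
                              image_w = 1536, image_h = 1536) {
  stopifnot(inherits(config, "filter_config"))
  detections <- validate_box_set(detections, "detections")
  if (nrow(detections) == 0L) return(detections)
  keep <- rep(TRUE, nrow(detections))
  for (k in which(detections$class_label %in% config$classes_filtered)) {
    box <- detections[k, , drop = FALSE]
    img <- resolve_image(image, box$image_id)
    if (is.null(img)) {
      w <- image_w; h <- image_h
      crop <- NULL
      win <- center_crop_window(box, config$crop_size, w, h)
    } else {
      h <- dim(img)[1]; w <- dim(img)[2]
      win <- center_crop_window(box, config$crop_size, w, h)
      crop <- img[(win["ymin"] + 1):win["ymax"],
                  (win["xmin"] + 1):win["xmax"], , drop = FALSE]
    }
    prob <- tryCatch(classifier(crop, box), error = function(e) {
      warning(sprintf("classifier failed on detection %d (%s); kept: %s",
                      k, box$class_label, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(prob)) next
    p <- as.numeric(prob[[box$class_label]])
    if (!is.na(p) && p < config$classifier_threshold) keep[k] <- FALSE
  }
  detections[keep, , drop = FALSE]
}

resolve_image <- function(image, image_id) {
  if (is.null(image)) return(NULL)
  if (is.list(image) && !is.array(image)) return(image[[image_id]])
  image
}

#' Bootstrap refinement of sparse training labels
#'
#' Implements the label-bootstrapping step that grows a sparse label set
#' from detector output: detections are merged per class, optionally
#' classifier-filtered, stripped of confidences, pooled with the existing
#' labels, and the combined set is merged per class again. The result
#' geometrically covers every input label.
#'
#' @param detections detector output on the training images.
#' @param labels the existing (sparse) training labels.
#' @param classifier optional classifier for [filter_detections()]; `NULL`
#'   skips the filtering step.
#' @param config a [filter_config()].
#' @inheritParams filter_detections
#' @return A refined label box data frame (no confidences).
#' @export
refine_labels <- function(detections, labels, classifier = NULL,
                          config = filter_config(), image = NULL,
                          image_w = 1536, image_h = 1536) {
  labels <- validate_box_set(labels, "labels")
  merged <- merge_boxes(detections)
  if (!is.null(classifier)) {
    merged <- filter_detections(merged, image, classifier, config,
                                image_w, image_h)
  }
  merged$confidence <- rep(NA_real_, nrow(merged))
  keep <- intersect(names(labels), names(merged))
  combined <- rbind(labels[keep], merged[keep])
  out <- merge_boxes(combined)
  out$confidence <- rep(NA_real_, nrow(out))
  rownames(out) <- NULL
  out
}
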