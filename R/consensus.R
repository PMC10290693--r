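#' Consensus configuration
#'
#' @param support_required minimum number of distinct annotators that must
#'   independently box an object for it to enter the consensus (default 2,
#'   the consensus-of-two rule).
#' @param iou_threshold minimum IOU for two same-class boxes to count as
#'   the same object (default 0.50).
#' @param n_annotators expected number of annotators (the study design used
#'   4); checked against the data when supplied.
#' @return An object of class `consensus_config`.
#' @export
consensus_config <- function(support_required = 2, iou_threshold = 0.5,
                             n_annotators = NULL) {
  assert_that(support_required >= 1, "support_required must be >= 1")
  assert_that(iou_threshold > 0 && iou_threshold <= 1,
              "iou_threshold must be in (0, 1]")
  if (!is.null(n_annotators)) {
    assert_that(support_required <= n_annotators,
                "support_required (%d) exceeds n_annotators (%d)",
                support_required, n_annotators)
  }
  structure(list(support_required = as.integer(support_required),
                 iou_threshold = iou_threshold,
                 n_annotators = n_annotators),
            class = "consensus_config")
}

#' Congruous-pair matching between two annotation sets
#'
#' Two label boxes form a congruous pair when they share a class label and
#' their IOU is at least the threshold. Each box may belong to at most one
#' pair. Matching is greedy in descending IOU, with ties broken by the
#' lexicographically smallest (row of `a`, row of `b`) pair, making the
#' result deterministic.
#'
#' @param a,b box data frames for the same image.
#' @param class_label class to match (`"cored"` or `"caa"`).
#' @param iou_threshold minimum IOU for a congruous pair (default 0.50).
#' @return A list with `pairs` (data frame `index_a`, `index_b`, `iou`,
#'   rows indexing into `a` and `b`) and `unmatched_a`, `unmatched_b`
#'   (integer row indices).
#' @export
match_congruous <- function(a, b, class_label = "cored", iou_threshold = 0.5) {
  a <- validate_box_set(a, "a"); b <- validate_box_set(b, "b")
  ia <- which(a$class_label == class_label)
  ib <- which(b$class_label == class_label)
  pairs <- greedy_pairs(a[ia, , drop = FALSE], b[ib, , drop = FALSE],
                        iou_threshold)
  pairs$index_a <- ia[pairs$index_a]
  pairs$index_b <- ib[pairs$index_b]
  list(pairs = pairs,
       unmatched_a = setdiff(ia, pairs$index_a),
       unmatched_b = setdiff(ib, pairs$index_b))
}

# Greedy one-to-one matching on local (row) indices; descending IOU,
# lexicographic (i, j) tie-break.
greedy_pairs <- function(a, b, iou_threshold) {
  empty <- data.frame(index_a = integer(0), index_b = integer(0),
                      iou = numeric(0))
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  m <- iou_matrix(a, b)
  cand <- which(m >= iou_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  ious <- m[cand]
  ord <- order(-ious, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  ious <- ious[ord]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE
      used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  data.frame(index_a = as.integer(cand[keep, 1]),
             index_b = as.integer(cand[keep, 2]),
             iou = ious[keep])
}

#' Interrater agreement accuracy between two annotators
#'
#' Over the superset of all class-`class_label` objects either annotator
#' identified, agreement is the number of congruous pairs ("overlaps")
#' divided by the cardinality of the union ("total" = |A| + |B| - overlaps,
#' each congruous pair counted once). Boxes are matched within each image
#' separately. Two empty annotation sets agree perfectly (1.0).
#'
#' @inheritParams match_congruous
#' @return Agreement accuracy in `[0, 1]`.
#' @examples
#' a <- box_set(c(0, 100), c(0, 100), c(40, 140), c(40, 140))
#' interrater_accuracy(a, a)  # 1
#' @export
interrater_accuracy <- function(a, b, class_label = "cored",
                                iou_threshold = 0.5) {
  a <- validate_box_set(a, "a"); b <- validate_box_set(b, "b")
  a <- a[a$class_label == class_label, , drop = FALSE]
  b <- b[b$class_label == class_label, , drop = FALSE]
  if (nrow(a) == 0L && nrow(b) == 0L) return(1)
  overlaps <- 0L
  for (img in union(unique(a$image_id), unique(b$image_id))) {
    m <- match_congruous(a[a$image_id == img, , drop = FALSE],
                         b[b$image_id == img, , drop = FALSE],
                         class_label, iou_threshold)
    overlaps <- overlaps + nrow(m$pairs)
  }
  total <- nrow(a) + nrow(b) - overlaps
  overlaps / total
}

#' Pairwise interrater agreement matrix
#'
#' @param annotators a named list of box data frames, one per annotator,
#'   all referring to the same image set.
#' @inheritParams match_congruous
#' @return A symmetric numeric matrix with unit diagonal, annotator names
#'   on both dimensions.
#' @export
agreement_matrix <- function(annotators, class_label = "cored",
                             iou_threshold = 0.5) {
  assert_that(length(annotators) >= 2L, "need at least 2 annotators")
  nm <- annotator_names(annotators)
  n <- length(annotators)
  m <- diag(1, n)
  dimnames(m) <- list(nm, nm)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      acc <- interrater_accuracy(annotators[[i]], annotators[[j]],
                                 class_label, iou_threshold)
      m[i, j] <- acc
      m[j, i] <- acc
    }
  }
  m
}

annotator_names <- function(annotators) {
  nm <- names(annotators)
  if (is.null(nm) || any(nm == "")) nm <- paste0("NP", seq_along(annotators))
  nm
}

#' Consensus-of-k annotation
#'
#' Builds the consensus annotation set: boxes of each class are clustered
#' across annotators by greedy congruous matching (annotators visited in
#' their declared order, each new annotator's boxes matched against the
#' running mean box of existing clusters), and every cluster supported by
#' at least `support_required` distinct annotators emits one consensus box,
#' the coordinate-wise mean of its members rounded to integers.
#'
#' @param annotators a named list of box data frames on a shared image set.
#' @param config a [consensus_config()].
#' @return A box data frame with extra columns `support_count` and
#'   `supporting_annotators` (comma-separated).
#' @export
consensus_boxes <- function(annotators, config = consensus_config()) {
  stopifnot(inherits(config, "consensus_config"))
  assert_that(length(annotators) >= config$support_required,
              "support_required (%d) exceeds the %d annotators supplied",
              config$support_required, length(annotators))
  if (!is.null(config$n_annotators)) {
    assert_that(length(annotators) == config$n_annotators,
                "expected %d annotators, got %d", config$n_annotators,
                length(annotators))
  }
  nm <- annotator_names(annotators)
  annotators <- lapply(annotators, validate_box_set)
  images <- unique(unlist(lapply(annotators, function(x) x$image_id)))
  out <- list()
  for (img in images) {
    per_img <- lapply(annotators, function(x) x[x$image_id == img, , drop = FALSE])
    for (cls in pathology_classes()) {
      clusters <- cluster_across_annotators(per_img, nm, cls,
                                            config$iou_threshold)
      for (cl in clusters) {
        supporters <- unique(cl$annotator)
        if (length(supporters) < config$support_required) next
        row <- box_set(
          xmin = round(mean(cl$xmin)), ymin = round(mean(cl$ymin)),
          xmax = round(mean(cl$xmax)), ymax = round(mean(cl$ymax)),
          class_label = cls, image_id = img
        )
        row$support_count <- length(supporters)
        row$supporting_annotators <- paste(supporters, collapse = ",")
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (length(out) == 0L) {
    res <- empty_box_set()
    res$support_count <- integer(0)
    res$supporting_annotators <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Cluster one image's boxes of one class across annotators. Returns a list
# of data frames, each the member boxes of one cluster with an `annotator`
# column. Matching pivots on the running mean box of each cluster.
cluster_across_annotators <- function(per_img, nm, cls, iou_threshold) {
  clusters <- list()
  mean_box <- function(cl) {
    box_set(mean(cl$xmin), mean(cl$ymin), mean(cl$xmax), mean(cl$ymax),
            class_label = cls)
  }
  for (k in seq_along(per_img)) {
    boxes <- per_img[[k]]
    boxes <- boxes[boxes$class_label == cls, , drop = FALSE]
    if (nrow(boxes) == 0L) next
    boxes$annotator <- nm[k]
    boxes <- boxes[c("image_id", "class_label", "xmin", "ymin", "xmax",
                     "ymax", "confidence", "annotator")]
    if (length(clusters) == 0L) {
      clusters <- lapply(seq_len(nrow(boxes)),
                         function(i) boxes[i, , drop = FALSE])
      next
    }
    reps <- do.call(rbind, lapply(clusters, mean_box))
    pairs <- greedy_pairs(reps, boxes, iou_threshold)
    for (p in seq_len(nrow(pairs))) {
      ci <- pairs$index_a[p]
      clusters[[ci]] <- rbind(clusters[[ci]],
                              boxes[pairs$index_b[p], , drop = FALSE])
    }
    for (j in setdiff(seq_len(nrow(boxes)), pairs$index_b)) {
      clusters[[length(clusters) + 1L]] <- boxes[j, , drop = FALSE]
    }
  }
  clusters
}
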