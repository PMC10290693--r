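#' CERAD-like category levels, in severity order
#' @return Character vector `none < sparse < moderate < frequent`.
#' @export
cerad_categories <- function() c("none", "sparse", "moderate", "frequent")

#' CERAD-like cohort records
#'
#' One record per whole-slide image: the semi-quantitative CERAD-like
#' plaque-burden category assigned by an expert and the model-derived
#' cored-plaque count for the same slide.
#'
#' @param wsi_id slide identifiers.
#' @param category CERAD-like categories, from [cerad_categories()].
#' @param model_count non-negative integer plaque counts.
#' @return A data frame with `category` as an ordered factor.
#' @export
cerad_records <- function(wsi_id, category, model_count) {
  assert_that(all(category %in% cerad_categories()),
              "categories must be one of: %s",
              paste(cerad_categories(), collapse = ", "))
  assert_that(all(model_count >= 0), "model_count must be non-negative")
  data.frame(
    wsi_id = as.character(wsi_id),
    category = factor(category, levels = cerad_categories(), ordered = TRUE),
    model_count = as.integer(model_count)
  )
}

# Canonical name for one tile image in a tile list.
tile_key <- function(row, col) sprintf("tile_r%d_c%d", row, col)

#' Score a whole-slide image by tile-wise detection
#'
#' Runs the detector over every tile of the grid, translates the per-tile
#' detections into WSI coordinates, merges overlapping same-class boxes
#' across the whole slide (so a pathology detected in two adjacent tiles
#' counts once, provided its part-boxes overlap in WSI coordinates),
#' optionally applies the classifier filter to CAA detections, and counts
#' boxes per class.
#'
#' @param tiles a named list of RGB tile arrays keyed `tile_r<row>_c<col>`
#'   (see [tile_grid()] rows), or `NULL` when the detector does not read
#'   pixels (e.g. [oracle_detector()]). A missing tile image is an error
#'   naming the tile.
#' @param grid a [tile_grid()].
#' @param detector a function `(image, stain, tile) -> detection box data
#'   frame` in tile-local coordinates, confidences in `[0, 1]`.
#' @param stain a [stain_profile()] or stain name, passed to the detector.
#' @param classifier optional classifier for [filter_detections()].
#' @param filter_cfg a [filter_config()], used when `classifier` is given.
#' @param wsi_id identifier stamped on the returned boxes.
#' @return A list with `counts` (named vector over classes) and
#'   `detections` (merged, filtered boxes in WSI coordinates).
#' @export
score_wsi <- function(tiles, grid, detector, stain = "4G8",
                      classifier = NULL, filter_cfg = filter_config(),
                      wsi_id = "wsi") {
  stopifnot(inherits(grid, "tile_grid"))
  all_det <- list()
  for (k in seq_len(nrow(grid$tiles))) {
    tile <- grid$tiles[k, ]
    key <- tile_key(tile$row, tile$col)
    img <- NULL
    if (!is.null(tiles)) {
      img <- tiles[[key]]
      assert_that(!is.null(img), "missing tile image '%s' (row %d, col %d)",
                  key, tile$row, tile$col)
    }
    det <- detector(img, stain, tile)
    det <- validate_box_set(det, sprintf("detections on %s", key))
    if (nrow(det) == 0L) next
    det <- to_wsi_coords(det, tile)
    det$image_id <- wsi_id
    all_det[[length(all_det) + 1L]] <- det
  }
  detections <- if (length(all_det) > 0L) {
    merge_boxes(do.call(rbind, all_det))
  } else {
    empty_box_set()
  }
  if (!is.null(classifier) && nrow(detections) > 0L) {
    detections <- filter_detections(detections, image = NULL,
                                    classifier = classifier,
                                    config = filter_cfg,
                                    image_w = grid$wsi_width,
                                    image_h = grid$wsi_height)
  }
  counts <- vapply(pathology_classes(),
                   function(cls) sum(detections$class_label == cls),
                   integer(1))
  rownames(detections) <- NULL
  list(counts = counts, detections = detections)
}

#' Two-sided pooled-variance t-test on plaque counts
#'
#' Classical Student t-test (equal variances pooled) as used to compare
#' model-derived count distributions between CERAD-like categories; Welch's
#' correction is available behind a flag. Two constant equal samples are
#' maximally compatible with the null and return `t = 0`, `p = 1`.
#'
#' @param x,y numeric count vectors, each of length at least 2.
#' @param welch use the Welch (unequal-variance) statistic instead.
#' @return A list with `t`, `p` (two-sided), and `df`.
#' @examples
#' two_sample_ttest(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0214
#' @export
two_sample_ttest <- function(x, y, welch = FALSE) {
  assert_that(length(x) >= 2 && length(y) >= 2,
              "each sample needs at least 2 observations")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    assert_that(mean(x) == mean(y),
                "both samples are constant with different means: t undefined")
    return(list(t = 0, p = 1, df = length(x) + length(y) - 2))
  }
  fit <- stats::t.test(x, y, var.equal = !welch, alternative = "two.sided")
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

# Post-hoc power of the two-sided pooled t-test at the observed effect
# size: noncentral-t tail mass outside the critical values.
posthoc_power <- function(x, y, alpha) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (sp2 <= 0) return(NA_real_)
  d <- abs(mean(x) - mean(y)) / sqrt(sp2)
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Pairwise CERAD-like category comparison
#'
#' Runs the two-sided pooled t-test between the model-derived count
#' distributions of every unordered pair of CERAD-like categories, flags
#' significance at `alpha`, and reports the post-hoc power of each pair
#' computed from the observed pooled effect size. Categories with fewer
#' than 2 slides are skipped with a warning.
#'
#' @param records a [cerad_records()] data frame.
#' @param alpha significance threshold (default 0.05).
#' @param welch passed to [two_sample_ttest()].
#' @return A list with `pairs` (data frame: `category_a`, `category_b`,
#'   `n_a`, `n_b`, `t`, `p`, `power`, `significant`) and `p_matrix`, a
#'   symmetric matrix of p-values over the categories present.
#' @export
cerad_comparison <- function(records, alpha = 0.05, welch = FALSE) {
  assert_that(is.data.frame(records) &&
                all(c("category", "model_count") %in% names(records)),
              "records must have columns category and model_count")
  present <- cerad_categories()[cerad_categories() %in% records$category]
  counts <- lapply(present, function(cc)
    records$model_count[records$category == cc])
  names(counts) <- present
  usable <- vapply(counts, length, integer(1)) >= 2L
  for (cc in present[!usable]) {
    warning(sprintf("category '%s' has fewer than 2 slides; pairs skipped", cc),
            call. = FALSE)
  }
  cats <- present[usable]
  assert_that(length(cats) >= 2L,
              "need at least 2 categories with >= 2 slides each")
  p_matrix <- matrix(NA_real_, length(cats), length(cats),
                     dimnames = list(cats, cats))
  diag(p_matrix) <- 1
  rows <- list()
  for (i in seq_len(length(cats) - 1L)) {
    for (j in seq((i + 1L), length(cats))) {
      x <- counts[[cats[i]]]; y <- counts[[cats[j]]]
      tt <- two_sample_ttest(x, y, welch = welch)
      pw <- posthoc_power(x, y, alpha)
      p_matrix[i, j] <- tt$p
      p_matrix[j, i] <- tt$p
      rows[[length(rows) + 1L]] <- data.frame(
        category_a = cats[i], category_b = cats[j],
        n_a = length(x), n_b = length(y),
        t = tt$t, p = tt$p, power = pw,
        significant = tt$p < alpha)
    }
  }
  list(pairs = do.call(rbind, rows), p_matrix = p_matrix, alpha = alpha)
}
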