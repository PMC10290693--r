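#' Scene specification for synthetic IHC tiles
#'
#' Describes one synthetic immunohistochemistry field: DAB-brown cored
#' plaques are rendered as filled discs with a darker center, CAA as
#' annular (vessel-like) rings, on a near-white tissue background. Object
#' colors are drawn strictly inside the stain's HSV gates and the
#' background strictly outside them (its value channel sits above every
#' built-in gate's V ceiling), so the HSV mask of a rendered tile is exact.
#'
#' @param tile_size tile side in pixels (default 1536, the workflow's
#'   field-of-view size; tests typically use smaller scenes).
#' @param stain stain name or [stain_profile()] whose gates the object
#'   colors must satisfy.
#' @param n_cored,n_caa number of objects of each class.
#' @param radius_range object radius range in pixels (outer radius for
#'   CAA rings).
#' @param min_separation minimum gap in pixels between object boundary
#'   circles (default 12; keeps distinct objects from merging).
#' @param seed integer seed; the same spec renders bit-identically.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(tile_size = 1536, stain = "4G8", n_cored = 3,
                       n_caa = 2, radius_range = c(12, 24),
                       min_separation = 12, seed = 1) {
  assert_that(tile_size >= 4 * max(radius_range),
              "tile_size too small for the requested radius range")
  assert_that(n_cored >= 0 && n_caa >= 0, "object counts must be >= 0")
  assert_that(radius_range[1] > 0 && radius_range[1] <= radius_range[2],
              "radius_range must be c(lo, hi) with 0 < lo <= hi")
  structure(list(tile_size = as.integer(tile_size),
                 stain = as_stain_profile(stain),
                 n_cored = as.integer(n_cored), n_caa = as.integer(n_caa),
                 radius_range = radius_range,
                 min_separation = min_separation, seed = seed),
            class = "scene_spec")
}

# Vectorized HSV (OpenCV 8-bit scale) -> RGB in [0, 1].
hsv8_to_rgb <- function(h, s, v) {
  hh <- (h * 2) / 60  # degrees / 60
  ss <- s / 255
  vv <- v / 255
  c_ <- vv * ss
  x <- c_ * (1 - abs(hh %% 2 - 1))
  m <- vv - c_
  sector <- floor(hh) %% 6
  r <- ifelse(sector == 0 | sector == 5, c_,
              ifelse(sector == 1 | sector == 4, x, 0))
  g <- ifelse(sector == 0 | sector == 3, x,
              ifelse(sector == 1 | sector == 2, c_, 0))
  b <- ifelse(sector == 2 | sector == 5, x,
              ifelse(sector == 3 | sector == 4, c_, 0))
  cbind(r + m, g + m, b + m)
}

# In-gate DAB-brown HSV ranges with safety margins against 8-bit rounding;
# valid for every built-in stain profile.
dab_hue <- c(5, 35)
dab_sat <- c(60, 200)
dab_val <- c(110, 200)
dab_core_val <- c(70, 100)

# Sample non-overlapping circle centers by rejection; gap between boundary
# circles must reach min_sep. Errors after bounded retries.
place_circles <- function(n, radii, lo, hi, min_sep, max_tries = 300L) {
  cx <- numeric(0); cy <- numeric(0); r <- numeric(0)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      x <- stats::runif(1, lo + radii[k], hi - radii[k])
      y <- stats::runif(1, lo + radii[k], hi - radii[k])
      if (length(cx) == 0L ||
          all(sqrt((cx - x)^2 + (cy - y)^2) >= r + radii[k] + min_sep)) {
        cx <- c(cx, x); cy <- c(cy, y); r <- c(r, radii[k])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("infeasible packing: could not place object ", k,
           " after ", max_tries, " tries", call. = FALSE)
    }
  }
  data.frame(cx = cx, cy = cy, r = r)
}

#' Render a synthetic IHC tile with ground truth
#'
#' @param spec a [scene_spec()].
#' @param image_id identifier stamped on the truth boxes.
#' @return A list with `image` (RGB array `[tile, tile, 3]` in `[0, 1]`)
#'   and `truth` (label box data frame; tight bounds of the painted
#'   pixels). Deterministic under the spec's seed.
#' @export
render_tile <- function(spec, image_id = "tile") {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, {
    ts <- spec$tile_size
    n <- spec$n_cored + spec$n_caa
    # near-white background: all channels in [251, 255]/255 keeps V >= 251,
    # above every built-in gate's V ceiling
    img <- array(stats::runif(ts * ts * 3, 251 / 255, 1), dim = c(ts, ts, 3))
    truth <- empty_box_set()
    if (n > 0L) {
      radii <- stats::runif(n, spec$radius_range[1], spec$radius_range[2])
      circ <- place_circles(n, radii, 0, ts, spec$min_separation)
      circ$class_label <- rep(c("cored", "caa"),
                              c(spec$n_cored, spec$n_caa))
      rows <- vector("list", n)
      for (k in seq_len(n)) {
        painted <- paint_object(img, circ[k, ])
        img <- painted$image
        rows[[k]] <- box_set(painted$xmin, painted$ymin, painted$xmax,
                             painted$ymax, class_label = circ$class_label[k],
                             image_id = image_id)
      }
      truth <- do.call(rbind, rows)
      rownames(truth) <- NULL
    }
    list(image = img, truth = truth)
  })
}

# Paint one disc (cored) or annulus (caa) into the image; returns the
# updated image and the tight 0-based half-open bounds of painted pixels.
paint_object <- function(img, obj) {
  ts <- dim(img)[1]
  x0 <- max(1, floor(obj$cx - obj$r)); x1 <- min(ts, ceiling(obj$cx + obj$r))
  y0 <- max(1, floor(obj$cy - obj$r)); y1 <- min(ts, ceiling(obj$cy + obj$r))
  xs <- x0:x1; ys <- y0:y1
  # pixel (row y, col x) 1-based; its 0-based center is (x-1, y-1)
  dx2 <- outer(rep(1, length(ys)), ((xs - 1) - obj$cx)^2)
  dy2 <- outer(((ys - 1) - obj$cy)^2, rep(1, length(xs)))
  d2 <- dx2 + dy2
  sel <- if (obj$class_label == "cored") {
    d2 <= obj$r^2
  } else {
    d2 <= obj$r^2 & d2 > (0.55 * obj$r)^2
  }
  idx <- which(sel, arr.ind = TRUE)
  n_px <- nrow(idx)
  h <- stats::runif(n_px, dab_hue[1], dab_hue[2])
  s <- stats::runif(n_px, dab_sat[1], dab_sat[2])
  v <- stats::runif(n_px, dab_val[1], dab_val[2])
  if (obj$class_label == "cored") {
    core <- d2[sel] <= (0.5 * obj$r)^2
    v[core] <- stats::runif(sum(core), dab_core_val[1], dab_core_val[2])
  }
  rgb <- hsv8_to_rgb(h, s, v)
  ry <- ys[idx[, 1]]; rx <- xs[idx[, 2]]
  for (ch in 1:3) img[cbind(ry, rx, ch)] <- rgb[, ch]
  list(image = img,
       xmin = min(rx) - 1, ymin = min(ry) - 1, xmax = max(rx), ymax = max(ry))
}

#' Annotator noise model
#'
#' @param jitter Gaussian standard deviation (pixels) added independently
#'   to each box corner coordinate.
#' @param drop_prob probability a true object goes unannotated.
#' @param fp_rate expected number of spurious (false-positive) boxes per
#'   image (Poisson).
#' @param seed integer seed.
#' @return An object of class `annotator_noise`.
#' @export
annotator_noise <- function(jitter = 2, drop_prob = 0, fp_rate = 0, seed = 1) {
  assert_that(jitter >= 0, "jitter must be >= 0")
  assert_that(drop_prob >= 0 && drop_prob <= 1, "drop_prob must be in [0, 1]")
  assert_that(fp_rate >= 0, "fp_rate must be >= 0")
  structure(list(jitter = jitter, drop_prob = drop_prob, fp_rate = fp_rate,
                 seed = seed),
            class = "annotator_noise")
}

# Jitter box corners, clip to the image, keep validity.
jitter_boxes <- function(boxes, jitter, image_w, image_h) {
  n <- nrow(boxes)
  if (n == 0L || jitter == 0) return(boxes)
  boxes$xmin <- boxes$xmin + round(stats::rnorm(n, 0, jitter))
  boxes$ymin <- boxes$ymin + round(stats::rnorm(n, 0, jitter))
  boxes$xmax <- boxes$xmax + round(stats::rnorm(n, 0, jitter))
  boxes$ymax <- boxes$ymax + round(stats::rnorm(n, 0, jitter))
  boxes$xmin <- pmin(pmax(boxes$xmin, 0), image_w - 1)
  boxes$ymin <- pmin(pmax(boxes$ymin, 0), image_h - 1)
  boxes$xmax <- pmin(pmax(boxes$xmax, boxes$xmin + 1), image_w)
  boxes$ymax <- pmin(pmax(boxes$ymax, boxes$ymin + 1), image_h)
  boxes
}

random_background_boxes <- function(n, image_w, image_h, image_id,
                                    classes = pathology_classes()) {
  if (n == 0L) return(empty_box_set())
  w <- stats::runif(n, 20, 60)
  h <- stats::runif(n, 20, 60)
  x0 <- stats::runif(n, 0, image_w - w)
  y0 <- stats::runif(n, 0, image_h - h)
  box_set(round(x0), round(y0), round(x0 + w), round(y0 + h),
          class_label = sample(classes, n, replace = TRUE),
          image_id = image_id)
}

#' Simulate one expert annotator
#'
#' Each ground-truth box is independently dropped with `drop_prob`, else
#' corner-jittered; Poisson-many false-positive boxes are added at random
#' background positions. With zero noise the output equals the truth.
#'
#' @param truth ground-truth label box data frame.
#' @param noise an [annotator_noise()].
#' @param image_w,image_h image bounds for clipping and false-positive
#'   placement.
#' @return An annotation box data frame (no confidences).
#' @export
simulate_annotator <- function(truth, noise, image_w = 1536, image_h = 1536) {
  stopifnot(inherits(noise, "annotator_noise"))
  truth <- validate_box_set(truth, "truth")
  with_local_seed(noise$seed, {
    keep <- stats::runif(nrow(truth)) >= noise$drop_prob
    out <- jitter_boxes(truth[keep, , drop = FALSE], noise$jitter,
                        image_w, image_h)
    img_id <- if (nrow(truth) > 0L) truth$image_id[1] else "image"
    fps <- random_background_boxes(stats::rpois(1, noise$fp_rate),
                                   image_w, image_h, img_id)
    out <- rbind(out[names(fps)], fps)
    out$confidence <- rep(NA_real_, nrow(out))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a confidence-scored detector
#'
#' Stands in for the trained object-detection network: each truth box is
#' missed with `miss_rate`, else emitted with corner jitter and a
#' confidence drawn from the true-positive range; false positives are
#' added at background positions with confidences from the (lower)
#' false-positive range. With zero noise the detector is an oracle and
#' every downstream evaluation yields AP 1.
#'
#' @param truth ground-truth label box data frame.
#' @param miss_rate probability a true object is missed.
#' @param fp_rate expected false positives per image (Poisson).
#' @param jitter corner jitter standard deviation in pixels.
#' @param confidence_model list with elements `tp` and `fp`, each a
#'   `c(lo, hi)` uniform range for confidences.
#' @param seed integer seed.
#' @param image_w,image_h image bounds.
#' @return A detection box data frame.
#' @export
simulate_detector <- function(truth, miss_rate = 0, fp_rate = 0, jitter = 0,
                              confidence_model = list(tp = c(0.7, 1),
                                                      fp = c(0.05, 0.5)),
                              seed = 1, image_w = 1536, image_h = 1536) {
  truth <- validate_box_set(truth, "truth")
  assert_that(miss_rate >= 0 && miss_rate <= 1, "miss_rate must be in [0, 1]")
  with_local_seed(seed, {
    keep <- stats::runif(nrow(truth)) >= miss_rate
    out <- jitter_boxes(truth[keep, , drop = FALSE], jitter,
                        image_w, image_h)
    out$confidence <- stats::runif(nrow(out), confidence_model$tp[1],
                                   confidence_model$tp[2])
    img_id <- if (nrow(truth) > 0L) truth$image_id[1] else "image"
    fps <- random_background_boxes(stats::rpois(1, fp_rate),
                                   image_w, image_h, img_id)
    fps$confidence <- stats::runif(nrow(fps), confidence_model$fp[1],
                                   confidence_model$fp[2])
    out <- rbind(out[names(fps)], fps)
    rownames(out) <- NULL
    out
  })
}

#' Oracle classifier built from ground truth
#'
#' Stands in for the external consensus-of-two CNN in
#' [filter_detections()]: the returned classifier gives probability 1 for
#' a class when the crop's source box overlaps a truth box of that class
#' at IOU at least `iou_threshold`, else 0. It reads only box geometry,
#' never pixels.
#'
#' @param truth ground-truth label box data frame (in the coordinate frame
#'   the classifier will be queried in).
#' @param iou_threshold overlap required to count as a true object.
#' @return A function `(crop, box) -> c(cored = p, caa = p)`.
#' @export
oracle_classifier <- function(truth, iou_threshold = 0.5) {
  truth <- validate_box_set(truth, "truth")
  function(crop, box) {
    vapply(pathology_classes(), function(cls) {
      t_cls <- truth[truth$class_label == cls, , drop = FALSE]
      if (nrow(t_cls) == 0L) return(0)
      as.numeric(max(iou_matrix(box, t_cls)) >= iou_threshold)
    }, numeric(1))
  }
}

#' Oracle detector over a whole-slide truth set
#'
#' Returns a [score_wsi()]-compatible detector that emits, for each tile,
#' exactly the truth boxes whose centers fall inside that tile, translated
#' to tile-local coordinates with unit confidence. It reads no pixels.
#'
#' @param truth_wsi ground-truth box data frame in WSI coordinates.
#' @param grid the [tile_grid()] of the WSI.
#' @return A detector function `(image, stain, tile) -> detections`.
#' @export
oracle_detector <- function(truth_wsi, grid) {
  truth_wsi <- validate_box_set(truth_wsi, "truth_wsi")
  ts <- grid$tile_size
  function(image, stain, tile) {
    cx <- (truth_wsi$xmin + truth_wsi$xmax) / 2
    cy <- (truth_wsi$ymin + truth_wsi$ymax) / 2
    sel <- cx >= tile$x_offset & cx < tile$x_offset + ts &
      cy >= tile$y_offset & cy < tile$y_offset + ts
    det <- truth_wsi[sel, , drop = FALSE]
    det$xmin <- det$xmin - tile$x_offset; det$xmax <- det$xmax - tile$x_offset
    det$ymin <- det$ymin - tile$y_offset; det$ymax <- det$ymax - tile$y_offset
    det$confidence <- rep(1, nrow(det))
    det
  }
}

#' Generate a synthetic CERAD-like cohort
#'
#' Emulates a graded whole-slide cohort: for each CERAD-like category, `n`
#' WSIs are generated, each with a Poisson-distributed number of cored
#' plaques (mean given per category) placed geometrically across the
#' slide's tiles (fully inside a tile, mutually separated). Objects are
#' geometric truth boxes; pair the cohort with [oracle_detector()] to
#' exercise [score_wsi()] and [cerad_comparison()] without rendering
#' pixels.
#'
#' @param category_means named numeric vector of Poisson means, names from
#'   [cerad_categories()].
#' @param n_per_category WSIs per category.
#' @param tiles_per_wsi `c(rows, cols)` of the tile grid per WSI.
#' @param tile_size tile side in pixels.
#' @param radius_range plaque radius range in pixels.
#' @param seed integer seed.
#' @return A list with `wsis` (list of entries `wsi_id`, `category`,
#'   `planted_count`, `truth`, `grid`) and `records`, the matching
#'   [cerad_records()] data frame built from the planted counts.
#' @export
generate_cerad_cohort <- function(category_means = c(none = 1, sparse = 8,
                                                     moderate = 25,
                                                     frequent = 60),
                                  n_per_category = 15,
                                  tiles_per_wsi = c(2, 3), tile_size = 1536,
                                  radius_range = c(12, 24), seed = 1) {
  assert_that(all(names(category_means) %in% cerad_categories()),
              "category_means names must be CERAD-like categories")
  assert_that(all(category_means >= 0), "means must be non-negative")
  with_local_seed(seed, {
    wsis <- list()
    for (cat in names(category_means)) {
      for (i in seq_len(n_per_category)) {
        wsi_id <- sprintf("%s_%02d", cat, i)
        grid <- tile_grid(tiles_per_wsi[2] * tile_size,
                          tiles_per_wsi[1] * tile_size, tile_size)
        count <- stats::rpois(1, category_means[[cat]])
        truth <- place_wsi_objects(count, grid, radius_range, wsi_id)
        wsis[[wsi_id]] <- list(wsi_id = wsi_id, category = cat,
                               planted_count = count, truth = truth,
                               grid = grid)
      }
    }
    records <- cerad_records(
      vapply(wsis, `[[`, character(1), "wsi_id"),
      vapply(wsis, `[[`, character(1), "category"),
      vapply(wsis, `[[`, numeric(1), "planted_count"))
    list(wsis = wsis, records = records)
  })
}

# Place `count` cored-plaque truth boxes across a grid; each object lies
# fully inside one tile, separated from others in the same tile.
place_wsi_objects <- function(count, grid, radius_range, wsi_id) {
  if (count == 0L || nrow(grid$tiles) == 0L) return(empty_box_set())
  ts <- grid$tile_size
  per_tile <- vector("list", nrow(grid$tiles))
  rows <- vector("list", count)
  for (k in seq_len(count)) {
    placed <- FALSE
    for (t in seq_len(300L)) {
      ti <- sample.int(nrow(grid$tiles), 1)
      r <- stats::runif(1, radius_range[1], radius_range[2])
      x <- stats::runif(1, r + 2, ts - r - 2)
      y <- stats::runif(1, r + 2, ts - r - 2)
      prev <- per_tile[[ti]]
      # Chebyshev separation: truth boxes are squares, so the box gap is
      # governed by the larger coordinate offset, not Euclidean distance
      if (is.null(prev) ||
          all(pmax(abs(prev$x - x), abs(prev$y - y)) >= prev$r + r + 8)) {
        per_tile[[ti]] <- rbind(prev, data.frame(x = x, y = y, r = r))
        tile <- grid$tiles[ti, ]
        rows[[k]] <- box_set(
          round(tile$x_offset + x - r), round(tile$y_offset + y - r),
          round(tile$x_offset + x + r), round(tile$y_offset + y + r),
          class_label = "cored", image_id = wsi_id)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible packing of WSI objects", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
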