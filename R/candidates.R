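#' Parameters of classical candidate detection
#'
#' @param smoothing_kernel side length of the Gaussian smoothing kernel in
#'   pixels; must be odd (default 5).
#' @param min_area minimum candidate segment area in pixels squared
#'   (default 100).
#' @param min_distance watershed marker separation in pixels: local maxima
#'   of the distance transform closer than this are treated as one marker
#'   (default 10).
#' @return An object of class `candidate_params`.
#' @export
candidate_params <- function(smoothing_kernel = 5, min_area = 100,
                             min_distance = 10) {
  assert_that(smoothing_kernel > 0 && smoothing_kernel %% 2 == 1,
              "smoothing_kernel must be a positive odd integer")
  assert_that(min_area > 0 && min_distance > 0,
              "min_area and min_distance must be positive")
  structure(list(smoothing_kernel = as.integer(smoothing_kernel),
                 min_area = as.numeric(min_area),
                 min_distance = as.numeric(min_distance)),
            class = "candidate_params")
}

#' Convert an RGB tile to 8-bit OpenCV-scale HSV
#'
#' @param image numeric array `[height, width, 3]` with values in `[0, 1]`
#'   (the convention of [png::readPNG()]).
#' @return Integer array `[height, width, 3]` with H in `[0, 179]`, S and V
#'   in `[0, 255]`.
#' @export
rgb_to_hsv8 <- function(image) {
  check_rgb(image)
  d <- dim(image)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(image[, , 1]), g = as.vector(image[, , 2]),
    b = as.vector(image[, , 3]), maxColorValue = 1
  )
  out <- array(0L, dim = d)
  out[, , 1] <- as.integer(round(hsv["h", ] * 180)) %% 180L
  out[, , 2] <- as.integer(round(hsv["s", ] * 255))
  out[, , 3] <- as.integer(round(hsv["v", ] * 255))
  out
}

check_rgb <- function(image) {
  assert_that(is.array(image) && length(dim(image)) == 3L && dim(image)[3] >= 3L,
              "expected an RGB image array [height, width, 3]; grayscale input is not supported")
  assert_that(all(dim(image)[1:2] > 0), "empty image")
  invisible(image)
}

#' Binary stain mask by HSV gating
#'
#' A pixel is foreground iff each of its H, S and V values lies inside the
#' stain's inclusive gate intervals. Widening any interval can only add
#' pixels to the mask.
#'
#' @param image RGB array `[height, width, 3]` in `[0, 1]`.
#' @param stain a [stain_profile()] or stain name.
#' @return Logical matrix `[height, width]`.
#' @export
hsv_mask <- function(image, stain) {
  stain <- as_stain_profile(stain)
  hsv <- rgb_to_hsv8(image)
  d <- dim(hsv)
  h <- matrix(hsv[, , 1], d[1], d[2])
  s <- matrix(hsv[, , 2], d[1], d[2])
  v <- matrix(hsv[, , 3], d[1], d[2])
  (h >= stain$h_range[1] & h <= stain$h_range[2]) &
    (s >= stain$s_range[1] & s <= stain$s_range[2]) &
    (v >= stain$v_range[1] & v <= stain$v_range[2])
}

# Gaussian-smooth a binary mask and re-threshold at 0.5. Keeps the 0.5
# level set close to the original boundary while removing speckle.
smooth_mask <- function(mask, kernel = 5) {
  if (kernel <= 1) return(mask)
  brush <- EBImage::makeBrush(kernel, shape = "gaussian", sigma = kernel / 5)
  sm <- EBImage::filter2(EBImage::Image(t(mask) * 1), brush)
  t(EBImage::imageData(sm)) > 0.5
}

#' Watershed-based candidate pathology detection
#'
#' The classical front end of the workflow: gate the tile by the stain's
#' HSV intervals, smooth the mask, split touching foreground components by
#' the watershed transform of the Euclidean distance map, and return the
#' tight bounding box of every segment at least `min_area` pixels large.
#' Candidate boxes carry no confidence and default to class `"cored"`;
#' class assignment proper is the job of a downstream classifier.
#'
#' @param image RGB array `[height, width, 3]` in `[0, 1]`.
#' @param stain a [stain_profile()] or stain name.
#' @param params a [candidate_params()] object.
#' @param class_label class assigned to the candidate boxes (plumbing
#'   default `"cored"`).
#' @param image_id identifier stored with the boxes.
#' @return A box data frame (possibly empty).
#' @export
detect_candidates <- function(image, stain, params = candidate_params(),
                              class_label = "cored", image_id = "image") {
  stopifnot(inherits(params, "candidate_params"))
  mask <- hsv_mask(image, stain)
  mask <- smooth_mask(mask, params$smoothing_kernel)
  if (!any(mask)) return(empty_box_set())
  dist <- EBImage::distmap(EBImage::Image(t(mask) * 1))
  labels <- EBImage::watershed(dist, tolerance = 1, ext = params$min_distance)
  lab <- t(EBImage::imageData(labels))  # back to [row = y, col = x]
  boxes <- lapply(seq_len(max(lab)), function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < params$min_area) return(NULL)
    box_set(xmin = min(px[, 2]) - 1, ymin = min(px[, 1]) - 1,
            xmax = max(px[, 2]), ymax = max(px[, 1]),
            class_label = class_label, image_id = image_id)
  })
  boxes <- boxes[!vapply(boxes, is.null, logical(1))]
  if (length(boxes) == 0L) return(empty_box_set())
  out <- do.call(rbind, boxes)
  rownames(out) <- NULL
  out
}

#' Reinhard-style color normalization
#'
#' Maps the per-channel mean and standard deviation of the image toward a
#' reference tile in the perceptual CIE Lab space, the standard recipe for
#' harmonising stain appearance across slides and scanners. The method is a
#' hook: detection itself operates on raw HSV gates, but cross-site slides
#' are typically normalized first.
#'
#' @param image,reference RGB arrays `[height, width, 3]` in `[0, 1]`.
#' @return Normalized RGB array, clamped to `[0, 1]`, same size as `image`.
#' @export
normalize_color <- function(image, reference) {
  check_rgb(image); check_rgb(reference)
  to_lab <- function(img) {
    px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
    grDevices::convertColor(px, from = "sRGB", to = "Lab")
  }
  lab <- to_lab(image)
  ref <- to_lab(reference)
  for (ch in 1:3) {
    mu <- mean(lab[, ch]); s <- stats::sd(lab[, ch])
    mu_r <- mean(ref[, ch]); s_r <- stats::sd(ref[, ch])
    ratio <- if (s > 1e-8) s_r / s else 0
    lab[, ch] <- (lab[, ch] - mu) * ratio + mu_r
  }
  rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  rgb <- pmin(pmax(rgb, 0), 1)
  out <- image
  for (ch in 1:3) out[, , ch] <- array(rgb[, ch], dim = dim(image)[1:2])
  out
}
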