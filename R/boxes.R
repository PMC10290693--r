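#' Bounding-box collections
#'
#' Annotations and detections are kept in plain data frames with one row per
#' axis-aligned box. Coordinates are 0-based and half-open: pixel column
#' `x` is covered iff `xmin <= x < xmax`, so `area = (xmax - xmin) * (ymax -
#' ymin)`. `confidence` is `NA` for human labels and a value in `[0, 1]` for
#' detector output; the presence of confidences is what distinguishes a
#' detection set from an annotation set.
#'
#' @param xmin,ymin,xmax,ymax box coordinates in pixels (0-based, half-open).
#' @param class_label pathology class, `"cored"` or `"caa"` (recycled).
#' @param confidence detection confidence in `[0, 1]`, or `NA` for labels.
#' @param image_id identifier of the image the boxes belong to (recycled).
#' @param annotator optional annotator identifier (recycled).
#' @return A data frame with columns `image_id`, `class_label`, `xmin`,
#'   `ymin`, `xmax`, `ymax`, `confidence` (and `annotator` if supplied).
#' @examples
#' box_set(0, 0, 10, 10)
#' box_set(c(0, 5), c(0, 5), c(10, 15), c(10, 15), class_label = "caa",
#'         confidence = c(0.9, 0.4))
#' @export
box_set <- function(xmin, ymin, xmax, ymax, class_label = "cored",
                    confidence = NA_real_, image_id = "image",
                    annotator = NULL) {
  n <- length(xmin)
  out <- data.frame(
    image_id = rep_len(as.character(image_id), n),
    class_label = rep_len(as.character(class_label), n),
    xmin = as.numeric(xmin), ymin = as.numeric(ymin),
    xmax = as.numeric(xmax), ymax = as.numeric(ymax),
    confidence = rep_len(as.numeric(confidence), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(annotator)) out$annotator <- rep_len(as.character(annotator), n)
  validate_box_set(out)
}

#' An empty box collection
#'
#' @param detections if `TRUE` the (empty) `confidence` column is understood
#'   to carry detector confidences.
#' @return A zero-row box data frame.
#' @export
empty_box_set <- function(detections = FALSE) {
  box_set(numeric(0), numeric(0), numeric(0), numeric(0))
}

pathology_classes <- function() c("cored", "caa")

#' Validate a box data frame
#'
#' Checks the column contract and the geometric invariants (`xmin < xmax`,
#' `ymin < ymax`, confidence in `[0, 1]` where present).
#'
#' @param boxes a box data frame (see [box_set()]).
#' @param where label used in error messages.
#' @return The input, invisibly unchanged, or an error naming the first
#'   offending row.
#' @export
validate_box_set <- function(boxes, where = "box set") {
  needed <- c("class_label", "xmin", "ymin", "xmax", "ymax")
  assert_that(is.data.frame(boxes), "%s must be a data frame", where)
  missing_cols <- setdiff(needed, names(boxes))
  assert_that(length(missing_cols) == 0L, "%s lacks column(s): %s",
              where, paste(missing_cols, collapse = ", "))
  if (is.null(boxes$image_id)) boxes$image_id <- "image"
  if (is.null(boxes$confidence)) boxes$confidence <- NA_real_
  if (nrow(boxes) == 0L) return(boxes)
  bad_class <- which(!boxes$class_label %in% pathology_classes())
  assert_that(length(bad_class) == 0L,
              "%s row %d: unknown class_label '%s'", where, bad_class[1],
              boxes$class_label[bad_class[1]])
  coords <- c("xmin", "ymin", "xmax", "ymax")
  bad_num <- which(!stats::complete.cases(boxes[coords]))
  assert_that(length(bad_num) == 0L, "%s row %d: non-numeric or missing coordinate",
              where, bad_num[1])
  bad_geom <- which(boxes$xmin >= boxes$xmax | boxes$ymin >= boxes$ymax)
  assert_that(length(bad_geom) == 0L,
              "%s row %d: degenerate box (requires xmin < xmax and ymin < ymax)",
              where, bad_geom[1])
  conf <- boxes$confidence
  bad_conf <- which(!is.na(conf) & (conf < 0 | conf > 1))
  assert_that(length(bad_conf) == 0L,
              "%s row %d: confidence outside [0, 1]", where, bad_conf[1])
  boxes
}

is_detection_set <- function(boxes) {
  nrow(boxes) > 0L && any(!is.na(boxes$confidence))
}

box_area <- function(boxes) (boxes$xmax - boxes$xmin) * (boxes$ymax - boxes$ymin)

#' Intersection-over-union of two boxes
#'
#' Areas are taken on the half-open pixel lattice, so for integer coordinates
#' the result equals counting covered pixels. Class labels are ignored.
#'
#' @param a,b single boxes: either one-row box data frames or numeric
#'   vectors `c(xmin, ymin, xmax, ymax)`.
#' @return IOU in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 5, 15, 15))  # 25/175
#' @export
iou <- function(a, b) {
  a <- as_coords(a); b <- as_coords(b)
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  if (inter <= 0) return(0)
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / un
}

as_coords <- function(b) {
  if (is.data.frame(b)) {
    assert_that(nrow(b) == 1L, "expected a single box, got %d rows", nrow(b))
    return(as.numeric(b[1, c("xmin", "ymin", "xmax", "ymax")]))
  }
  assert_that(is.numeric(b) && length(b) == 4L,
              "a box must be c(xmin, ymin, xmax, ymax)")
  assert_that(b[1] < b[3] && b[2] < b[4], "degenerate box")
  as.numeric(b)
}

# All-pairs IOU between the rows of two box data frames (class-blind).
iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(0, na, nb))
  iw <- pmin(rep(a$xmax, nb), rep(b$xmax, each = na)) -
    pmax(rep(a$xmin, nb), rep(b$xmin, each = na))
  ih <- pmin(rep(a$ymax, nb), rep(b$ymax, each = na)) -
    pmax(rep(a$ymin, nb), rep(b$ymin, each = na))
  inter <- pmax(iw, 0) * pmax(ih, 0)
  un <- rep(box_area(a), nb) + rep(box_area(b), each = na) - inter
  matrix(ifelse(inter > 0, inter / un, 0), na, nb)
}

#' Minimal superset of two same-class boxes
#'
#' The union box spans `(min(xmin), min(ymin))` to `(max(xmax), max(ymax))`.
#' When either input carries a confidence, the result keeps the larger one,
#' preserving the strongest evidence for confidence-ranked evaluation.
#'
#' @param a,b one-row box data frames of the same class.
#' @return A one-row box data frame.
#' @export
union_box <- function(a, b) {
  assert_that(is.data.frame(a) && is.data.frame(b) &&
                nrow(a) == 1L && nrow(b) == 1L, "union_box expects single boxes")
  assert_that(a$class_label == b$class_label,
              "cannot union boxes of different classes (%s vs %s)",
              a$class_label, b$class_label)
  out <- a
  out$xmin <- min(a$xmin, b$xmin); out$ymin <- min(a$ymin, b$ymin)
  out$xmax <- max(a$xmax, b$xmax); out$ymax <- max(a$ymax, b$ymax)
  conf <- c(a$confidence, b$confidence)
  out$confidence <- if (all(is.na(conf))) NA_real_ else max(conf, na.rm = TRUE)
  out
}

#' Iterative same-class box merging
#'
#' Implements the label-consolidation rule used both when preparing training
#' labels and when post-processing detector output: whenever two boxes of the
#' same class overlap (strictly positive intersection area; edge-touching
#' boxes do not count), they are replaced by their minimal superset. Merging
#' can create new overlaps, so the rule is applied to closure: each output
#' box is the minimal superset of one connected component of the overlap
#' graph, recomputed until a fixed point. Classes never merge with each
#' other, and the result is independent of input order.
#'
#' @param boxes a box data frame; classes may be mixed.
#' @return A box data frame in which no two same-class boxes overlap. Merged
#'   detections keep the maximum confidence of their members.
#' @examples
#' chain <- box_set(c(0, 8, 18), c(0, 0, 0), c(10, 20, 30), c(10, 10, 10))
#' merge_boxes(chain)  # single box (0, 0, 30, 10)
#' @export
merge_boxes <- function(boxes) {
  boxes <- validate_box_set(boxes)
  if (nrow(boxes) <= 1L) return(boxes)
  pieces <- lapply(split(boxes, boxes$class_label), merge_one_class)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

merge_one_class <- function(boxes) {
  repeat {
    n <- nrow(boxes)
    if (n <= 1L) return(boxes)
    m <- iou_matrix(boxes, boxes) > 0
    comp <- connected_components(m)
    if (all(tabulate(comp) <= 1L)) return(boxes)
    merged <- lapply(split(seq_len(n), comp), function(idx) {
      sub <- boxes[idx, , drop = FALSE]
      out <- sub[1, , drop = FALSE]
      out$xmin <- min(sub$xmin); out$ymin <- min(sub$ymin)
      out$xmax <- max(sub$xmax); out$ymax <- max(sub$ymax)
      out$confidence <- if (all(is.na(sub$confidence))) NA_real_ else
        max(sub$confidence, na.rm = TRUE)
      out
    })
    boxes <- do.call(rbind, merged)
  }
}

# Connected components of a symmetric logical adjacency matrix (BFS).
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    k <- k + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Square crop window centred on a box
#'
#' Returns the `crop` x `crop` window centred on the box centre, translated
#' (never shrunk or padded) so it lies fully inside the image. Used to cut
#' fixed-size classifier inputs around detections.
#'
#' @param box a single box (one-row data frame or coordinate vector).
#' @param crop window side length in pixels (default 256).
#' @param image_w,image_h image dimensions in pixels.
#' @return Named numeric `c(xmin, ymin, xmax, ymax)` of the window.
#' @examples
#' center_crop_window(c(100, 100, 120, 130), 256, 1536, 1536)
#' @export
center_crop_window <- function(box, crop = 256, image_w, image_h) {
  b <- as_coords(box)
  assert_that(crop <= image_w && crop <= image_h,
              "crop size %d exceeds image dimensions %dx%d: tile unusable",
              crop, image_w, image_h)
  cx <- (b[1] + b[3]) / 2
  cy <- (b[2] + b[4]) / 2
  x0 <- min(max(floor(cx - crop / 2), 0), image_w - crop)
  y0 <- min(max(floor(cy - crop / 2), 0), image_h - crop)
  c(xmin = x0, ymin = y0, xmax = x0 + crop, ymax = y0 + crop)
}
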