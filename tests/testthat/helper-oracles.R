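# Independent brute-force oracles used to verify the implementation.
# Deliberately naive: pixel counting, repeated full rescans, explicit
# loops. They share no code path with the package.

# IOU by counting covered pixels on the half-open integer lattice.
px_iou <- function(a, b) {
  cover <- function(v) {
    px <- expand.grid(x = seq(v[1], v[3] - 1), y = seq(v[2], v[4] - 1))
    paste(px$x, px$y)
  }
  pa <- cover(a); pb <- cover(b)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

overlap_area <- function(a, b) {
  iw <- min(a$xmax, b$xmax) - max(a$xmin, b$xmin)
  ih <- min(a$ymax, b$ymax) - max(a$ymin, b$ymin)
  max(iw, 0) * max(ih, 0)
}

# Merge closure by repeated rescan: find the first overlapping same-class
# pair, replace it by its hull, start over.
naive_merge <- function(boxes) {
  repeat {
    n <- nrow(boxes)
    hit <- NULL
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          if (boxes$class_label[i] == boxes$class_label[j] &&
              overlap_area(boxes[i, ], boxes[j, ]) > 0) {
            hit <- c(i, j); break
          }
        }
        if (!is.null(hit)) break
      }
    }
    if (is.null(hit)) return(boxes)
    a <- boxes[hit[1], ]; b <- boxes[hit[2], ]
    a$xmin <- min(a$xmin, b$xmin); a$ymin <- min(a$ymin, b$ymin)
    a$xmax <- max(a$xmax, b$xmax); a$ymax <- max(a$ymax, b$ymax)
    conf <- c(a$confidence, b$confidence)
    a$confidence <- if (all(is.na(conf))) NA_real_ else max(conf, na.rm = TRUE)
    boxes <- rbind(a, boxes[-hit, ])
  }
}

# Canonical geometric signature of a box set for order-free comparison.
box_signature <- function(boxes) {
  s <- sprintf("%s|%g|%g|%g|%g", boxes$class_label, boxes$xmin, boxes$ymin,
               boxes$xmax, boxes$ymax)
  sort(s)
}

# Greedy congruous matching by repeatedly scanning for the maximum-IOU
# eligible pair (no sorting; lexicographic tie-break by explicit scan).
naive_match <- function(a, b, cls, thr) {
  ia <- which(a$class_label == cls); ib <- which(b$class_label == cls)
  pairs <- NULL
  used_a <- c(); used_b <- c()
  repeat {
    best <- NULL; best_iou <- -1
    for (i in ia) {
      if (i %in% used_a) next
      for (j in ib) {
        if (j %in% used_b) next
        v <- px_free_iou(a[i, ], b[j, ])
        if (v >= thr && v > best_iou + 1e-12) {
          best <- c(i, j); best_iou <- v
        }
      }
    }
    if (is.null(best)) break
    pairs <- rbind(pairs, data.frame(index_a = best[1], index_b = best[2],
                                     iou = best_iou))
    used_a <- c(used_a, best[1]); used_b <- c(used_b, best[2])
  }
  pairs
}

# Continuous IOU written independently (no pixel grid; for non-integer
# random boxes in the matching/AP oracles).
px_free_iou <- function(a, b) {
  inter <- overlap_area(a, b)
  if (inter <= 0) return(0)
  ua <- (a$xmax - a$xmin) * (a$ymax - a$ymin)
  ub <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
  inter / (ua + ub - inter)
}

# VOC TP/FP assignment re-implemented with nested loops.
naive_assign <- function(det, lab, cls, thr) {
  di <- which(det$class_label == cls)
  di <- di[order(-det$confidence[di])]
  li <- which(lab$class_label == cls)
  claimed <- rep(FALSE, length(li))
  flags <- logical(length(di))
  for (k in seq_along(di)) {
    d <- det[di[k], ]
    best <- 0; best_iou <- 0
    for (m in seq_along(li)) {
      if (claimed[m]) next
      l <- lab[li[m], ]
      if (l$image_id != d$image_id) next
      v <- px_free_iou(d, l)
      if (v > best_iou) { best <- m; best_iou <- v }
    }
    if (best > 0 && best_iou >= thr) {
      claimed[best] <- TRUE
      flags[k] <- TRUE
    }
  }
  flags
}

# All-points interpolated AP by explicit envelope scan: at each ranked
# position, precision is replaced by the best precision at any deeper
# position, then integrated over recall increments.
naive_ap <- function(flags, n_labels) {
  if (n_labels == 0) return(NA_real_)
  if (length(flags) == 0) return(0)
  tp <- 0; fp <- 0
  recall <- numeric(length(flags)); prec <- numeric(length(flags))
  for (i in seq_along(flags)) {
    if (flags[i]) tp <- tp + 1 else fp <- fp + 1
    recall[i] <- tp / n_labels
    prec[i] <- tp / (tp + fp)
  }
  ap <- 0; prev_r <- 0
  for (i in seq_along(flags)) {
    env <- max(prec[i:length(flags)])
    ap <- ap + (recall[i] - prev_r) * env
    prev_r <- recall[i]
  }
  ap
}

# Pooled two-sample t-test from the textbook closed form.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Random integer box sets for the property tests.
random_boxes <- function(n, max_coord = 40, max_side = 15,
                         classes = c("cored", "caa"), confidence = FALSE) {
  if (n == 0) return(empty_box_set())
  x0 <- sample.int(max_coord, n, replace = TRUE) - 1
  y0 <- sample.int(max_coord, n, replace = TRUE) - 1
  w <- sample.int(max_side, n, replace = TRUE)
  h <- sample.int(max_side, n, replace = TRUE)
  box_set(x0, y0, x0 + w, y0 + h,
          class_label = sample(classes, n, replace = TRUE),
          confidence = if (confidence) round(runif(n), 3) else NA_real_)
}

# Non-overlapping ground-truth boxes for annotator/consensus simulations:
# square boxes of side `side` on a jittered grid, guaranteed separated.
grid_truth <- function(n, side = 40, gap = 30, classes = c("cored", "caa"),
                       image_id = "image") {
  per_row <- ceiling(sqrt(n))
  pitch <- side + gap
  idx <- seq_len(n) - 1
  x0 <- (idx %% per_row) * pitch + sample.int(10, n, replace = TRUE)
  y0 <- (idx %/% per_row) * pitch + sample.int(10, n, replace = TRUE)
  box_set(x0, y0, x0 + side, y0 + side,
          class_label = sample(classes, n, replace = TRUE),
          image_id = image_id)
}
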