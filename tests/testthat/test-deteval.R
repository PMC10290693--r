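test_that("highest-confidence detection takes the label, rest are FPs", {
  lab <- box_set(0, 0, 40, 40)
  det <- box_set(c(1, 2), c(1, 2), c(41, 42), c(41, 42),
                 confidence = c(0.9, 0.8))
  flags <- assign_detections(det, lab)
  expect_equal(flags$tp, c(TRUE, FALSE))
  expect_equal(flags$confidence, c(0.9, 0.8))

  # detections identical to labels at confidence 1: all TP
  labs <- grid_truth(4, classes = "cored")
  dets <- labs; dets$confidence <- 1
  expect_true(all(assign_detections(dets, labs)$tp))
})

test_that("assignment equals the nested-loop oracle on random instances", {
  set.seed(71)
  for (r in 1:80) {
    lab <- random_boxes(sample(0:8, 1))
    det <- random_boxes(sample(0:8, 1), confidence = TRUE)
    for (thr in c(0.3, 0.5)) {
      got <- assign_detections(det, lab, "cored", thr)$tp
      expect_equal(got, naive_assign(det, lab, "cored", thr))
    }
  }
})

test_that("average precision integrates the all-points envelope", {
  expect_equal(average_precision(TRUE, 1), 1)
  expect_equal(average_precision(c(TRUE, FALSE), 1), 1)
  expect_equal(naive_ap(c(TRUE, FALSE, TRUE), 2), 0.5 + 0.5 * 2 / 3)
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2), 0.5 + 0.5 * 2 / 3)
  expect_true(is.na(average_precision(logical(0), 0)))
  expect_equal(average_precision(logical(0), 3), 0)
  # 11-point variant averages precisions on the recall grid
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2,
                                 eleven_point = TRUE),
               (6 * 1 + 5 * 2 / 3) / 11)
})

test_that("AP equals the brute-force oracle on random rankings", {
  set.seed(81)
  for (r in 1:200) {
    n_lab <- sample(1:8, 1)
    flags <- runif(sample(0:8, 1)) < 0.5
    flags <- flags[cumsum(flags) <= n_lab]  # TP count cannot exceed labels
    expect_equal(average_precision(flags, n_lab), naive_ap(flags, n_lab),
                 tolerance = 1e-12)
  }
})

test_that("AP tables flag undefined entries and a perfect detector", {
  labs <- grid_truth(5, classes = "cored")
  dets <- labs; dets$confidence <- 1
  tab <- ap_over_thresholds(dets, labs)
  expect_equal(tab$ap[tab$class_label == "cored"], rep(1, 5))
  # no CAA labels anywhere: CAA AP undefined, not zero
  expect_true(all(is.na(tab$ap[tab$class_label == "caa"])))
  expect_error(ap_over_thresholds(dets, labs, thresholds = 0), "thresholds")
})

test_that("cross-expert precision covers the ordered comparisons", {
  a <- box_set(c(0, 100), c(0, 100), c(40, 140), c(40, 140))
  same4 <- replicate(4, a, simplify = FALSE)
  res <- cross_expert_precision(same4)
  expect_equal(res$mean, 1)
  expect_equal(res$sd, 0)
  expect_equal(nrow(res$precisions), 12L)  # n (n - 1) for n = 4

  # A = 2 boxes, B = 3 boxes, 1 congruous pair
  b <- box_set(c(2, 300, 400), c(2, 300, 400), c(42, 340, 440),
               c(42, 340, 440))
  two <- cross_expert_precision(list(A = a, B = b))
  pb <- two$precisions
  expect_equal(pb$precision[pb$truth == "A"], 1 / 3)
  expect_equal(pb$precision[pb$truth == "B"], 1 / 2)

  # mean invariant to annotator relabeling
  set.seed(91)
  truth <- grid_truth(6)
  sets <- lapply(1:4, function(k) {
    simulate_annotator(truth, annotator_noise(jitter = 3, fp_rate = 1,
                                              seed = 300 + k), 300, 300)
  })
  r1 <- cross_expert_precision(sets)
  r2 <- cross_expert_precision(rev(sets))
  expect_equal(r1$mean, r2$mean)

  empty_pred <- list(A = a, B = empty_box_set())
  expect_warning(cross_expert_precision(empty_pred), "excluded")
})

test_that("classifier filtering removes sub-threshold boxes of filtered classes", {
  truth <- box_set(c(10, 200), c(10, 200), c(60, 260), c(60, 260),
                   class_label = c("caa", "cored"))
  det <- box_set(c(11, 201, 400), c(11, 201, 400), c(61, 261, 450),
                 c(61, 261, 450),
                 class_label = c("caa", "cored", "caa"),
                 confidence = c(0.9, 0.9, 0.8))
  oracle <- oracle_classifier(truth)
  kept <- filter_detections(det, image = NULL, classifier = oracle,
                            image_w = 512, image_h = 512)
  # the spurious CAA at (400, 400) is removed; cored passes untouched
  expect_equal(nrow(kept), 2L)
  expect_false(any(kept$xmin == 400))
  expect_true("cored" %in% kept$class_label)

  # threshold 0 is the identity
  all_kept <- filter_detections(det, NULL, oracle,
                                filter_config(classifier_threshold = 0),
                                image_w = 512, image_h = 512)
  expect_equal(nrow(all_kept), 3L)

  # probability exactly at the threshold is kept (only strictly-below drops)
  at_thr <- function(crop, box) c(cored = 0.5, caa = 0.5)
  expect_equal(nrow(filter_detections(det, NULL, at_thr,
                                      image_w = 512, image_h = 512)), 3L)

  # fail-open: a broken classifier keeps the box with a warning
  broken <- function(crop, box) stop("backend down")
  one_caa <- det[1, ]
  expect_warning(
    out <- filter_detections(one_caa, NULL, broken,
                             image_w = 512, image_h = 512),
    "kept")
  expect_equal(nrow(out), 1L)
})

test_that("label refinement unions detections with labels and covers them", {
  labels <- box_set(c(0, 100), c(0, 100), c(40, 140), c(40, 140))
  expect_equal(box_signature(refine_labels(empty_box_set(), labels)),
               box_signature(merge_boxes(labels)))

  dup <- labels[1, ]; dup$confidence <- 0.9
  refined <- refine_labels(dup, labels)
  expect_equal(nrow(refined), 2L)
  expect_true(all(is.na(refined$confidence)))

  # sparse labels + oracle detector + oracle classifier recover full truth
  set.seed(101)
  truth <- grid_truth(6)
  sparse <- truth[1:2, ]
  det <- simulate_detector(truth, fp_rate = 2, seed = 7,
                           image_w = 300, image_h = 300)
  refined2 <- refine_labels(det, sparse, oracle_classifier(truth),
                            filter_config(classes_filtered = c("cored", "caa")),
                            image_w = 300, image_h = 300)
  expect_equal(box_signature(refined2[names(truth)]), box_signature(truth))
})
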