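test_that("congruous matching is one-to-one, thresholded and greedy", {
  a <- box_set(c(0, 100), c(0, 100), c(40, 140), c(40, 140))
  m <- match_congruous(a, a)
  expect_equal(nrow(m$pairs), 2L)
  expect_equal(m$pairs$iou, c(1, 1))
  expect_length(m$unmatched_a, 0)

  low <- match_congruous(box_set(0, 0, 10, 10), box_set(5, 5, 15, 15))
  expect_equal(nrow(low$pairs), 0L)  # iou 25/175 < 0.5

  # one A box over two B boxes: only the higher-iou B box pairs
  a1 <- box_set(0, 0, 40, 40)
  b2 <- box_set(c(2, 8), c(2, 8), c(42, 48), c(42, 48))
  m2 <- match_congruous(a1, b2)
  expect_equal(nrow(m2$pairs), 1L)
  expect_equal(m2$pairs$index_b, 1L)
  expect_equal(m2$unmatched_b, 2L)

  # classes never match
  caa <- box_set(0, 0, 40, 40, class_label = "caa")
  expect_equal(nrow(match_congruous(a1, caa, "cored")$pairs), 0L)
})

test_that("greedy matching agrees with the max-scan oracle", {
  set.seed(31)
  for (r in 1:60) {
    a <- random_boxes(sample(0:6, 1))
    b <- random_boxes(sample(0:6, 1))
    got <- match_congruous(a, b, "cored", 0.3)$pairs
    want <- naive_match(a, b, "cored", 0.3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$index_a, want$index_a)
      expect_equal(got$index_b, want$index_b)
      expect_equal(got$iou, want$iou, tolerance = 1e-12)
    }
  }
})

test_that("interrater accuracy follows overlaps over total", {
  a <- box_set(c(0, 100), c(0, 100), c(40, 140), c(40, 140))
  expect_equal(interrater_accuracy(a, a), 1)
  # |A| = 2, |B| = 3, one congruous pair: 1 / (2 + 3 - 1)
  b <- box_set(c(2, 300, 400), c(2, 300, 400), c(42, 340, 440),
               c(42, 340, 440))
  expect_equal(interrater_accuracy(a, b), 0.25)
  disjoint <- box_set(500, 500, 540, 540)
  expect_equal(interrater_accuracy(a, disjoint), 0)
  expect_equal(interrater_accuracy(empty_box_set(), empty_box_set()), 1)
})

test_that("agreement matrices are symmetric with unit diagonal", {
  four <- replicate(4, box_set(c(0, 100), c(0, 100), c(40, 140), c(40, 140)),
                    simplify = FALSE)
  m <- agreement_matrix(four)
  expect_equal(m, matrix(1, 4, 4, dimnames = dimnames(m)))
  expect_error(agreement_matrix(four[1]), "at least 2")

  set.seed(41)
  truth <- grid_truth(6)
  sets <- lapply(1:4, function(a) {
    simulate_annotator(truth, annotator_noise(jitter = 4, drop_prob = 0.2,
                                              fp_rate = 1, seed = 100 + a),
                       image_w = 300, image_h = 300)
  })
  m2 <- agreement_matrix(sets, "cored")
  expect_equal(m2, t(m2))
  expect_equal(diag(m2), setNames(rep(1, 4), rownames(m2)))
  expect_true(all(m2 >= 0 & m2 <= 1))
})

test_that("consensus-of-k requires support and averages the geometry", {
  a1 <- box_set(10, 10, 50, 50)
  a2 <- box_set(12, 12, 52, 52)
  silent <- empty_box_set()
  cons <- consensus_boxes(list(NP1 = a1, NP2 = a2, NP3 = silent,
                               NP4 = silent))
  expect_equal(nrow(cons), 1L)
  expect_equal(as.numeric(cons[c("xmin", "ymin", "xmax", "ymax")]),
               c(11, 11, 51, 51))
  expect_equal(cons$support_count, 2L)
  expect_equal(cons$supporting_annotators, "NP1,NP2")

  # an object boxed by a single annotator is absent at support 2
  lone <- consensus_boxes(list(NP1 = a1, NP2 = silent, NP3 = silent,
                               NP4 = silent))
  expect_equal(nrow(lone), 0L)

  # four identical annotators reproduce the annotation set
  same <- consensus_boxes(replicate(4, a1, simplify = FALSE))
  expect_equal(as.numeric(same[c("xmin", "ymin", "xmax", "ymax")]),
               c(10, 10, 50, 50))
  expect_equal(same$support_count, 4L)

  expect_error(consensus_boxes(list(a1, a2),
                               consensus_config(support_required = 3)),
               "exceeds")
})

test_that("support extremes behave as set union and intersection", {
  set.seed(51)
  truth <- grid_truth(5)
  sets <- lapply(1:4, function(a) {
    simulate_annotator(truth, annotator_noise(jitter = 1, drop_prob = 0.3,
                                              seed = 200 + a),
                       image_w = 300, image_h = 300)
  })
  c1 <- consensus_boxes(sets, consensus_config(support_required = 1))
  c4 <- consensus_boxes(sets, consensus_config(support_required = 4))
  expect_gte(nrow(c1), nrow(c4))
  # support-4 objects were boxed by every annotator
  if (nrow(c4) > 0) expect_true(all(c4$support_count == 4L))
  # adding one more annotation can only keep or grow the consensus
  extra <- sets
  extra[[3]] <- rbind(extra[[3]], truth[1, names(extra[[3]])])
  c2 <- consensus_boxes(sets)
  c2x <- consensus_boxes(extra)
  expect_gte(nrow(c2x), nrow(c2))
})

test_that("zero-noise annotators reproduce the truth through consensus", {
  set.seed(61)
  truth <- grid_truth(6)
  clean <- annotator_noise(jitter = 0, drop_prob = 0, fp_rate = 0, seed = 1)
  sets <- replicate(4, simulate_annotator(truth, clean, 300, 300),
                    simplify = FALSE)
  cons <- consensus_boxes(sets)
  expect_equal(box_signature(cons[names(truth)]), box_signature(truth))
})
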