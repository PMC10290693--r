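test_that("rendering is bit-reproducible and leaves global RNG alone", {
  spec <- scene_spec(tile_size = 128, n_cored = 2, n_caa = 1,
                     radius_range = c(8, 12), seed = 42)
  t1 <- render_tile(spec)
  set.seed(1); before <- runif(3)
  set.seed(1)
  t2 <- render_tile(spec)
  after <- runif(3)
  expect_identical(t1$image, t2$image)
  expect_identical(t1$truth, t2$truth)
  expect_identical(before, after)  # no global random state consumed
})

test_that("empty scenes render pure background", {
  tl <- render_tile(scene_spec(tile_size = 96, n_cored = 0, n_caa = 0,
                               seed = 3))
  expect_equal(nrow(tl$truth), 0L)
  expect_false(any(hsv_mask(tl$image, "4G8")))
})

test_that("truth boxes are the tight bounds of painted objects", {
  tl <- render_tile(scene_spec(tile_size = 160, n_cored = 2, n_caa = 1,
                               radius_range = c(9, 14), seed = 8))
  m <- hsv_mask(tl$image, "4G8")
  for (i in seq_len(nrow(tl$truth))) {
    b <- tl$truth[i, ]
    sub <- m[(b$ymin + 1):b$ymax, (b$xmin + 1):b$xmax]
    expect_true(any(sub[1, ]) && any(sub[nrow(sub), ]))  # tight in y
    expect_true(any(sub[, 1]) && any(sub[, ncol(sub)]))  # tight in x
  }
})

test_that("infeasible packings error after bounded retries", {
  expect_error(
    render_tile(scene_spec(tile_size = 100, n_cored = 12, n_caa = 0,
                           radius_range = c(20, 25), min_separation = 30,
                           seed = 1)),
    "infeasible")
})

test_that("annotator simulation honours its noise parameters", {
  set.seed(111)
  truth <- grid_truth(6)
  clean <- simulate_annotator(truth, annotator_noise(jitter = 0, seed = 4),
                              300, 300)
  expect_equal(clean[names(truth)], truth, ignore_attr = TRUE)

  gone <- simulate_annotator(truth,
                             annotator_noise(drop_prob = 1, fp_rate = 0,
                                             seed = 4), 300, 300)
  expect_equal(nrow(gone), 0L)

  noisy <- simulate_annotator(truth,
                              annotator_noise(jitter = 2, fp_rate = 3,
                                              seed = 4), 300, 300)
  expect_true(all(noisy$xmin < noisy$xmax & noisy$ymin < noisy$ymax))
  expect_true(all(noisy$xmax <= 300 & noisy$ymax <= 300))

  # moderate jitter on 40-px boxes keeps two annotators in high agreement
  accs <- vapply(1:20, function(s) {
    a <- simulate_annotator(truth, annotator_noise(jitter = 4, seed = s),
                            300, 300)
    b <- simulate_annotator(truth, annotator_noise(jitter = 4, seed = 1000 + s),
                            300, 300)
    mean(c(interrater_accuracy(a, b, "cored"),
           interrater_accuracy(a, b, "caa")))
  }, numeric(1))
  expect_gt(mean(accs), 0.9)
})

test_that("detector simulation controls recall and confidence ranges", {
  set.seed(121)
  truth <- grid_truth(40, side = 30, gap = 25)
  det0 <- simulate_detector(truth, seed = 5, image_w = 400, image_h = 400)
  expect_equal(nrow(det0), nrow(truth))
  expect_true(all(det0$confidence >= 0.7 & det0$confidence <= 1))

  hits <- vapply(1:10, function(s) {
    d <- simulate_detector(truth, miss_rate = 0.2, seed = s,
                           image_w = 400, image_h = 400)
    nrow(d) / nrow(truth)
  }, numeric(1))
  expect_equal(mean(hits), 0.8, tolerance = 0.08)  # binomial tolerance

  fp <- simulate_detector(truth, fp_rate = 5, seed = 5,
                          image_w = 400, image_h = 400)
  extra <- fp[-seq_len(nrow(truth)), ]
  expect_gt(nrow(extra), 0)
  expect_true(all(extra$confidence <= 0.5))
})

test_that("the oracle classifier encodes truth overlap at threshold 0.5", {
  truth <- box_set(10, 10, 60, 60, class_label = "caa")
  oracle <- oracle_classifier(truth)
  near <- box_set(12, 12, 62, 62, class_label = "caa", confidence = 0.9)
  far <- box_set(200, 200, 250, 250, class_label = "caa", confidence = 0.9)
  expect_equal(unname(oracle(NULL, near)["caa"]), 1)
  expect_equal(unname(oracle(NULL, far)["caa"]), 0)
  expect_equal(unname(oracle(NULL, near)["cored"]), 0)
  # with no truth CAAs every CAA detection is filtered
  no_caa <- oracle_classifier(box_set(10, 10, 60, 60))
  kept <- filter_detections(rbind(near, far), NULL, no_caa,
                            image_w = 512, image_h = 512)
  expect_equal(nrow(kept), 0L)
})

test_that("cohort generation is seeded and respects its means", {
  c1 <- generate_cerad_cohort(n_per_category = 3, tiles_per_wsi = c(1, 2),
                              tile_size = 1024, seed = 5)
  c2 <- generate_cerad_cohort(n_per_category = 3, tiles_per_wsi = c(1, 2),
                              tile_size = 1024, seed = 5)
  expect_identical(c1$records, c2$records)
  zero <- generate_cerad_cohort(category_means = c(none = 0, sparse = 0,
                                                   moderate = 0, frequent = 0),
                                n_per_category = 2, tiles_per_wsi = c(1, 1),
                                tile_size = 512, seed = 2)
  expect_true(all(zero$records$model_count == 0))
  # planted truth matches the recorded count, inside the WSI bounds
  w <- c1$wsis[[length(c1$wsis)]]
  expect_equal(nrow(w$truth), w$planted_count)
  expect_true(all(w$truth$xmax <= w$grid$wsi_width))
})
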