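test_that("RBF-SVM separates linear and XOR toy feature sets", {
  set.seed(1)
  x <- rbind(matrix(rnorm(80, mean = 0), ncol = 2),
             matrix(rnorm(80, mean = 4), ncol = 2))
  y <- rep(c("negative", "positive"), each = 40)
  fit <- train_svm(x, y, svm_config(seed = 1))
  expect_equal(mean(predict(fit, x, type = "class") == y), 1.0)
  # determinism under the seed
  p1 <- predict(train_svm(x, y, svm_config(seed = 4)), x, type = "prob")
  p2 <- predict(train_svm(x, y, svm_config(seed = 4)), x, type = "prob")
  expect_identical(p1, p2)
  # XOR arrangement needs the non-linear kernel
  set.seed(2)
  n <- 60
  quad <- rbind(cbind(rnorm(n, 0, .3), rnorm(n, 0, .3)),
                cbind(rnorm(n, 3, .3), rnorm(n, 3, .3)),
                cbind(rnorm(n, 0, .3), rnorm(n, 3, .3)),
                cbind(rnorm(n, 3, .3), rnorm(n, 0, .3)))
  yx <- rep(c("positive", "positive", "negative", "negative"), each = n)
  xor_fit <- train_svm(quad, yx, svm_config(C = 10, seed = 2))
  expect_gt(mean(predict(xor_fit, quad, type = "class") == yx), 0.9)
  expect_error(train_svm(x, rep("positive", nrow(x))), "both classes")
})

test_that("evaluate reproduces closed-form metrics", {
  perfect <- evaluate(c(rep(1, 5), rep(0, 5)),
                      rep(c("positive", "negative"), each = 5))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  # TP=40, FN=10, FP=20, TN=30
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 20), rep(0.1, 30))
  labels <- c(rep("positive", 50), rep("negative", 50))
  r <- evaluate(scores, labels)
  expect_equal(r$accuracy, 0.70)
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 0.8)
  expect_equal(r$f1, 2 * (2 / 3) * 0.8 / (2 / 3 + 0.8))
  expect_equal(unname(r$confusion["positive", "positive"]), 40)
  expect_equal(unname(r$confusion["negative", "positive"]), 20)
})

test_that("metric identities hold over random confusion matrices", {
  set.seed(11)
  for (i in 1:1000) {
    cnt <- stats::rmultinom(1, sample(20:200, 1), prob = runif(4, .05, 1))
    tp <- cnt[1]; fn <- cnt[2]; fp <- cnt[3]; tn <- cnt[4]
    scores <- c(rep(0.8, tp), rep(0.2, fn), rep(0.8, fp), rep(0.2, tn))
    labels <- c(rep("positive", tp + fn), rep("negative", fp + tn))
    r <- evaluate(scores, labels)
    n <- tp + fn + fp + tn
    expect_identical(sum(r$confusion), as.integer(n))
    expect_identical(r$accuracy, (tp + tn) / n)
    expect_identical(r$precision,
                     if (tp + fp > 0) tp / (tp + fp) else NA_real_)
    expect_identical(r$recall, if (tp + fn > 0) tp / (tp + fn) else NA_real_)
    pr <- r$precision; rc <- r$recall
    expect_identical(r$f1,
                     if (!is.na(pr) && !is.na(rc) && pr + rc > 0)
                       2 * pr * rc / (pr + rc) else NA_real_)
  }
})

test_that("AUC is rank-based: monotone-invariant, chance-level on noise", {
  set.seed(21)
  scores <- runif(500)
  labels <- sample(c("positive", "negative"), 500, replace = TRUE)
  a1 <- evaluate(scores, labels)$auc
  expect_lt(abs(a1 - 0.5), 0.08)
  # strictly monotone transform leaves AUC unchanged
  a2 <- evaluate(stats::qlogis(scores * 0.98 + 0.01), labels)$auc
  expect_identical(a1, a2)
  # agrees with an independent implementation
  a3 <- as.numeric(pROC::auc(pROC::roc(
    response = factor(labels, levels = c("negative", "positive")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(a1, a3, tolerance = 1e-12)
  # one-class labels: AUC undefined, other metrics still computed
  one <- evaluate(runif(10), rep("positive", 10))
  expect_true(is.na(one$auc))
  expect_false(is.na(one$accuracy))
})

test_that("probability quantization is monotone with fixed endpoints", {
  q <- habsuit:::quantize_suitability
  expect_equal(q(0), 1L)      # "very low"
  expect_equal(q(1), 5L)      # "very high"
  expect_equal(q(c(0.19, 0.2, 0.79, 0.8)), c(1L, 2L, 4L, 5L))
  p <- sort(runif(100))
  expect_true(all(diff(q(p)) >= 0))
})

test_that("suitability maps concentrate high classes over planted footprints", {
  cfg_a <- sim_config(raster_size_px = 128L, pixel_size_m = 300,
                      n_stopovers = 3L,
                      stopover_centers = tibble::tibble(
                        stop_id = c("S1", "S2", "S3"),
                        lon = c(98.63, 98.70, 98.77),
                        lat = c(36.63, 36.70, 36.77)),
                      texture_contrast = 1, seed = 41L)
  cfg_b <- cfg_a
  cfg_b$seed <- 42L
  scene_a <- gen_raster(cfg_a, scene_id = "train-scene")
  scene_b <- gen_raster(cfg_b, scene_id = "predict-scene")
  centers <- cfg_a$stopover_centers
  samples <- label_patches(extract_patches(scene_a), centers)
  samples <- augment_samples(samples)
  samples$split <- "train"
  net <- train_mcnn(build_mcnn(mcnn_config(include_temp = FALSE), seed = 41),
                    samples, train_config(epochs = 12L, batch_size = 16L,
                                          seed = 41))
  map <- predict_map(scene_b, net)
  expect_s3_class(map, "suitability_map")
  expect_equal(dim(map$prob), c(8, 8))
  expect_true(all(map$prob >= 0 & map$prob <= 1))
  # class grid is exactly the quantization of the probability grid
  expect_identical(map$class_idx,
                   matrix(habsuit:::quantize_suitability(map$prob), 8, 8))
  # the majority of patches containing a planted centre sit in the top two
  # bins, and they score far above the background
  td <- tidy(map)
  centre_cells <- label_patches(extract_patches(scene_b), centers)
  hot <- centre_cells[centre_cells$label == "positive", c("row", "col")]
  got <- dplyr::inner_join(td, hot, by = c("row", "col"))
  expect_gt(mean(got$class %in% c("high", "very high")), 0.5)
  bg <- dplyr::anti_join(td, hot, by = c("row", "col"))
  expect_gt(stats::median(got$prob), stats::median(bg$prob))
  # a dual-branch model without temperatures is refused
  dual <- build_mcnn(seed = 1)
  expect_error(predict_map(scene_b, dual), "temperature")
  # writers
  tf <- withr::local_tempfile(fileext = ".tif")
  jf <- withr::local_tempfile(fileext = ".json")
  write_suitability_map(map, tf)
  write_suitability_map(map, jf)
  expect_true(file.exists(paste0(tf, ".meta.json")))
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$class_levels, map$class_levels)
})
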