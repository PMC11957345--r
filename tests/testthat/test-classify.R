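test_that("feature bank behaves on constant input and counts channels", {
  v <- array(0.6, c(24, 24, 2))
  f <- compute_features(v)
  expect_equal(ncol(f), 25)
  rec <- attr(f, "recipe")
  expect_equal(length(rec$kinds) * length(rec$scales_px), 25)
  sm <- f[, grepl("^smooth", colnames(f))]
  expect_equal(unname(as.vector(sm)), rep(0.6, length(sm)), tolerance = 1e-6)
  other <- f[, !grepl("^smooth", colnames(f))]
  expect_lt(max(abs(other)), 1e-6)
  expect_error(compute_features(v, scales_px = 30), "scale")
})

test_that("LoG response at the matching scale peaks at a blob centre", {
  n <- 41
  g <- expand.grid(y = 1:n, x = 1:n)
  blob <- matrix(exp(-((g$y - 21)^2 + (g$x - 21)^2) / (2 * 3^2)), n, n)
  f <- compute_features(array(blob, c(n, n, 1)), scales_px = 3)
  log3 <- matrix(f[, "log_s3"], n, n)
  expect_equal(unname(which(log3 == min(log3), arr.ind = TRUE)[1, ]),
               c(21, 21))   # dark-centre convention: minimum at the centre
})

test_that("training separates well-separated classes and is deterministic", {
  set.seed(10)
  n <- 100
  feats <- rbind(matrix(rnorm(n * 4, 0), n),
                 matrix(rnorm(n * 4, 8), n))
  colnames(feats) <- paste0("f", 1:4)
  attr(feats, "vol_dim") <- c(2 * n, 1, 1)
  attr(feats, "recipe") <- list(kinds = "toy", scales_px = 1:4)
  lab <- data.frame(y = seq_len(2 * n), x = 1, z = 1,
                    class = rep(c("signal", "non-myelin"), each = n))
  m <- train_pixel_classifier(feats, lab, seed = 2)
  g <- acquisition_geometry(2 * n, 2 * n, 1)
  p <- predict_probability(m, feats, g)
  pv <- as.vector(p$values)[seq_len(2 * n)]
  expect_true(all(pv[1:n] < 0.5) && all(pv[(n + 1):(2 * n)] > 0.5))
  m2 <- train_pixel_classifier(feats, lab, seed = 2)
  p2 <- predict_probability(m2, feats, g)
  expect_identical(p$values, p2$values)
  expect_error(train_pixel_classifier(feats, transform(lab,
    class = "signal"), seed = 1), "both classes")
})

test_that("compiled batch predictor equals the trainer's own predictions", {
  set.seed(3)
  vol <- array(runif(30 * 30 * 3), c(30, 30, 3))
  f <- compute_features(vol, scales_px = c(1, 2))
  lab <- data.frame(y = sample(30, 160, TRUE), x = sample(30, 160, TRUE),
                    z = sample(3, 160, TRUE),
                    class = rep(c("signal", "non-myelin"), 80))
  m <- train_pixel_classifier(f, lab, seed = 5)
  pm <- predict_probability(m, f, acquisition_geometry(30, 30, 1))
  idx <- sample(length(pm$values), 2000)
  ref <- predict(m$forest, data = f[idx, , drop = FALSE],
                 num.threads = 1)$predictions[, "non-myelin"]
  expect_equal(pm$values[idx], unname(ref), tolerance = 1e-12)
})

test_that("label permutation destroys the signal (null AUC about 0.5)", {
  sc <- small_scene()
  lab <- sc$sim$truth$labels[[1]]
  v <- preprocess_volume(stack_volume(sc$sim$stack, 1))
  f <- compute_features(v, scales_px = c(1, 1.6, 3.5))
  truth_pos <- which(lab == 3L | lab == 5L)
  truth_neg <- which(lab == 1L)
  aucs <- vapply(1:20, function(s) {
    ann <- sample_sparse_labels(lab, 200, seed = s)
    set.seed(s + 100)
    ann$class <- sample(ann$class)
    m <- tryCatch(train_pixel_classifier(f, ann, seed = s),
                  error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    p <- predict_probability(m, f, sc$geometry)
    auc_score(p$values[truth_pos], p$values[truth_neg])
  }, numeric(1))
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.05)
})

test_that("probability maps discriminate pathology from myelin (AUC >= 0.9)", {
  sc <- small_scene()
  lab <- sc$sim$truth$labels[[1]]
  v <- preprocess_volume(stack_volume(sc$sim$stack, 1))
  f <- compute_features(v)
  ann <- sample_sparse_labels(lab, 300, seed = 5)
  m <- train_pixel_classifier(f, ann, seed = 6)
  p <- predict_probability(m, f, sc$geometry)
  expect_true(all(p$values >= 0 & p$values <= 1))
  auc <- auc_score(p$values[lab == 3L], p$values[lab == 1L])
  expect_gte(auc, 0.90)
  # in-sample consistency: annotated voxels mostly keep their class
  rows <- (ann$z - 1) * prod(dim(lab)[1:2]) + (ann$x - 1) * dim(lab)[1] + ann$y
  pv <- p$values[rows]
  ok <- ifelse(ann$class == "non-myelin", pv >= 0.5, pv < 0.5)
  expect_gte(mean(ok), 0.95)
  # calibration sanity: volume-mean probability within the prior band
  priors <- c(mean(lab %in% c(3L, 5L)), 1 - mean(lab %in% c(3L, 5L)))
  expect_gte(mean(p$values), min(priors) - 0.2)
  expect_lte(mean(p$values), max(priors) + 0.2)
  # recipe mismatch is refused
  f2 <- compute_features(v, scales_px = c(1, 2))
  expect_error(predict_probability(m, f2, sc$geometry), "recipe")
})
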