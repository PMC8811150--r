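gaussian_two_class <- function(n, delta_mu, sigma = diag(length(delta_mu)),
                               seed = 1) {
  set.seed(seed)
  p <- length(delta_mu)
  ch <- chol(sigma)
  hi <- matrix(rnorm(n * p), n) %*% ch +
    matrix(delta_mu, n, p, byrow = TRUE)
  lo <- matrix(rnorm(n * p), n) %*% ch
  list(x = rbind(hi, lo),
       labels = rep(c("high_load", "low_load"), each = n))
}

test_that("the learned weights solve the regularized Fisher system", {
  d <- gaussian_two_class(200, c(1, 0), seed = 4)
  m <- train_load_biomarker(d$x, d$labels)
  hi <- d$x[d$labels == "high_load", ]
  lo <- d$x[d$labels == "low_load", ]
  sw <- (crossprod(scale(hi, scale = FALSE)) +
           crossprod(scale(lo, scale = FALSE))) / (nrow(d$x) - 2)
  w_ref <- solve(sw + diag(m$training_meta$ridge, 2),
                 colMeans(hi) - colMeans(lo))
  expect_equal(m$weights, unname(w_ref), tolerance = 1e-12)
  # near-identity covariance, mean gap along e1 -> direction ~ (1, 0)
  expect_gt(abs(m$weights[1]) / sqrt(sum(m$weights^2)), 0.95)
})

test_that("swapping class labels negates the discriminant", {
  d <- gaussian_two_class(50, c(0.8, -0.3), seed = 5)
  m1 <- train_load_biomarker(d$x, d$labels)
  swapped <- ifelse(d$labels == "high_load", "low_load", "high_load")
  m2 <- train_load_biomarker(d$x, swapped)
  expect_equal(m1$weights, -m2$weights, tolerance = 1e-10)
})

test_that("learned direction matches closed form and MASS::lda", {
  sigma <- matrix(c(1, 0.6, 0.6, 2), 2)
  d <- gaussian_two_class(4000, c(1, 0.5), sigma, seed = 6)
  m <- train_load_biomarker(d$x, d$labels)
  w <- m$weights / sqrt(sum(m$weights^2))
  # population closed form
  w_pop <- solve(sigma, c(1, 0.5))
  w_pop <- w_pop / sqrt(sum(w_pop^2))
  angle <- acos(min(1, abs(sum(w * w_pop)))) * 180 / pi
  expect_lt(angle, 2)
  # independent library cross-check on the same sample
  ld <- MASS::lda(d$x, grouping = d$labels)
  w_lib <- ld$scaling[, 1] / sqrt(sum(ld$scaling[, 1]^2))
  expect_lt(acos(min(1, abs(sum(w * w_lib)))) * 180 / pi, 0.5)
})

test_that("degenerate training inputs are rejected or regularized", {
  d <- gaussian_two_class(20, c(1, 0), seed = 7)
  expect_error(train_load_biomarker(d$x, rep("high_load", 40)), "both")
  x_const <- cbind(d$x[, 1], 5)
  expect_warning(train_load_biomarker(x_const, d$labels), "constant")
})

test_that("applying a biomarker is the advertised projection", {
  m <- structure(list(weights = c(0, 1, 0), bias = 0, transfer = "linear",
                      norm = NULL, training_meta = list()),
                 class = "load_biomarker")
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_biomarker(m, X), X[, 2])
  m$weights <- c(0, 0, 0)
  m$bias <- 1.5
  expect_equal(apply_biomarker(m, X), rep(1.5, 10))
  m$transfer <- "logistic"
  sc <- apply_biomarker(m, matrix(rnorm(300), 100, 3))
  expect_true(all(sc > 0 & sc < 1))
  expect_error(apply_biomarker(m, matrix(1, 2, 2)), "feature count")
})

test_that("normalization maps the calibration percentiles onto 1-100", {
  raw <- as.numeric(1:100) # P1 = 1.99, P99 = 99.01 under type-7 quantiles
  m <- structure(list(weights = 1, bias = 0, transfer = "linear",
                      norm = NULL, training_meta = list()),
                 class = "load_biomarker")
  m <- calibrate_biomarker(m, raw)
  p <- unname(quantile(raw, c(0.01, 0.99)))
  expect_equal(normalize_scores(m, p[1]), 1)
  expect_equal(normalize_scores(m, p[2]), 100)
  expect_equal(normalize_scores(m, p[2] + 50), 100) # clipped
  expect_equal(normalize_scores(m, p[1] - 50), 1)
  med <- median(raw)
  expect_equal(normalize_scores(m, med),
               1 + 99 * (med - p[1]) / (p[2] - p[1]))
  expect_error(calibrate_biomarker(m, rep(3, 50)), "degenerate")
})

test_that("the pretrained pipeline biomarker separates load end to end", {
  pre <- default_pretrained()
  expect_equal(length(pre$model$weights), 121)
  # within-sample AUC on the calibration corpus itself is near-perfect
  raw <- apply_biomarker(pre$model, pre$corpus_features)
  expect_gt(mean(raw[pre$corpus_labels == "high_load"]),
            mean(raw[pre$corpus_labels == "low_load"]))
  # rank AUC agrees with an independent ROC implementation
  auc_ref <- as.numeric(suppressMessages(
    pROC::auc(pre$corpus_labels == "high_load", raw)))
  auc_cv <- cv_biomarker_auc(pre$corpus_features, pre$corpus_labels,
                             pre$segment_id, k = 5, seed = 2)
  expect_lt(abs(auc_cv - auc_ref), 0.05) # CV vs in-sample, same scale
  # mean normalized score increases from clearly low to clearly high load
  score_at <- function(load) {
    rec <- synthesize_eeg(load, 10, seed = 900 + round(100 * load),
                          eeg_noise_sd = 0)
    mean(predict(pre$model, baf_extract(rec, pre$baf_spec),
                 type = "normalized"))
  }
  s <- vapply(c(0.1, 0.5, 0.9), score_at, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("model JSON round-trip preserves predictions", {
  pre <- default_pretrained()
  path <- withr::local_tempfile(fileext = ".json")
  write_biomarker_json(pre$model, path)
  m2 <- read_biomarker_json(path)
  X <- pre$corpus_features[1:20, ]
  expect_equal(predict(m2, X, type = "normalized"),
               predict(pre$model, X, type = "normalized"),
               tolerance = 1e-12)
})
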