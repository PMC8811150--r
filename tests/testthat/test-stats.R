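test_that("trial summaries join behavior with temporal EEG means", {
  rec <- data.frame(participant = "P01", experiment = "e", trial = 1,
                    accuracy = 80, economy = 70, time_s = 120,
                    latent_load = 0.5)
  eeg <- synthesize_eeg(0.5, 6, seed = 1)
  bp <- band_powers(eeg)
  scores <- seq(40, 50, length.out = 6)
  row <- summarize_trial(bp, scores, rec)
  expect_equal(row$vc9, mean(scores))
  expect_equal(row$theta, unname(summarize_bands(bp)["theta"]))
  expect_false(row$missing_eeg)
  # permuting epochs leaves the means unchanged
  bp2 <- bp
  perm <- sample(6)
  bp2$values <- bp2$values[perm, ]
  bp2$flagged <- bp2$flagged[perm]
  row2 <- summarize_trial(bp2, scores[perm], rec)
  expect_equal(row2$theta, row$theta)
  expect_equal(row2$vc9, row$vc9)
  # missing EEG flags the row instead of failing
  row3 <- summarize_trial(NULL, NULL, rec)
  expect_true(row3$missing_eeg)
  expect_true(is.na(row3$vc9))
  expect_equal(row3$accuracy, 80)
})

test_that("the gate keeps the LMM for normal data, drops to Wilcoxon otherwise", {
  lmm_rate <- mean(vapply(1:200, function(s) {
    set.seed(s)
    g <- replicate(3, rnorm(19), simplify = FALSE)
    gate_test(g)$chosen_test == "lmm"
  }, logical(1)))
  # four independent gates (3 Shapiro + 1 Levene) at alpha = 0.05 admit
  # the LMM with probability ~0.95^4 ~ 0.81 under exact normality
  expect_gte(lmm_rate, 0.72)
  expect_lte(lmm_rate, 0.90)
  wil_rate <- mean(vapply(1:200, function(s) {
    set.seed(1000 + s)
    g <- replicate(3, rt(19, df = 1), simplify = FALSE)
    gate_test(g)$chosen_test == "wilcoxon"
  }, logical(1)))
  expect_gte(wil_rate, 0.90)
  # degenerate constant group falls through with a warning
  expect_warning(
    res <- gate_test(list(rep(1, 10), rnorm(10), rnorm(10))),
    "constant")
  expect_equal(res$chosen_test, "wilcoxon")
  expect_error(gate_test(list(1:2, 1:10, 1:10)), ">= 3")
})

test_that("the mixed model recovers noiseless dummy-coded effects", {
  d <- simulate_summary_table(n = 10, sd_resid = 0, seed = 2)
  fit <- fit_trial_lmm(d, "y")
  expect_equal(fit$table$coef[fit$table$effect == "trial2_vs_1"], -1.5,
               tolerance = 1e-3)
  expect_equal(fit$table$coef[fit$table$effect == "trial3_vs_1"], -1.75,
               tolerance = 1e-3)
  expect_true(all(fit$table$ci_lo <= fit$table$coef &
                    fit$table$coef <= fit$table$ci_hi))
  expect_true(all(fit$varcomp >= 0))
})

test_that("Westfall-style d equals the variance-component formula", {
  d <- simulate_summary_table(seed = 3)
  fit <- fit_trial_lmm(d, "y")
  for (eff in c("trial2_vs_1", "trial3_vs_1")) {
    coef <- fit$table$coef[fit$table$effect == eff]
    expect_equal(effect_size_d(fit, eff), coef / sqrt(sum(fit$varcomp)),
                 tolerance = 1e-12)
    expect_equal(fit$table$d[fit$table$effect == eff],
                 effect_size_d(fit, eff), tolerance = 1e-12)
  }
  degenerate <- structure(list(table = fit$table,
                               varcomp = c(subject = 0, residual = 0)),
                          class = "trial_lmm")
  expect_error(effect_size_d(degenerate, "trial2_vs_1"), "zero")
})

test_that("exact Wilcoxon matches enumeration and handles degeneracy", {
  # canonical small case: 5 positive differences
  res <- wilcoxon_paired(c(2, 4, 6, 8, 10), 1:5)
  expect_equal(res$W, 0)
  expect_equal(res$p, 0.0625)
  # identical vectors
  expect_warning(res0 <- wilcoxon_paired(1:6, 1:6), "zero")
  expect_equal(res0$p, 1)
  # independent library check on ties-free data
  set.seed(8)
  x <- rnorm(12)
  y <- rnorm(12)
  expect_equal(wilcoxon_paired(x, y)$p,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(wilcoxon_paired(1:3, 1:4), "equal length")
})

test_that("rmcorr equals the centering oracle and honours its contracts", {
  set.seed(12)
  for (i in 1:10) {
    n_subj <- sample(3:10, 1)
    subject <- rep(seq_len(n_subj), each = 3)
    x <- rnorm(3 * n_subj)
    y <- rnorm(3 * n_subj)
    fit <- rmcorr_fit(subject, x, y)
    oracle <- rmcorr_center_oracle(subject, x, y)
    expect_equal(fit$r_rm, oracle$r, tolerance = 1e-10)
    expect_equal(fit$p, oracle$p, tolerance = 1e-10)
    expect_equal(fit$df, 3 * n_subj - n_subj - 1)
  }
  # parallel lines with common slope 1 -> perfect correlation
  x <- rep(1:3, 4)
  y <- x + rep(c(0, 5, 9, 20), each = 3)
  expect_equal(rmcorr_fit(rep(1:4, each = 3), x, y)$r_rm, 1)
  expect_error(rmcorr_fit(rep(1:3, each = 3), rep(1:3, each = 3), rnorm(9)),
               "within-subject")
})

test_that("rmcorr is unbiased under the within-subject null", {
  rs <- vapply(1:500, function(s) {
    set.seed(s)
    subject <- rep(1:19, each = 3)
    rmcorr_fit(subject, rnorm(57), rnorm(57))$r_rm
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("feature selection requires significance in both analyses", {
  stub_lmm <- function(p2, p3) {
    structure(list(table = data.frame(
      effect = c("intercept", "trial2_vs_1", "trial3_vs_1"),
      p = c(0, p2, p3))), class = "trial_lmm")
  }
  stub_rm <- function(p) structure(list(p = p), class = "rmcorr_fit")
  lmm <- list(a = stub_lmm(0.01, 0.6), b = stub_lmm(0.01, 0.01),
              c = stub_lmm(0.5, 0.6))
  rmc <- list(a = list(stub_rm(0.2), stub_rm(0.03)),
              b = list(stub_rm(0.9), stub_rm(0.8)),
              c = stub_rm(0.001))
  expect_equal(select_features(lmm, rmc), "a")
  expect_error(select_features(lmm, rmc[1:2]), "same features")
})

test_that("session comparison gates between paired t and Wilcoxon", {
  set.seed(21)
  base <- data.frame(participant = sprintf("P%02d", 1:10),
                     accuracy = rnorm(10, 80, 5))
  same <- base
  out <- compare_sessions(base, same, features = "accuracy")
  expect_equal(out$p, 1)
  shifted <- base
  shifted$accuracy <- base$accuracy + 2 * 5 + rnorm(10, 0, 1)
  out2 <- compare_sessions(shifted, base, features = "accuracy")
  expect_lt(out2$p, 0.05)
  other <- base
  other$participant <- sprintf("Q%02d", 1:10)
  expect_error(compare_sessions(base, other), "pairing")
  expect_error(compare_sessions(base[1:4, ], base[1:4, ]), ">= 5")
})

test_that("paired power analysis matches the noncentral-t search", {
  expect_equal(sample_size_paired(0.8, 0.05, 0.80), 15)
  expect_lte(sample_size_paired(3, 0.05, 0.80), 4)
  expect_gt(sample_size_paired(0.5), sample_size_paired(0.8))
  # oracle: smallest integer n at/above the continuous power.t.test root
  for (d in c(0.5, 0.8, 1.2)) {
    n_cont <- power.t.test(delta = d, sd = 1, sig.level = 0.05,
                           power = 0.80, type = "paired")$n
    expect_equal(sample_size_paired(d), ceiling(n_cont))
  }
  expect_error(sample_size_paired(-1), "effect_d")
  expect_error(sample_size_paired(0.8, alpha = 0.2, power = 0.1), "exceed")
})
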