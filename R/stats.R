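# Trial-level statistical battery: per-trial summaries, distribution-gated
# mixed models with dummy-coded trial contrasts and Wald inference,
# Westfall-style effect sizes, exact paired Wilcoxon tests,
# repeated-measures correlation, feature selection, session comparisons,
# and a priori paired-t power analysis.

#' Summarize one trial into a row of dependent variables
#'
#' Joins the behavioral record with temporal means of the per-second EEG
#' features: the normalized biomarker and the per-band powers. Missing EEG
#' yields a row with flagged `NA` EEG fields rather than an error.
#'
#' @param band_series a [band_powers()] series, or `NULL` if EEG missing
#' @param biomarker_scores per-second normalized biomarker scores, or `NULL`
#' @param record one-row data frame with participant, experiment, trial,
#'   accuracy, economy, time_s (latent_load carried through if present)
#' @return one-row data frame (`TrialFeatureSummary`): ids, behavioral
#'   scores, `vc9`, one column per band, `missing_eeg` flag
#' @export
summarize_trial <- function(band_series, biomarker_scores, record) {
  stopifnot(nrow(record) == 1)
  out <- data.frame(participant = record$participant,
                    experiment = record$experiment,
                    trial = record$trial,
                    accuracy = record$accuracy,
                    economy = record$economy,
                    time_s = record$time_s)
  if (!is.null(record$latent_load)) out$latent_load <- record$latent_load
  missing_eeg <- is.null(band_series) || is.null(biomarker_scores)
  if (missing_eeg) {
    out$vc9 <- NA_real_
    for (b in default_bands()$name) out[[b]] <- NA_real_
  } else {
    if (length(biomarker_scores) == 0) stopf("empty biomarker series")
    out$vc9 <- mean(biomarker_scores)
    bm <- summarize_bands(band_series)
    for (b in names(bm)) out[[b]] <- unname(bm[b])
  }
  out$missing_eeg <- missing_eeg
  out
}

#' Normality/variance gating between LMM and Wilcoxon
#'
#' Shapiro-Wilk on each trial group and Levene's test (center = mean)
#' across groups at the 0.05 two-tailed level; if any gate rejects, the
#' nonparametric Wilcoxon route is chosen instead of the mixed model. A
#' constant group leaves Shapiro undefined and falls through to Wilcoxon
#' with a warning.
#'
#' @param values_by_trial list of numeric vectors, one per trial group
#' @param alpha gate level (default 0.05)
#' @return object of class `gate_result`: `shapiro_p` (per group),
#'   `levene_p`, `chosen_test` (`"lmm"` or `"wilcoxon"`)
#' @export
gate_test <- function(values_by_trial, alpha = 0.05) {
  if (any(vapply(values_by_trial, length, numeric(1)) < 3)) {
    stopf("each trial group needs >= 3 values")
  }
  constant <- vapply(values_by_trial,
                     function(v) stats::var(v) == 0, logical(1))
  shapiro_p <- rep(NA_real_, length(values_by_trial))
  for (g in seq_along(values_by_trial)) {
    if (!constant[g]) {
      shapiro_p[g] <- stats::shapiro.test(values_by_trial[[g]])$p.value
    }
  }
  y <- unlist(values_by_trial)
  grp <- factor(rep(seq_along(values_by_trial),
                    vapply(values_by_trial, length, numeric(1))))
  levene_p <- car::leveneTest(y, grp, center = mean)[1, "Pr(>F)"]
  if (any(constant)) {
    warnf("constant trial group: Shapiro undefined, falling back to Wilcoxon")
    chosen <- "wilcoxon"
  } else if (any(shapiro_p < alpha) || levene_p < alpha) {
    chosen <- "wilcoxon"
  } else {
    chosen <- "lmm"
  }
  structure(list(shapiro_p = shapiro_p, levene_p = levene_p,
                 chosen_test = chosen),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("Gate: shapiro p = [%s], levene p = %.3g -> %s\n",
              paste(signif(x$shapiro_p, 3), collapse = ", "),
              x$levene_p, x$chosen_test))
  invisible(x)
}

#' Linear mixed model of trial repetition for one dependent variable
#'
#' Fits `dv ~ 1 + trial2 + trial3 + (1 | participant)` by REML, with trial
#' indicator (dummy) variables referenced to trial 1, so the two fixed
#' effects are the trial-2-vs-1 and trial-3-vs-1 contrasts read directly
#' from the model without multiplicity correction. Inference is Wald: z =
#' coef/SE, two-sided normal p, 95% Wald CI. Effect sizes are a Cohen's-d
#' analog: coefficient divided by the SD of a single observation,
#' `sqrt(sigma_subject^2 + sigma_resid^2)`.
#'
#' @param summaries trial-summary data frame (one row per participant x
#'   trial, columns `participant`, `trial`, and the DV)
#' @param dv dependent-variable column name
#' @return object of class `trial_lmm`: `table` (effect, coef, std_err, z,
#'   p, ci_lo, ci_hi, d), `varcomp` (subject and residual variances),
#'   `singular` flag, `dv`, and the underlying `lme4` fit
#' @export
fit_trial_lmm <- function(summaries, dv) {
  if (!dv %in% names(summaries)) stopf("no column '%s' in summaries", dv)
  d <- summaries[!is.na(summaries[[dv]]), ]
  if (length(unique(d$participant)) < 2) stopf("need >= 2 participants")
  dat <- data.frame(y = d[[dv]],
                    participant = factor(d$participant),
                    trial2 = as.numeric(d$trial == 2),
                    trial3 = as.numeric(d$trial == 3))
  fit <- suppressMessages(lme4::lmer(
    y ~ 1 + trial2 + trial3 + (1 | participant), data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(0.975)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_subj <- vc$vcov[vc$grp == "participant"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  sd_obs <- sqrt(var_subj + var_resid)
  tab <- data.frame(
    effect = c("intercept", "trial2_vs_1", "trial3_vs_1"),
    coef = unname(beta), std_err = unname(se), z = unname(z), p = unname(p),
    ci_lo = unname(beta - zc * se), ci_hi = unname(beta + zc * se),
    d = if (sd_obs > 0) unname(beta) / sd_obs else rep(NA_real_, 3))
  structure(list(table = tab,
                 varcomp = c(subject = var_subj, residual = var_resid),
                 singular = lme4::isSingular(fit), dv = dv, fit = fit),
            class = "trial_lmm")
}

#' @export
print.trial_lmm <- function(x, ...) {
  cat(sprintf("Trial LMM for '%s'%s\n", x$dv,
              if (x$singular) " (singular fit)" else ""))
  print(cbind(x$table[1],
              round(x$table[-1], 4)), row.names = FALSE)
  cat(sprintf("  var(subject) = %.4g, var(resid) = %.4g\n",
              x$varcomp["subject"], x$varcomp["residual"]))
  invisible(x)
}

#' Westfall-style effect size of one trial contrast
#'
#' `d = coef / sqrt(var_subject + var_residual)` — the expected mean
#' difference divided by the SD of an individual observation.
#'
#' @param fit a [fit_trial_lmm()] result
#' @param effect `"trial2_vs_1"` or `"trial3_vs_1"`
#' @return numeric d
#' @export
effect_size_d <- function(fit, effect) {
  tot <- sum(fit$varcomp)
  if (tot <= 0) stopf("total variance is zero; effect size undefined")
  row <- fit$table[fit$table$effect == effect, ]
  if (nrow(row) != 1) stopf("unknown effect '%s'", effect)
  row$coef / sqrt(tot)
}

#' Paired Wilcoxon signed-rank test
#'
#' Differences of zero are dropped; `W` is the smaller of the positive- and
#' negative-rank sums. For n <= 25 without ties in |differences| the
#' two-sided p-value is exact (signed-rank null distribution); otherwise a
#' normal approximation with continuity and tie correction is used.
#'
#' @param x,y paired numeric vectors
#' @return list: `W`, `p`, `n` (pairs used), `method`
#' @examples
#' wilcoxon_paired(c(2, 4, 6, 8, 10), 1:5) # W = 0, p = 0.0625
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warnf("all paired differences are zero")
    return(list(W = 0, p = 1, n = 0, method = "degenerate"))
  }
  if (n < 5) warnf("fewer than 5 nonzero differences; p-value is coarse")
  r <- rank(abs(d))
  v_pos <- sum(r[d > 0])
  v_neg <- n * (n + 1) / 2 - v_pos
  W <- min(v_pos, v_neg)
  if (n <= 25) {
    # exact null distribution of the positive-rank sum by dynamic
    # programming over the (possibly tied, half-integer) ranks; the
    # distribution is symmetric, so 2 * P(V <= W) is the two-sided p
    s <- round(2 * r) # doubled ranks are integers even with .5 ties
    dist <- 1
    for (si in s) dist <- (c(dist, numeric(si)) + c(numeric(si), dist)) / 2
    p <- min(1, 2 * sum(dist[seq_len(round(2 * W) + 1)]))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal_approx"
  }
  list(W = W, p = p, n = n, method = method)
}

#' Repeated-measures correlation
#'
#' ANCOVA formulation: `y ~ subject (factor) + x` estimates the common
#' within-subject slope; `r_rm = sign(slope) * sqrt(SS_x / (SS_x +
#' SS_error))` with `df = n_obs - n_subjects - 1` and a two-sided t
#' p-value.
#'
#' @param subject subject identifiers (one per observation)
#' @param x,y paired numeric observations
#' @return object of class `rmcorr_fit`: `r_rm`, `df`, `p`, `slope`
#' @export
rmcorr_fit <- function(subject, x, y) {
  keep <- stats::complete.cases(subject, x, y)
  subject <- factor(subject[keep])
  x <- x[keep]
  y <- y[keep]
  counts <- table(subject)
  if (sum(counts >= 2) < 2) stopf("need >= 2 subjects with >= 2 observations")
  wvar <- tapply(x, subject, stats::var)
  if (all(is.na(wvar) | wvar == 0)) {
    stopf("x has no within-subject variance for any subject")
  }
  fit <- stats::lm(y ~ subject + x)
  an <- suppressWarnings(stats::anova(fit)) # Type I, subject entered first
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  df <- length(x) - nlevels(subject) - 1
  slope <- stats::coef(fit)[["x"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(r_rm = r, df = df, p = p, slope = slope),
            class = "rmcorr_fit")
}

#' @export
print.rmcorr_fit <- function(x, ...) {
  cat(sprintf("rmcorr: r_rm = %.3f, df = %d, p = %.4g\n",
              x$r_rm, x$df, x$p))
  invisible(x)
}

#' Select EEG features significant in both analyses
#'
#' A feature is retained iff at least one of its LMM trial contrasts and at
#' least one of its repeated-measures correlations reach `alpha`.
#'
#' @param lmm_fits named list of [fit_trial_lmm()] results per feature
#' @param rmcorr_fits named list per feature; each element a single
#'   [rmcorr_fit()] or a list of them (one per behavioral measure)
#' @param alpha significance level (default 0.05)
#' @return character vector of retained feature names
#' @export
select_features <- function(lmm_fits, rmcorr_fits, alpha = 0.05) {
  feats <- names(lmm_fits)
  if (!setequal(feats, names(rmcorr_fits))) {
    stopf("lmm_fits and rmcorr_fits must cover the same features")
  }
  keep <- vapply(feats, function(f) {
    tab <- lmm_fits[[f]]$table
    lmm_sig <- any(tab$p[tab$effect != "intercept"] < alpha)
    rf <- rmcorr_fits[[f]]
    if (inherits(rf, "rmcorr_fit")) rf <- list(rf)
    rm_sig <- any(vapply(rf, function(r) r$p, numeric(1)) < alpha)
    lmm_sig && rm_sig
  }, logical(1))
  feats[keep]
}

#' Paired comparison of two sessions, feature by feature
#'
#' For each feature, pairs the two summary tables by participant, gates on
#' Shapiro normality of the paired differences (alpha = 0.05), and applies
#' a paired t-test or the exact Wilcoxon accordingly — the comparison used
#' between the last trial of one session and the first trial of the next.
#'
#' @param summaries_a,summaries_b one-row-per-participant data frames with
#'   the same participants and feature columns
#' @param features feature column names to compare
#' @param alpha gate level
#' @return data frame: `feature`, `test` (`"t"`/`"wilcoxon"`),
#'   `statistic`, `p`
#' @export
compare_sessions <- function(summaries_a, summaries_b,
                             features = c("accuracy", "economy", "time_s",
                                          "vc9", "theta", "delta"),
                             alpha = 0.05) {
  if (!setequal(summaries_a$participant, summaries_b$participant)) {
    stopf("sessions contain different participants; pairing impossible")
  }
  if (nrow(summaries_a) < 5) stopf("need >= 5 paired participants")
  b <- summaries_b[match(summaries_a$participant, summaries_b$participant), ]
  rows <- lapply(features, function(f) {
    diffs <- summaries_a[[f]] - b[[f]]
    normal <- if (stats::var(diffs) == 0) FALSE
              else stats::shapiro.test(diffs)$p.value >= alpha
    if (normal) {
      tt <- stats::t.test(summaries_a[[f]], b[[f]], paired = TRUE)
      data.frame(feature = f, test = "t",
                 statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcoxon_paired(summaries_a[[f]], b[[f]]))
      data.frame(feature = f, test = "wilcoxon",
                 statistic = wt$W, p = wt$p)
    }
  })
  do.call(rbind, rows)
}

#' A priori sample size for a paired t-test
#'
#' Smallest n such that a two-sided paired t-test at level `alpha` reaches
#' the target power under the noncentral t distribution with noncentrality
#' `d * sqrt(n)` and `n - 1` degrees of freedom.
#'
#' @param effect_d standardized paired effect size (> 0)
#' @param alpha significance level (default 0.05)
#' @param power target power (default 0.80)
#' @param n_max search bound
#' @return minimum n (integer)
#' @examples
#' sample_size_paired(0.8) # 15
#' @export
sample_size_paired <- function(effect_d, alpha = 0.05, power = 0.80,
                               n_max = 1e5) {
  if (effect_d <= 0) stopf("effect_d must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stopf("alpha and power must lie in (0, 1)")
  }
  if (power <= alpha) stopf("target power must exceed alpha")
  for (n in 2:n_max) {
    df <- n - 1
    tcrit <- stats::qt(1 - alpha / 2, df)
    ncp <- effect_d * sqrt(n)
    pw <- stats::pt(tcrit, df, ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp)
    if (pw >= power) return(n)
  }
  stopf("no n <= %g attains the requested power", n_max)
}
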