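# LDA-derived linear load biomarker on the wavelet-packet features:
# score = Psi(w . x + b), trained to separate high- from low-load
# calibration segments, then normalized to the 1-100 scale.

feature_matrix <- function(x) {
  if (inherits(x, "baf_series")) x$values
  else if (is.matrix(x)) x
  else matrix(as.numeric(x), nrow = 1)
}

#' Train a linear-discriminant load biomarker
#'
#' Fisher discriminant on pooled per-second feature rows: the weight vector
#' is `solve(Sw + lambda I, mean_high - mean_low)` with `Sw` the pooled
#' within-class covariance and a small ridge `lambda` guarding
#' near-singularity (constant feature columns are tolerated with a
#' warning). The sign convention makes higher raw scores mean higher load;
#' the bias centers the score midway between the class means.
#'
#' @param features pooled feature rows: a matrix or [baf_extract()] series
#' @param labels `"high_load"` / `"low_load"` per row
#' @param transfer transfer function Psi: `"linear"` (default, identity) or
#'   `"logistic"`
#' @param ridge ridge strength; default `1e-6 * trace(Sw) / n_features`
#' @return object of class `load_biomarker` with `weights`, `bias`,
#'   `transfer`, `norm` (filled by [calibrate_biomarker()]),
#'   `training_meta`
#' @export
train_load_biomarker <- function(features, labels,
                                 transfer = c("linear", "logistic"),
                                 ridge = NULL) {
  transfer <- match.arg(transfer)
  X <- feature_matrix(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stopf("one label per feature row required")
  classes <- sort(unique(labels))
  if (!identical(classes, c("high_load", "low_load"))) {
    stopf("labels must contain both 'high_load' and 'low_load'")
  }
  hi <- X[labels == "high_load", , drop = FALSE]
  lo <- X[labels == "low_load", , drop = FALSE]
  if (nrow(hi) < 2 || nrow(lo) < 2) stopf("need >= 2 rows per class")
  mu_hi <- colMeans(hi)
  mu_lo <- colMeans(lo)
  sw <- (crossprod(sweep(hi, 2, mu_hi)) + crossprod(sweep(lo, 2, mu_lo))) /
    (nrow(X) - 2)
  if (any(diag(sw) <= .Machine$double.eps)) {
    warnf("constant feature column(s) present; relying on ridge regularization")
  }
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(sw)) / ncol(X)
  w <- solve(sw + diag(ridge, ncol(X)), mu_hi - mu_lo)
  structure(list(
    weights = as.numeric(w),
    bias = -sum(w * (mu_hi + mu_lo)) / 2,
    transfer = transfer,
    norm = NULL,
    training_meta = list(n_high = nrow(hi), n_low = nrow(lo),
                         n_features = ncol(X), ridge = ridge,
                         fingerprint = signif(sum(X) + sum(X^2), 12))
  ), class = "load_biomarker")
}

psi_transfer <- function(y, transfer) {
  if (transfer == "logistic") 1 / (1 + exp(-y)) else y
}

#' Apply a biomarker to feature rows
#'
#' Row-wise `Psi(w . x + bias)`. With the linear transfer the raw score is
#' unbounded; the logistic transfer maps into (0, 1).
#'
#' @param model a [train_load_biomarker()] model
#' @param features matrix or `baf_series` with matching feature count
#' @return numeric vector of raw scores, one per row
#' @export
apply_biomarker <- function(model, features) {
  X <- feature_matrix(features)
  if (ncol(X) != length(model$weights)) {
    stopf("feature count %d does not match weight length %d",
          ncol(X), length(model$weights))
  }
  psi_transfer(drop(X %*% model$weights) + model$bias, model$transfer)
}

#' Fix the 1-100 normalization from a calibration score corpus
#'
#' Stores the affine map sending the 1st and 99th percentiles of the
#' calibration raw scores to 1 and 100; subsequent scores are mapped and
#' clipped into [1, 100]. Percentile anchors (rather than min/max) keep the
#' scale robust to outliers.
#'
#' @param model a `load_biomarker`
#' @param calibration either raw scores (numeric) or calibration features
#'   to be scored with the model
#' @param probs anchor percentiles (default `c(0.01, 0.99)`)
#' @return the model with `norm` filled in
#' @export
calibrate_biomarker <- function(model, calibration, probs = c(0.01, 0.99)) {
  raw <- if (is.numeric(calibration) && is.null(dim(calibration))) {
    calibration
  } else {
    apply_biomarker(model, calibration)
  }
  anchors <- stats::quantile(raw, probs, names = FALSE, type = 7)
  if (diff(anchors) <= 0) {
    stopf("degenerate calibration distribution: P%g == P%g",
          100 * probs[1], 100 * probs[2])
  }
  model$norm <- list(p_lo = anchors[1], p_hi = anchors[2],
                     lo = 1, hi = 100, probs = probs)
  model
}

#' Map raw biomarker scores onto the 1-100 scale
#'
#' @param model a calibrated `load_biomarker`
#' @param raw numeric raw scores
#' @return scores in [1, 100]
#' @export
normalize_scores <- function(model, raw) {
  if (is.null(model$norm)) stopf("model is not calibrated; run calibrate_biomarker()")
  n <- model$norm
  clip(n$lo + (n$hi - n$lo) * (raw - n$p_lo) / (n$p_hi - n$p_lo),
       n$lo, n$hi)
}

#' @export
predict.load_biomarker <- function(object, newdata,
                                   type = c("raw", "normalized"), ...) {
  type <- match.arg(type)
  raw <- apply_biomarker(object, newdata)
  if (type == "raw") raw else normalize_scores(object, raw)
}

#' @export
coef.load_biomarker <- function(object, ...) {
  c(bias = object$bias, stats::setNames(object$weights,
      paste0("w", seq_along(object$weights))))
}

#' @export
print.load_biomarker <- function(x, ...) {
  cat(sprintf("LDA load biomarker: %d features, %s transfer%s\n",
              length(x$weights), x$transfer,
              if (is.null(x$norm)) " (uncalibrated)" else ", 1-100 scale"))
  cat(sprintf("  trained on %d high / %d low segments (ridge %.2g)\n",
              x$training_meta$n_high, x$training_meta$n_low,
              x$training_meta$ridge))
  invisible(x)
}

# Rank-based AUC of scores against binary labels (positive = high_load).
rank_auc <- function(scores, labels) {
  pos <- scores[labels == "high_load"]
  neg <- scores[labels == "low_load"]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Cross-validated AUC of the biomarker on a labeled feature set
#'
#' Splits segments (not rows) into folds, trains on the held-in folds and
#' scores the held-out rows; returns the pooled rank AUC.
#'
#' @param features pooled feature matrix
#' @param labels per-row class labels
#' @param segment_id per-row segment identifier (rows of one segment stay
#'   in the same fold); defaults to one segment per row
#' @param k folds (default 5)
#' @param seed fold-assignment seed
#' @return AUC in [0, 1]
#' @export
cv_biomarker_auc <- function(features, labels, segment_id = NULL, k = 5,
                             seed = 1) {
  X <- feature_matrix(features)
  labels <- as.character(labels)
  if (is.null(segment_id)) segment_id <- seq_len(nrow(X))
  segs <- unique(segment_id)
  fold_of <- with_seed(seed,
    stats::setNames(sample(rep_len(seq_len(k), length(segs))), segs))
  scores <- numeric(nrow(X))
  for (fold in seq_len(k)) {
    test <- fold_of[as.character(segment_id)] == fold
    fit <- train_load_biomarker(X[!test, , drop = FALSE], labels[!test])
    scores[test] <- apply_biomarker(fit, X[test, , drop = FALSE])
  }
  rank_auc(scores, labels)
}
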