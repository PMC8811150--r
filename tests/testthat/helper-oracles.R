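# Independent oracles used across the suite. These deliberately avoid the
# package's fast code paths: the wavelet oracle builds dense analysis
# matrices from first principles, the Wilcoxon oracle enumerates sign
# assignments, and the rmcorr oracle centers within subjects.

# Dense periodized convolution-decimation matrix (N/2 x N) for taps.
dense_decim_matrix <- function(N, taps) {
  D <- matrix(0, N / 2, N)
  for (k in seq_len(N / 2)) {
    for (j in seq_along(taps)) {
      col <- (2 * (k - 1) + j - 1) %% N + 1
      D[k, col] <- D[k, col] + taps[j]
    }
  }
  D
}

# Explicit analysis matrix of packet node (scale, freq): rows are the basis
# vectors' inner products, built as a product of per-level dense matrices
# following the bits of freq (MSB first; 0 = low-pass, 1 = high-pass).
dense_node_matrix <- function(N, filter, scale, freq) {
  B <- diag(N)
  len <- N
  for (i in seq_len(scale)) {
    bit <- bitwAnd(bitwShiftR(freq, scale - i), 1)
    taps <- if (bit == 0) filter$s_taps else filter$d_taps
    B <- dense_decim_matrix(len, taps) %*% B
    len <- len / 2
  }
  B
}

# All node analysis matrices of a depth-d tree, named like tree nodes,
# built level by level (child matrix = dense decimation x parent matrix).
dense_tree_matrices <- function(N, filter, max_depth) {
  out <- list(s0.f0 = diag(N))
  for (s in seq_len(max_depth)) {
    len <- N / 2^(s - 1)
    for (f in 0:(2^s - 1)) {
      taps <- if (f %% 2 == 0) filter$s_taps else filter$d_taps
      out[[sprintf("s%d.f%d", s, f)]] <-
        dense_decim_matrix(len, taps) %*%
        out[[sprintf("s%d.f%d", s - 1, f %/% 2)]]
    }
  }
  out
}

# Two-sided exact paired-Wilcoxon p by enumerating all 2^n sign
# assignments of the nonzero differences (W = smaller rank sum).
wilcoxon_enum_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  tot <- n * (n + 1) / 2
  v_obs <- sum(r[d > 0])
  W <- min(v_obs, tot - v_obs)
  stats <- vapply(0:(2^n - 1), function(m) {
    sg <- as.integer(intToBits(m))[seq_len(n)]
    v <- sum(r[sg == 1])
    min(v, tot - v)
  }, numeric(1))
  list(W = W, p = mean(stats <= W))
}

# Repeated-measures correlation by per-subject centering + plain OLS.
rmcorr_center_oracle <- function(subject, x, y) {
  xc <- x - ave(x, subject)
  yc <- y - ave(y, subject)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  df <- length(x) - length(unique(subject)) - 1
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# Integrated periodogram power of a real signal over [lo, hi) Hz,
# 0 < lo < hi < fs/2 (counts both spectral half-planes).
periodogram_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  freqs <- (0:(n - 1)) * fs / n
  pw <- Mod(stats::fft(x))^2 / n^2
  sel <- freqs >= lo & freqs < hi & freqs < fs / 2
  2 * sum(pw[sel])
}
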