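# Classical band-power pipeline: per-second Welch PSD over 1-50 Hz,
# averaged into named frequency bands and expressed in dB.

#' Default EEG band definitions
#'
#' Delta 0.5-4 Hz and theta 4-7 Hz as used throughout the analysis; alpha,
#' beta and gamma at the conventional 8-12, 13-30 and 30-50 Hz edges,
#' bounded by the 1-50 Hz analysis range.
#'
#' @return data frame with columns `name`, `lo_hz`, `hi_hz`
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo_hz = c(0.5, 4, 8, 13, 30),
             hi_hz = c(4, 7, 12, 30, 50))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Welch PSD of each column of a segment matrix (one-sided density,
# units^2/Hz). Returns matrix [n_freq x n_cols].
welch_density <- function(segs, fs) {
  n <- nrow(segs)
  w <- hann_window(n)
  # no per-segment demeaning: it bites into the lowest in-band bin via the
  # window main lobe; the caller removes the recording-wide offset instead
  X <- stats::mvfft(segs * w)
  n_freq <- floor(n / 2) + 1
  P <- (Mod(X[seq_len(n_freq), , drop = FALSE])^2) / (fs * sum(w^2))
  dbl <- rep(2, n_freq)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_freq] <- 1
  P * dbl
}

#' Per-second band powers of a recording
#'
#' Splits the recording into whole-second epochs and estimates each epoch's
#' power spectral density by Welch's method (0.5-s Hann segments, 50%
#' overlap, per-segment mean removal). Per band, the per-Hz density is
#' averaged over `[lo_hz, hi_hz)` and converted to dB relative to a fixed
#' 1 microvolt^2/Hz reference. Epochs with zero variance are flagged and
#' emitted as `NA` rather than `-Inf`.
#'
#' @param recording an [eeg_recording()]
#' @param bands band definitions, see [default_bands()]
#' @param epoch_s epoch length in seconds (default 1)
#' @param seg_s Welch segment length in seconds (default 0.5)
#' @param overlap fractional segment overlap (default 0.5)
#' @param ref_density dB reference, microvolt^2/Hz (default 1)
#' @return object of class `band_power_series`: `values` (matrix
#'   [epochs x bands], dB), `band_names`, `flagged` (logical per epoch),
#'   `epoch_s`
#' @export
band_powers <- function(recording, bands = default_bands(), epoch_s = 1,
                        seg_s = 0.5, overlap = 0.5, ref_density = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (any(bands$hi_hz > fs / 2)) {
    stopf("band '%s' exceeds the Nyquist frequency %g Hz",
          bands$name[which(bands$hi_hz > fs / 2)[1]], fs / 2)
  }
  if (any(bands$lo_hz <= 0 | bands$lo_hz >= bands$hi_hz)) {
    stopf("bands must satisfy 0 < lo_hz < hi_hz")
  }
  ep_len <- round(fs * epoch_s)
  n_ep <- floor(length(recording$samples) / ep_len)
  if (n_ep < 1) stopf("recording shorter than one epoch")
  x <- recording$samples - mean(recording$samples) # sensor DC offset
  epochs <- matrix(x[seq_len(n_ep * ep_len)], nrow = ep_len)
  flagged <- apply(epochs, 2, stats::var) == 0

  seg_len <- round(fs * seg_s)
  step <- max(1, round(seg_len * (1 - overlap)))
  starts <- seq(1, ep_len - seg_len + 1, by = step)
  # all segments of all epochs, column-blocked by epoch
  seg_idx <- outer(seq_len(seg_len) - 1, starts, "+")
  segs <- matrix(epochs[as.vector(seg_idx) +
                          rep((seq_len(n_ep) - 1) * ep_len,
                              each = length(seg_idx))],
                 nrow = seg_len)
  dens <- welch_density(segs, fs)
  n_seg <- length(starts)
  freqs <- (seq_len(nrow(dens)) - 1) * fs / seg_len

  values <- matrix(NA_real_, n_ep, nrow(bands),
                   dimnames = list(NULL, bands$name))
  for (b in seq_len(nrow(bands))) {
    sel <- freqs >= bands$lo_hz[b] & freqs < bands$hi_hz[b]
    if (!any(sel)) stopf("band '%s' covers no frequency bin", bands$name[b])
    band_dens <- colMeans(dens[sel, , drop = FALSE])
    per_epoch <- colMeans(matrix(band_dens, nrow = n_seg))
    values[, b] <- ifelse(flagged, NA_real_,
                          10 * log10(pmax(per_epoch, 1e-300) / ref_density))
  }
  structure(list(values = values, band_names = bands$name,
                 flagged = flagged, epoch_s = epoch_s),
            class = "band_power_series")
}

#' Per-band mean over unflagged epochs
#'
#' @param series a [band_powers()] result
#' @return named numeric vector of per-band means, dB
#' @export
summarize_bands <- function(series) {
  stopifnot(inherits(series, "band_power_series"))
  keep <- !series$flagged
  if (!any(keep)) stopf("all epochs are flagged silent; nothing to average")
  colMeans(series$values[keep, , drop = FALSE])
}

#' @export
print.band_power_series <- function(x, ...) {
  cat(sprintf("Band-power series: %d epochs x %d bands (%d flagged)\n",
              nrow(x$values), ncol(x$values), sum(x$flagged)))
  invisible(x)
}
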