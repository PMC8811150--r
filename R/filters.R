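# Conjugate quadrature filter pairs generating the wavelet-packet tree.

# Orthonormal Daubechies scaling (low-pass) coefficients, normalized so that
# sum(taps) = sqrt(2) and sum(taps^2) = 1.
.db_scaling <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  db4 = c(0.230377813308855230, 0.714846570552541500,
          0.630880767929590400, -0.027983769416983850,
          -0.187034811718881140, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

#' Build a quadrature filter pair
#'
#' Returns the low-pass ("averages", operator H) and high-pass
#' ("differences", operator G) convolution-decimation taps that generate the
#' wavelet-packet binary tree. The high-pass taps are the alternating-sign
#' reverse of the low-pass taps, so the pair satisfies the orthonormal
#' quadrature (perfect-reconstruction) identities.
#'
#' @param name one of `"haar"`, `"db2"`, `"db4"` (default `"db4"`,
#'   Daubechies with four vanishing moments, 8 taps)
#' @return an object of class `wp_filter_pair` with elements `s_taps`
#'   (low-pass), `d_taps` (high-pass) and `name`
#' @examples
#' f <- build_filter_pair("haar")
#' f$s_taps # (1, 1)/sqrt(2)
#' @export
build_filter_pair <- function(name = "db4") {
  if (!is.character(name) || length(name) != 1 ||
      !(name %in% names(.db_scaling))) {
    stopf("unknown filter '%s'; supported filters: %s",
          as.character(name)[1], paste(names(.db_scaling), collapse = ", "))
  }
  s <- .db_scaling[[name]]
  L <- length(s)
  d <- (-1)^(seq_len(L) - 1) * rev(s)
  pair <- structure(list(s_taps = s, d_taps = d, name = name),
                    class = "wp_filter_pair")
  check_quadrature(pair)
  pair
}

#' Verify the orthonormal quadrature identities of a filter pair
#'
#' Checks, to `tol`, that each tap set has unit energy, that the low- and
#' high-pass taps are orthogonal at all even shifts, and that each filter is
#' orthogonal to its own even-shifted translates. These identities make the
#' periodized convolution-decimation operators an orthogonal transform.
#'
#' @param pair a `wp_filter_pair`
#' @param tol numeric tolerance (default 1e-10)
#' @return `TRUE` invisibly; errors if any identity fails
#' @export
check_quadrature <- function(pair, tol = 1e-10) {
  s <- pair$s_taps
  d <- pair$d_taps
  if (!all(is.finite(s)) || !all(is.finite(d))) {
    stopf("filter taps must be finite")
  }
  L <- length(s)
  shifts <- seq(0, L - 2, by = 2)
  err <- max(abs(sum(s^2) - 1), abs(sum(d^2) - 1))
  for (k in shifts) {
    idx <- seq_len(L - k)
    err <- max(err,
               abs(sum(s[idx] * d[idx + k])),
               abs(sum(d[idx] * s[idx + k])))
    if (k > 0) {
      err <- max(err,
                 abs(sum(s[idx] * s[idx + k])),
                 abs(sum(d[idx] * d[idx + k])))
    }
  }
  if (err > tol) {
    stopf("filter pair '%s' violates the quadrature identity (err = %.3g)",
          pair$name, err)
  }
  invisible(TRUE)
}

#' @export
print.wp_filter_pair <- function(x, ...) {
  cat(sprintf("Quadrature filter pair '%s' (%d taps)\n", x$name,
              length(x$s_taps)))
  cat("  low-pass  s:", format(x$s_taps, digits = 6), "\n")
  cat("  high-pass d:", format(x$d_taps, digits = 6), "\n")
  invisible(x)
}
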