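# Internal helpers shared across modules.

#' Deterministically mix a base seed with integer/string keys
#'
#' Produces a reproducible 31-bit seed for per-entity random draws so that
#' every participant/trial/component stream is independent of generation
#' order. Strings are folded to integers by character codes.
#'
#' @param seed base integer seed
#' @param ... integer or character keys
#' @return an integer in [0, 2^31 - 2]
#' @keywords internal
mix_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, keeps products < 2^53 in double arithmetic
  x <- as.numeric(seed) %% m
  for (key in list(...)) {
    if (is.character(key)) {
      key <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
    }
    x <- (x * 1103 + as.numeric(key) + 12345) %% m
  }
  as.integer(x)
}

# Run code with a temporary RNG state; global .Random.seed is restored.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
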