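# Wavelet-packet decomposition, best-basis selection, and the pruned
# brain-activity-feature (BAF) bank.
#
# The packet tree is generated by recursive periodized
# convolution-decimation: child 2n is the low-pass (averages) image of node
# n, child 2n+1 the high-pass (differences) image. Nodes are indexed by
# (scale s = depth, freq f = Paley index within depth). All transforms
# operate column-wise on a matrix of epochs so whole recordings are
# decomposed in one pass.

node_key <- function(scale, freq) sprintf("s%d.f%d", scale, freq)

# Periodized convolution + dyadic decimation, column-wise.
# out[k, ] = sum_j taps[j] * X[(2(k-1) + j - 1) mod N + 1, ]
conv_decim <- function(X, taps) {
  N <- nrow(X)
  half <- N / 2
  out <- matrix(0, half, ncol(X))
  base <- 2 * (seq_len(half) - 1)
  for (j in seq_along(taps)) {
    idx <- (base + j - 1) %% N + 1
    out <- out + taps[j] * X[idx, , drop = FALSE]
  }
  out
}

# Adjoint of conv_decim: distribute child coefficients back to length N.
up_undecim <- function(Y, taps, N) {
  out <- matrix(0, N, ncol(Y))
  base <- 2 * (seq_len(nrow(Y)) - 1)
  for (j in seq_along(taps)) {
    idx <- (base + j - 1) %% N + 1
    out[idx, ] <- out[idx, ] + taps[j] * Y
  }
  out
}

#' Full wavelet-packet decomposition of an epoch
#'
#' Recursively applies the low-/high-pass convolution-decimation operators
#' with periodic boundary handling, producing the complete binary tree of
#' packet coefficients down to `max_depth` (2^d nodes of length N/2^d at
#' depth d).
#'
#' @param x numeric vector (one epoch) or matrix with one epoch per column;
#'   epoch length must be divisible by `2^max_depth`
#' @param filter a [build_filter_pair()] object, or a filter name
#' @param max_depth tree depth (default 6)
#' @return an object of class `wp_tree`: list with `nodes` (named list of
#'   coefficient matrices keyed `"s<depth>.f<freq>"`, including the root
#'   `"s0.f0"`), `max_depth`, `filter`, `n` (epoch length), `n_epochs`
#' @examples
#' tr <- wp_decompose(sin(2 * pi * (0:511) / 64), "haar", max_depth = 3)
#' names(tr$nodes)
#' @export
wp_decompose <- function(x, filter = "db4", max_depth = 6) {
  if (is.character(filter)) filter <- build_filter_pair(filter)
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  if (!all(is.finite(X))) stopf("epoch contains non-finite samples")
  N <- nrow(X)
  if (max_depth < 1) stopf("max_depth must be >= 1")
  if (N %% 2^max_depth != 0) {
    stopf("epoch length %d is not divisible by 2^%d = %d",
          N, max_depth, 2^max_depth)
  }
  nodes <- list()
  nodes[[node_key(0, 0)]] <- X
  for (s in seq_len(max_depth)) {
    for (f in seq(0, 2^(s - 1) - 1)) {
      parent <- nodes[[node_key(s - 1, f)]]
      nodes[[node_key(s, 2 * f)]] <- conv_decim(parent, filter$s_taps)
      nodes[[node_key(s, 2 * f + 1)]] <- conv_decim(parent, filter$d_taps)
    }
  }
  structure(list(nodes = nodes, max_depth = max_depth, filter = filter,
                 n = N, n_epochs = ncol(X)),
            class = "wp_tree")
}

#' Reconstruct an epoch from its deepest packet coefficients
#'
#' Applies the adjoint (inverse, for orthonormal filters) transform from the
#' leaves at `max_depth` back to the root. With an orthonormal pair the
#' reconstruction is exact up to round-off.
#'
#' @param tree a `wp_tree`
#' @return numeric vector (single epoch) or matrix of reconstructed epochs
#' @export
wp_reconstruct <- function(tree) {
  filter <- tree$filter
  level <- lapply(seq(0, 2^tree$max_depth - 1),
                  function(f) tree$nodes[[node_key(tree$max_depth, f)]])
  for (s in seq(tree$max_depth, 1)) {
    parent_n <- tree$n / 2^(s - 1)
    nxt <- vector("list", length(level) / 2)
    for (f in seq_along(nxt)) {
      nxt[[f]] <- up_undecim(level[[2 * f - 1]], filter$s_taps, parent_n) +
        up_undecim(level[[2 * f]], filter$d_taps, parent_n)
    }
    level <- nxt
  }
  out <- level[[1]]
  if (ncol(out) == 1) drop(out) else out
}

# Additive information cost of one node's coefficients (single epoch),
# normalized by the total epoch energy so costs are comparable across nodes.
node_cost <- function(coef, total_energy, cost) {
  c2 <- coef^2
  if (cost == "shannon_entropy") {
    if (total_energy <= 0) return(0)
    p <- c2 / total_energy
    p <- p[p > 0]
    -sum(p * log(p))
  } else { # log_energy
    sum(log(c2 + .Machine$double.eps))
  }
}

#' Cost of an arbitrary node set under an additive information cost
#'
#' @param tree a single-epoch `wp_tree`
#' @param nodes data frame with columns `scale`, `freq`
#' @param cost `"shannon_entropy"` (default) or `"log_energy"`
#' @return total cost (numeric scalar)
#' @export
basis_cost <- function(tree, nodes, cost = "shannon_entropy") {
  cost <- match.arg(cost, c("shannon_entropy", "log_energy"))
  total_energy <- sum(tree$nodes[[node_key(0, 0)]]^2)
  sum(vapply(seq_len(nrow(nodes)), function(i) {
    node_cost(tree$nodes[[node_key(nodes$scale[i], nodes$freq[i])]],
              total_energy, cost)
  }, numeric(1)))
}

#' Best-basis selection (Coifman-Wickerhauser)
#'
#' Bottom-up dynamic program over the complete packet tree: a parent node is
#' kept when its cost does not exceed the summed best cost of its children,
#' yielding the disjoint time-frequency cover that minimizes the additive
#' information cost. The root is a candidate, so the selected cost never
#' exceeds any uniform-depth basis.
#'
#' @param tree a single-epoch `wp_tree` complete to `max_depth`
#' @param cost `"shannon_entropy"` (default) or `"log_energy"`
#' @return an object of class `wp_basis`: `nodes` (data frame `scale`,
#'   `freq`), `total_cost`, `cost`
#' @export
best_basis <- function(tree, cost = c("shannon_entropy", "log_energy")) {
  cost <- match.arg(cost)
  if (tree$n_epochs != 1) stopf("best_basis expects a single epoch")
  expected <- sum(2^(0:tree$max_depth))
  if (length(tree$nodes) != expected) {
    stopf("incomplete tree: %d nodes present, %d expected",
          length(tree$nodes), expected)
  }
  total_energy <- sum(tree$nodes[[node_key(0, 0)]]^2)
  best_cost <- list()
  best_nodes <- list()
  for (s in seq(tree$max_depth, 0)) {
    for (f in seq(0, 2^s - 1)) {
      key <- node_key(s, f)
      own <- node_cost(tree$nodes[[key]], total_energy, cost)
      if (s == tree$max_depth) {
        best_cost[[key]] <- own
        best_nodes[[key]] <- data.frame(scale = s, freq = f)
      } else {
        kids <- c(node_key(s + 1, 2 * f), node_key(s + 1, 2 * f + 1))
        child_cost <- best_cost[[kids[1]]] + best_cost[[kids[2]]]
        if (own <= child_cost + 1e-12) {
          best_cost[[key]] <- own
          best_nodes[[key]] <- data.frame(scale = s, freq = f)
        } else {
          best_cost[[key]] <- child_cost
          best_nodes[[key]] <- rbind(best_nodes[[kids[1]]],
                                     best_nodes[[kids[2]]])
        }
      }
    }
  }
  structure(list(nodes = best_nodes[[node_key(0, 0)]],
                 total_cost = best_cost[[node_key(0, 0)]],
                 cost = cost),
            class = "wp_basis")
}

#' All nodes of one tree depth (a uniform basis)
#'
#' @param depth tree depth
#' @return data frame with columns `scale`, `freq`
#' @export
uniform_basis <- function(depth) {
  data.frame(scale = depth, freq = seq(0, 2^depth - 1))
}

#' Prune the packet tree to a fixed brain-activity-feature bank
#'
#' Ranks every candidate node (all depths 1..max_depth) by the median across
#' calibration epochs of its per-coefficient energy — a robust location
#' statistic — and retains the top `k`. Ties break deterministically by
#' (scale, freq) lexicographic order.
#'
#' @param trees a `wp_tree` or list of `wp_tree` objects from the
#'   calibration corpus (epochs are pooled; at least 10 required)
#' @param k number of features to retain (default 121)
#' @return an object of class `wp_basis_spec`: `filter` (name), `max_depth`,
#'   `retained_nodes` (data frame `scale`, `freq`), `k`
#' @export
prune_to_baf <- function(trees, k = 121) {
  if (inherits(trees, "wp_tree")) trees <- list(trees)
  max_depth <- trees[[1]]$max_depth
  filter_name <- trees[[1]]$filter$name
  n_epochs <- sum(vapply(trees, function(t) t$n_epochs, numeric(1)))
  if (n_epochs < 10) {
    stopf("calibration corpus has %d epochs; at least 10 required", n_epochs)
  }
  cand <- do.call(rbind, lapply(seq_len(max_depth), uniform_basis))
  if (k > nrow(cand)) {
    stopf("k = %d exceeds the %d candidate nodes at depth %d",
          k, nrow(cand), max_depth)
  }
  med_energy <- vapply(seq_len(nrow(cand)), function(i) {
    key <- node_key(cand$scale[i], cand$freq[i])
    e <- unlist(lapply(trees, function(t) colMeans(t$nodes[[key]]^2)))
    stats::median(e)
  }, numeric(1))
  ord <- order(-med_energy, cand$scale, cand$freq)
  retained <- cand[sort(ord[seq_len(k)]), , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(filter = filter_name, max_depth = max_depth,
                 retained_nodes = retained, k = k),
            class = "wp_basis_spec")
}

#' @export
print.wp_basis_spec <- function(x, ...) {
  cat(sprintf("BAF bank: %d wavelet-packet nodes (filter %s, depth %d)\n",
              x$k, x$filter, x$max_depth))
  cat("  nodes per depth:",
      paste(sprintf("d%d:%d", seq_len(x$max_depth),
                    tabulate(x$retained_nodes$scale, x$max_depth)),
            collapse = " "), "\n")
  invisible(x)
}

# Symmetric zero-padding of an epoch matrix to dyadic length.
pad_dyadic <- function(X, target) {
  extra <- target - nrow(X)
  if (extra == 0) return(X)
  lo <- extra %/% 2
  hi <- extra - lo
  rbind(matrix(0, lo, ncol(X)), X, matrix(0, hi, ncol(X)))
}

#' Extract per-second brain-activity features from a recording
#'
#' Splits the recording into whole-second epochs, zero-pads each epoch
#' symmetrically to the next dyadic length (500 samples at 500 Hz become
#' 512), decomposes all epochs in one batched transform, and for each
#' retained node emits `log(1 + RMS)` of its coefficients — a
#' scale-compressing, non-negative summary of packet energy.
#'
#' @param recording an [eeg_recording()] (or plain numeric vector with `fs`
#'   passed explicitly)
#' @param spec a [prune_to_baf()] basis specification
#' @param fs sampling rate, taken from the recording when available
#' @return an object of class `baf_series`: `values` (matrix, one row per
#'   second, one column per feature), `feature_ids`, `epoch_s`
#' @export
baf_extract <- function(recording, spec, fs = NULL) {
  samples <- if (inherits(recording, "eeg_recording")) recording$samples
             else as.numeric(recording)
  if (is.null(fs)) {
    fs <- if (inherits(recording, "eeg_recording")) recording$fs
          else stopf("fs must be supplied for plain numeric input")
  }
  n_sec <- floor(length(samples) / fs)
  if (n_sec < 1) stopf("recording shorter than one 1-s epoch")
  epochs <- matrix(samples[seq_len(n_sec * fs)], nrow = fs)
  target <- 2^ceiling(log2(fs))
  epochs <- pad_dyadic(epochs, target)
  tree <- wp_decompose(epochs, build_filter_pair(spec$filter),
                       spec$max_depth)
  keys <- node_key(spec$retained_nodes$scale, spec$retained_nodes$freq)
  values <- vapply(keys, function(key) {
    log1p(sqrt(colMeans(tree$nodes[[key]]^2)))
  }, numeric(n_sec))
  values <- matrix(values, nrow = n_sec,
                   dimnames = list(NULL, keys))
  structure(list(values = values, feature_ids = keys, epoch_s = 1),
            class = "baf_series")
}

#' @export
print.baf_series <- function(x, ...) {
  cat(sprintf("BAF series: %d s x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
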