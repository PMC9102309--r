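# Periodized analysis step: one stage of filter-and-downsample.
# a[k] = sum_n h[n] x[(2k + n) mod N], N even. Returns length N/2.
wp_analysis_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2L
  acc <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (i in seq_along(filt)) {
    idx <- (base + (i - 1L)) %% n + 1L
    acc <- acc + filt[i] * x[idx]
  }
  acc
}

# Adjoint (= inverse for an orthonormal bank) of one analysis stage:
# x[(2k + n) mod N] += h[n] a[k] + g[n] d[k].
wp_synthesis_step <- function(a, d, h, g) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (i in seq_along(h)) {
    idx <- (base + (i - 1L)) %% n + 1L
    x[idx] <- x[idx] + h[i] * a + g[i] * d
  }
  x
}

#' Number of terminal sub-bands at a decomposition level
#'
#' @param j Decomposition level (>= 1).
#' @return `2^j`, the number of equal-width frequency sub-bands.
#' @examples
#' num_subbands(4)  # 16
#' @export
num_subbands <- function(j) {
  if (!is.numeric(j) || length(j) != 1L || j < 1 || j != round(j))
    stop("'j' must be a positive integer level", call. = FALSE)
  as.integer(2^j)
}

#' Level-j wavelet packet decomposition (periodized)
#'
#' Recursively splits both the approximation and the detail branch with the
#' bank's low/high-pass pair, filter-and-downsample at every stage, down to
#' level `j`, producing `2^j` terminal coefficient blocks. Periodic
#' (circular) boundary extension is used, so the total coefficient count
#' equals the (padded) signal length and reconstruction is exact. Signals
#' whose length is not a multiple of `2^j` are symmetrically padded to the
#' next multiple; the padding is removed again after synthesis.
#'
#' @param x Numeric vector, `length(x) >= 2^j`.
#' @param bank A [wp_filter_bank()] or a wavelet name.
#' @param j Decomposition level.
#' @return An object of class `wp_packet_tree`: terminal-node coefficient
#'   blocks in natural (Paley) order, plus bookkeeping for exact inversion.
#' @seealso [wp_reconstruct()], [wp_subbands()]
#' @export
wp_decompose <- function(x, bank, j = 4) {
  if (is.character(bank)) bank <- wp_filter_bank(bank)
  stopifnot(inherits(bank, "wp_filter_bank"))
  j <- as.integer(j)
  if (j < 1) stop("'j' must be >= 1", call. = FALSE)
  x <- as.numeric(x)
  n0 <- length(x)
  if (n0 < 2L^j)
    stop("signal of length ", n0, " is shorter than 2^j = ", 2L^j, call. = FALSE)
  block <- 2L^j
  pad_total <- (block - n0 %% block) %% block
  pad_left <- pad_total %/% 2L
  pad_right <- pad_total - pad_left
  if (pad_total > 0L) {
    # symmetric (reflect) padding; removed after synthesis
    left <- if (pad_left > 0L) x[pad_left:1L] else numeric(0)
    right <- if (pad_right > 0L) x[n0:(n0 - pad_right + 1L)] else numeric(0)
    x <- c(left, x, right)
  }
  nodes <- list(x)
  for (lev in seq_len(j)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      nxt[[2L * i - 1L]] <- wp_analysis_step(nodes[[i]], bank$h)
      nxt[[2L * i]] <- wp_analysis_step(nodes[[i]], bank$g)
    }
    nodes <- nxt
  }
  structure(
    list(level = j, nodes = nodes, wavelet = bank$name, n = n0,
         pad_left = pad_left, pad_right = pad_right),
    class = "wp_packet_tree"
  )
}

#' @export
print.wp_packet_tree <- function(x, ...) {
  cat(sprintf("<wp_packet_tree> %s, level %d (%d terminal nodes), n = %d\n",
              x$wavelet, x$level, length(x$nodes), x$n))
  invisible(x)
}

#' Inverse wavelet packet transform
#'
#' Rebuilds the signal from all terminal nodes of a packet tree. With the
#' orthonormal periodized bank this is the exact inverse of
#' [wp_decompose()].
#'
#' @param tree A `wp_packet_tree` from [wp_decompose()].
#' @param bank The same [wp_filter_bank()] (or name) used for analysis;
#'   defaults to the bank recorded in the tree.
#' @return Numeric vector of the original length.
#' @export
wp_reconstruct <- function(tree, bank = NULL) {
  stopifnot(inherits(tree, "wp_packet_tree"))
  if (is.null(bank)) bank <- tree$wavelet
  if (is.character(bank)) bank <- wp_filter_bank(bank)
  stopifnot(inherits(bank, "wp_filter_bank"))
  if (bank$name != tree$wavelet)
    stop("filter bank '", bank$name, "' does not match the tree's bank '",
         tree$wavelet, "'", call. = FALSE)
  nodes <- tree$nodes
  while (length(nodes) > 1L) {
    up <- vector("list", length(nodes) %/% 2L)
    for (i in seq_along(up))
      up[[i]] <- wp_synthesis_step(nodes[[2L * i - 1L]], nodes[[2L * i]],
                                   bank$h, bank$g)
    nodes <- up
  }
  x <- nodes[[1L]]
  x[(tree$pad_left + 1L):(tree$pad_left + tree$n)]
}

# Natural (Paley) index of the node with frequency rank k (0-based):
# binary-reflected Gray code. The alternating flip comes from the spectral
# reversal that decimation applies to every high-pass branch.
wp_frequency_order <- function(j) {
  k <- 0:(2L^j - 1L)
  bitwXor(k, k %/% 2L) + 1L
}

#' Time-domain sub-band components of a signal
#'
#' Decomposes the signal to level `j` and reconstructs each terminal node
#' in isolation, giving an `N x 2^j` matrix whose columns are time-domain
#' sub-band component signals. Columns are ordered by ascending center
#' frequency: column `c` covers the nominal band
#' `[(c-1) fs / 2^(j+1), c fs / 2^(j+1))`. Column 1 is the approximation
#' sub-band (lowest band); following the S/D naming convention the columns
#' are labelled `S{2^j-1}, D1, ..., D{2^j-1}` (e.g. `S15` at `j = 4`). By
#' linearity of the synthesis the columns sum row-wise to the input signal.
#'
#' @param x Numeric vector or a [recording()].
#' @param bank A [wp_filter_bank()] or wavelet name.
#' @param j Decomposition level (default 4, giving 16 sub-bands).
#' @return Object of class `wp_subbands`: list with `components`
#'   (`N x 2^j` matrix), `approx_index` (always 1 after frequency
#'   ordering), `wavelet`, `level`, `fs` (NA if `x` was a bare vector).
#' @examples
#' x <- sin(2 * pi * 3 * (0:511) / 256)
#' sb <- wp_subbands(x, "db2", j = 4)
#' ncol(sb$components)                     # 16
#' max(abs(rowSums(sb$components) - x))    # ~1e-15
#' @export
wp_subbands <- function(x, bank, j = 4) {
  fs <- NA_real_
  if (inherits(x, "recording")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.character(bank)) bank <- wp_filter_bank(bank)
  tree <- wp_decompose(x, bank, j)
  m <- length(tree$nodes)
  comps <- matrix(0, nrow = tree$n, ncol = m)
  ord <- wp_frequency_order(tree$level)
  zero <- function(v) numeric(length(v))
  for (col in seq_len(m)) {
    # climb from the single kept terminal node to the root, synthesizing
    # against a zero sibling at every stage (all other nodes are zero)
    i <- ord[col]
    cur <- tree$nodes[[i]]
    for (lev in seq_len(tree$level)) {
      cur <- if (i %% 2L == 1L)
        wp_synthesis_step(cur, zero(cur), bank$h, bank$g)
      else
        wp_synthesis_step(zero(cur), cur, bank$h, bank$g)
      i <- (i + 1L) %/% 2L
    }
    comps[, col] <- cur[(tree$pad_left + 1L):(tree$pad_left + tree$n)]
  }
  colnames(comps) <- c(sprintf("S%d", m - 1L), sprintf("D%d", seq_len(m - 1L)))
  structure(
    list(components = comps, approx_index = 1L, wavelet = bank$name,
         level = tree$level, fs = fs),
    class = "wp_subbands"
  )
}

#' @export
print.wp_subbands <- function(x, ...) {
  cat(sprintf("<wp_subbands> %s, level %d: %d x %d (approx column %d)\n",
              x$wavelet, x$level, nrow(x$components), ncol(x$components),
              x$approx_index))
  invisible(x)
}
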