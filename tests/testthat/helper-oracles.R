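# Independent oracles and small fixtures, built in code at test time.

rel_err <- function(a, b) {
  denom <- max(abs(b))
  if (denom == 0) return(max(abs(a - b)))
  max(abs(a - b)) / denom
}

# Independent CCA oracle: whitening (via SVD of the data matrices) followed
# by SVD of the cross-correlation between the interior of X and the
# neighbor-sum surrogate. Shares no code with cca_fit's eigen route.
cca_oracle_rho <- function(X) {
  X <- as.matrix(X)
  T_ <- ncol(X)
  Xc <- X - rowMeans(X)
  Xi <- Xc[, 2:(T_ - 1L), drop = FALSE]
  Y <- Xc[, 1:(T_ - 2L), drop = FALSE] + Xc[, 3:T_, drop = FALSE]
  Xi <- Xi - rowMeans(Xi)
  Y <- Y - rowMeans(Y)
  sx <- svd(t(Xi))
  sy <- svd(t(Y))
  svd(crossprod(sx$u, sy$u))$d
}

# Exhaustive component-selection oracle: best Pearson correlation over all
# proper subsets of removable components (for small M only).
exhaustive_best_rho <- function(reconstruct, M, reference) {
  best <- -Inf
  for (mask in 0:(2^M - 2L)) {  # exclude removing everything
    removed <- which(bitwAnd(mask, 2^(seq_len(M) - 1L)) > 0L)
    r <- stats::cor(reference, reconstruct(removed))
    if (!is.na(r) && r > best) best <- r
  }
  best
}

# small, fast synthetic configuration for unit tests (two artifact bursts)
small_eeg_config <- function(seed = 7, ...) {
  synth_config("EEG", duration_s = 270, fs = 256, seed = seed, ...)
}

# fraction of spectral energy of x below f_cut
spectral_fraction_below <- function(x, fs, f_cut) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1L) * fs / n
  freq <- pmin(freq, fs - freq)
  sum(p[freq <= f_cut]) / sum(p)
}
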