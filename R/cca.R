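#' Neighbor-sum surrogate of a multichannel matrix
#'
#' Builds the secondary variable set for the canonical correlation: for
#' each channel, `y_t = x_{t-1} + x_{t+1}` over the interior samples
#' `t = 2, ..., T-1`. Maximizing correlation against this surrogate makes
#' the canonical sources maximally autocorrelated, which is what turns CCA
#' into a second-order-statistics blind source separation.
#'
#' @param X Numeric matrix, channels in rows (`M x T`, `T >= 3`).
#' @return `M x (T-2)` matrix of neighbor sums.
#' @examples
#' neighbor_surrogate(matrix(1:4, nrow = 1))  # 1+3, 2+4
#' @export
neighbor_surrogate <- function(X) {
  X <- as.matrix(X)
  T_ <- ncol(X)
  if (T_ < 3L) stop("need at least 3 samples for the neighbor surrogate",
                    call. = FALSE)
  X[, 1:(T_ - 2L), drop = FALSE] + X[, 3:T_, drop = FALSE]
}

#' Canonical-correlation blind source separation
#'
#' Estimates an un-mixing matrix `W` such that `S = W X` (channels
#' mean-centered) by canonical correlation analysis between the interior of
#' `X` and its neighbor-sum surrogate. Only the x-side eigenproblem
#' `Cxx^-1 Cxy Cyy^-1 Cyx w = rho^2 w` is solved (solved here through a
#' symmetric whitened form for numerical stability); the eigenvalues are
#' the squared canonical correlations. Sources are ordered by descending
#' canonical correlation, normalized to unit variance, with sign fixed so
#' each source correlates non-negatively with the channel sum; none of
#' these conventions affects the back-projection.
#'
#' @param X Numeric matrix, channels in rows (`M x T`). Requires `M >= 2`
#'   (CCA needs at least two input channels) and `T - 2 > M`.
#' @param surrogate `"sum"` (default): the neighbor-sum
#'   `y_t = x_{t-1} + x_{t+1}`; `"delay"`: the classical single-lag
#'   surrogate `y_t = x_{t-1}`. The sum form makes every pure tone reach
#'   `|rho| = 1` (since `x_{t-1} + x_{t+1} = 2 cos(omega) x_t`), so its
#'   leading canonical directions rank by spectral purity; the delay form
#'   ranks by smoothness (lag-one autocorrelation), which is usually the
#'   better behaved choice for artifact separation.
#' @param reg Ridge added to the within-set covariances, as a fraction of
#'   their mean diagonal (near-collinear wavelet sub-bands can make them
#'   numerically singular). Default `1e-10`.
#' @return Object of class `cca_decomposition`: `sources` (`M x T`),
#'   `W`, `W_inv` (pseudo-inverse), `rho` (descending canonical
#'   correlations), `means` (channel means, restored on re-mixing).
#' @export
cca_fit <- function(X, surrogate = c("sum", "delay"), reg = 1e-10) {
  surrogate <- match.arg(surrogate)
  X <- as.matrix(X)
  M <- nrow(X); T_ <- ncol(X)
  if (M < 2L)
    stop("CCA needs at least two input channels (got ", M, ")", call. = FALSE)
  if (T_ - 2L <= M)
    stop("too few samples: need T - 2 > M", call. = FALSE)
  means <- rowMeans(X)
  Xc <- X - means
  sds <- sqrt(rowMeans(Xc^2))
  if (any(sds == 0) && all(sds == 0))
    stop("all channels are constant", call. = FALSE)
  if (surrogate == "sum") {
    Xi <- Xc[, 2:(T_ - 1L), drop = FALSE]
    Y <- neighbor_surrogate(Xc)
  } else {
    Xi <- Xc[, 2:T_, drop = FALSE]
    Y <- Xc[, 1:(T_ - 1L), drop = FALSE]
  }
  Y <- Y - rowMeans(Y)
  Xi2 <- Xi - rowMeans(Xi)
  nn <- ncol(Xi2)
  Cxx <- tcrossprod(Xi2) / nn
  Cyy <- tcrossprod(Y) / nn
  Cxy <- tcrossprod(Xi2, Y) / nn
  eps_x <- reg * sum(diag(Cxx)) / M
  eps_y <- reg * sum(diag(Cyy)) / M
  diag(Cxx) <- diag(Cxx) + eps_x
  diag(Cyy) <- diag(Cyy) + eps_y
  # symmetric whitened eigenproblem: B = Cxx^-1/2 Cxy Cyy^-1 Cyx Cxx^-1/2
  ex <- eigen(Cxx, symmetric = TRUE)
  vals <- pmax(ex$values, max(ex$values) * 1e-14)
  Whalf <- ex$vectors %*% (t(ex$vectors) / sqrt(vals))  # Cxx^(-1/2)
  Byx <- solve(Cyy, t(Cxy))
  B <- Whalf %*% Cxy %*% Byx %*% Whalf
  B <- (B + t(B)) / 2
  eb <- eigen(B, symmetric = TRUE)
  rho <- sqrt(pmin(pmax(eb$values, 0), 1))
  W <- t(Whalf %*% eb$vectors)      # rows are the un-mixing vectors
  S <- W %*% Xc
  # unit-variance sources, sign aligned with the channel sum
  ssd <- sqrt(rowMeans((S - rowMeans(S))^2))
  ssd[ssd == 0] <- 1
  colsum <- colSums(Xc)
  sgn <- vapply(seq_len(M), function(i) {
    cv <- sum(S[i, ] * colsum)
    if (cv < 0) -1 else 1
  }, numeric(1))
  W <- W * (sgn / ssd)
  S <- S * (sgn / ssd)
  W_inv <- pseudo_inverse(W)
  structure(
    list(sources = S, W = W, W_inv = W_inv, rho = rho, means = means),
    class = "cca_decomposition"
  )
}

pseudo_inverse <- function(A, tol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d)
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' @export
print.cca_decomposition <- function(x, ...) {
  cat(sprintf("<cca_decomposition> %d sources x %d samples\n",
              nrow(x$sources), ncol(x$sources)))
  cat("  rho:", paste(sprintf("%.3f", utils::head(x$rho, 8)), collapse = " "),
      if (length(x$rho) > 8) "..." else "", "\n")
  invisible(x)
}

#' Back-project sources to channel space with selected components removed
#'
#' Zeroes the chosen source rows and maps the edited source matrix back
#' through the (pseudo-)inverse of the un-mixing matrix, restoring the
#' channel means. With `removed = integer(0)` this reproduces the input
#' matrix of [cca_fit()].
#'
#' @param dec A `cca_decomposition`.
#' @param removed Integer indices of sources to zero out (possibly empty).
#'   Removing every component is refused.
#' @return `M x T` matrix of re-mixed channels.
#' @export
cca_remix <- function(dec, removed = integer(0)) {
  stopifnot(inherits(dec, "cca_decomposition"))
  M <- nrow(dec$sources)
  removed <- as.integer(removed)
  if (length(removed) > 0 &&
      (any(removed < 1L) || any(removed > M) || anyDuplicated(removed)))
    stop("'removed' must be distinct indices in 1..", M, call. = FALSE)
  if (length(removed) >= M)
    stop("refusing to remove every component (the result would be the ",
         "channel means only)", call. = FALSE)
  S <- dec$sources
  if (length(removed) > 0L) S[removed, ] <- 0
  dec$W_inv %*% S + dec$means
}

#' Collapse a multichannel sub-band matrix to a single channel
#'
#' Sums the sub-band channels sample-wise. Applied to an unmodified
#' re-mix of a sub-band decomposition this reproduces the analyzed signal
#' (row-sum property of the sub-band matrix plus the re-mix identity).
#'
#' @param Xhat `M x T` matrix of (possibly artifact-edited) sub-band
#'   channels.
#' @return Numeric vector of length `T`.
#' @export
cca_collapse <- function(Xhat) {
  colSums(as.matrix(Xhat))
}
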