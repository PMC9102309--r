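#' Pearson correlation with domain checks
#'
#' @param a,b Numeric vectors or [recording()]s of equal length (>= 2),
#'   each with nonzero variance.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  if (inherits(a, "recording")) a <- a$samples
  if (inherits(b, "recording")) b <- b$samples
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 2L) stop("need at least two samples", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a zero-variance signal", call. = FALSE)
  stats::cor(a, b)
}

# population variance (divide by N); all metric ratios use the same
# convention so the normalization cancels
varp <- function(x) mean((x - mean(x))^2)

#' Signal-to-noise-ratio improvement from cleaning
#'
#' `delta_snr = 10 log10(sigma_x^2 / sigma_e_after^2)
#'            - 10 log10(sigma_x^2 / sigma_e_before^2)`,
#' referenced to the ground-truth channel. The reference variance
#' `sigma_x^2` cancels in the difference. In the default
#' `"error_variance"` mode the before/after terms are the variances of the
#' residuals `reference - corrupted` and `reference - cleaned` (the `e`
#' subscript denotes error). The `"literal_variance"` mode instead takes
#' the variances of the corrupted and cleaned signals themselves, the
#' literal reading of the defining sentence; both modes agree at 0 dB when
#' nothing was removed.
#'
#' @param reference,corrupted,cleaned Numeric vectors or [recording()]s of
#'   equal length.
#' @param mode `"error_variance"` (default) or `"literal_variance"`.
#' @return Improvement in dB. A vanishing after-variance (perfect
#'   recovery) is reported as a capped sentinel of 300 dB with a warning.
#' @examples
#' delta_snr(c(1, -1, 1, -1), c(2, -2, 2, -2), c(1.5, -1.5, 1.5, -1.5))
#' # 10*log10(4) = 6.02 dB
#' @export
delta_snr <- function(reference, corrupted, cleaned,
                      mode = c("error_variance", "literal_variance")) {
  mode <- match.arg(mode)
  if (inherits(reference, "recording")) reference <- reference$samples
  if (inherits(corrupted, "recording")) corrupted <- corrupted$samples
  if (inherits(cleaned, "recording")) cleaned <- cleaned$samples
  if (length(reference) != length(corrupted) ||
      length(reference) != length(cleaned))
    stop("signals must have equal length", call. = FALSE)
  if (mode == "error_variance") {
    vb <- varp(reference - corrupted)
    va <- varp(reference - cleaned)
  } else {
    vb <- varp(corrupted)
    va <- varp(cleaned)
  }
  # variances at numerical-noise level count as zero
  tiny <- 1e-20 * max(varp(reference), varp(corrupted), .Machine$double.xmin)
  if (va <= tiny && vb <= tiny) return(0)  # nothing changed: no improvement
  if (va <= tiny) {
    warning("after-variance is zero; delta SNR capped at 300 dB",
            call. = FALSE)
    return(300)
  }
  if (vb <= tiny) {
    warning("before-variance is zero; delta SNR capped at -300 dB",
            call. = FALSE)
    return(-300)
  }
  10 * log10(vb / va)
}

#' Percentage reduction in motion artifacts (general form)
#'
#' `eta = 100 (1 - (rho_clean - rho_after) / (rho_clean - rho_before))`,
#' where `rho_before`/`rho_after` are the correlations of the reference
#' with the corrupted/cleaned signal and `rho_clean` is the correlation
#' over artifact-free epochs. Values above 100% are possible when
#' `rho_after > rho_clean` and are reported as computed.
#'
#' @param rho_before,rho_after,rho_clean Correlations in `[-1, 1]`;
#'   requires `rho_clean > rho_before`.
#' @return Percentage.
#' @examples
#' eta_general(0.6, 0.8, 0.95)  # 57.14
#' @export
eta_general <- function(rho_before, rho_after, rho_clean) {
  check_rho(rho_before, rho_after, rho_clean)
  if (rho_clean <= rho_before)
    stop("eta undefined: requires rho_clean > rho_before", call. = FALSE)
  100 * (1 - (rho_clean - rho_after) / (rho_clean - rho_before))
}

#' Percentage reduction in motion artifacts (idealized form)
#'
#' The general form with `rho_clean = 1`: in an ideal recording the
#' reference and corrupted channels are perfectly correlated over
#' artifact-free epochs. Since any real `rho_clean < 1` yields a larger
#' eta for the same before/after correlations, this choice is the
#' worst-case (most conservative) report.
#'
#' @param rho_before,rho_after Correlations in `[-1, 1]`;
#'   requires `rho_before < 1`.
#' @return Percentage.
#' @examples
#' eta_ideal(0.6, 0.8)  # 50
#' @export
eta_ideal <- function(rho_before, rho_after) {
  check_rho(rho_before, rho_after)
  if (rho_before >= 1)
    stop("eta undefined: requires rho_before < 1", call. = FALSE)
  100 * (1 - (1 - rho_after) / (1 - rho_before))
}

check_rho <- function(...) {
  for (r in c(...)) {
    if (!is.numeric(r) || length(r) != 1L || is.na(r) ||
        r < -1 - 1e-12 || r > 1 + 1e-12)
      stop("correlations must be single values in [-1, 1]", call. = FALSE)
  }
  invisible(NULL)
}
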