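#' Preprocessing configuration
#'
#' Bundles the three preprocessing stages applied before decomposition:
#' anti-aliased downsampling, power-line notch filtering (50 Hz and its
#' harmonics below Nyquist), and polynomial baseline-drift correction.
#'
#' @param target_fs Target sampling rate in Hz for downsampling, or `NULL`
#'   to keep the original rate. EEG benchmark records are processed at
#'   256 Hz; fNIRS stays at its native 25 Hz.
#' @param notch_center Notch center frequency in Hz (power-line frequency).
#' @param notch_order Butterworth order of each band-stop section.
#' @param notch_bandwidth Full stop-band width in Hz around each harmonic.
#'   The 2 Hz default is narrow enough to spare EEG gamma content.
#' @param baseline_poly_order Order of the baseline-drift polynomial
#'   (least-squares fit over the whole record, then subtracted).
#' @param apply_downsample,apply_notch,apply_baseline Stage switches.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = NULL,
                              notch_center = 50,
                              notch_order = 3,
                              notch_bandwidth = 2,
                              baseline_poly_order = 6,
                              apply_downsample = !is.null(target_fs),
                              apply_notch = TRUE,
                              apply_baseline = TRUE) {
  if (!is.null(target_fs) && (!is.numeric(target_fs) || target_fs <= 0))
    stop("'target_fs' must be positive", call. = FALSE)
  if (notch_order < 1) stop("'notch_order' must be >= 1", call. = FALSE)
  if (baseline_poly_order < 0)
    stop("'baseline_poly_order' must be >= 0", call. = FALSE)
  structure(
    list(target_fs = target_fs, notch_center = notch_center,
         notch_order = as.integer(notch_order),
         notch_bandwidth = notch_bandwidth,
         baseline_poly_order = as.integer(baseline_poly_order),
         apply_downsample = isTRUE(apply_downsample),
         apply_notch = isTRUE(apply_notch),
         apply_baseline = isTRUE(apply_baseline)),
    class = "preprocess_config"
  )
}

# Zero-phase IIR filtering: applies the forward-backward operator |H(w)|^2
# exactly in the frequency domain. Time-domain filtfilt (signal::filtfilt,
# and reimplementations with steady-state initial conditions) leaves
# recursion transients at the record edges that would corrupt the
# comparison between the corrupted and untouched reference channel; the
# spectral form of the same linear operator has none. Odd-reflection
# padding suppresses circular wrap-around at the edges.
zero_phase_filter <- function(b, a, x, npad = NULL) {
  nfilt <- max(length(a), length(b))
  if (is.null(npad)) npad <- max(3L * (nfilt - 1L), 12L)
  n <- length(x)
  npad <- min(as.integer(npad), n - 1L)
  m0 <- n + 2L * npad
  m <- stats::nextn(m0, c(2, 3, 5))  # keep the FFT length composite
  pad_left <- npad
  pad_right <- npad + (m - m0)
  extra <- pad_right - (n - 1L)
  left <- 2 * x[1L] - x[(pad_left + 1L):2L]
  if (extra > 0L) {
    # record shorter than the required right padding: periodize the tail
    right <- 2 * x[n] - x[c((n - 1L):1L, rep(1L, extra))]
  } else {
    right <- 2 * x[n] - x[(n - 1L):(n - pad_right)]
  }
  xp <- c(left, x, right)
  w <- -1i * 2 * pi * (0:(m - 1L)) / m
  num <- 0i; den <- 0i
  for (k in seq_along(b)) num <- num + b[k] * exp(w * (k - 1L))
  for (k in seq_along(a)) den <- den + a[k] * exp(w * (k - 1L))
  mag2 <- Mod(num / den)^2
  y <- Re(stats::fft(stats::fft(xp) * mag2, inverse = TRUE)) / m
  y[(pad_left + 1L):(pad_left + n)]
}

#' Downsample a recording with anti-alias filtering
#'
#' For integer decimation factors the record is low-pass filtered with an
#' 8th-order Chebyshev type-II filter (80 dB stop band starting at the
#' target Nyquist frequency) applied forward-backward (zero phase), then
#' decimated. Zero-phase filtering keeps the downsampled channel aligned
#' with an untouched reference channel. Non-integer rational factors are
#' delegated to polyphase resampling after the same anti-alias stage.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate in Hz. Must not exceed `rec$fs`.
#' @return A [recording()] at `target_fs`.
#' @examples
#' r <- recording(sin(2 * pi * 5 * (0:18431) / 2048), fs = 2048)
#' length(downsample(r, 256)$samples)  # 2304
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop("'target_fs' must be a single positive number", call. = FALSE)
  if (target_fs > rec$fs)
    stop("upsampling (target_fs > fs) is not supported", call. = FALSE)
  if (target_fs == rec$fs) return(rec)
  ratio <- rec$fs / target_fs
  x <- rec$samples
  if (abs(ratio - round(ratio)) < 1e-9) {
    q <- as.integer(round(ratio))
    cf <- signal::cheby2(8, 80, 1 / q)  # stop band starts at target Nyquist
    y <- zero_phase_filter(cf$b, cf$a, x, npad = 100L * q)
    y <- y[seq(1L, length(y), by = q)]
  } else {
    fr <- rational_approx(target_fs / rec$fs)
    cf <- signal::cheby2(8, 80, target_fs / rec$fs)
    y <- zero_phase_filter(cf$b, cf$a, x, npad = ceiling(100 * ratio))
    y <- as.numeric(signal::resample(y, fr[1L], fr[2L]))
    y <- y[seq_len(floor(length(x) * target_fs / rec$fs))]
  }
  recording(y, fs = target_fs, modality = rec$modality, label = rec$label)
}

rational_approx <- function(r, max_den = 4096L) {
  # continued-fraction rational approximation of r = p/q
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < 1e-12) break
    if (x - a < 1e-12) break
    x <- 1 / (x - a)
  }
  c(as.integer(p1), as.integer(q1))
}

#' Power-line notch filter with harmonics
#'
#' Applies a Butterworth band-stop filter (zero phase, forward-backward) at
#' the notch center and every harmonic below the Nyquist frequency. When
#' the center frequency itself is at or above Nyquist (the 25 Hz fNIRS
#' case, where 50 Hz cannot be represented), the signal is returned
#' unchanged with a warning.
#'
#' @param rec A [recording()].
#' @param cfg A [preprocess_config()]; `notch_center`, `notch_order` and
#'   `notch_bandwidth` are used.
#' @return A [recording()] of the same length and rate.
#' @export
notch_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "recording"), inherits(cfg, "preprocess_config"))
  nyq <- rec$fs / 2
  if (cfg$notch_center >= nyq) {
    warning(sprintf(
      "notch center %g Hz is at or above Nyquist (%g Hz); signal returned unchanged",
      cfg$notch_center, nyq), call. = FALSE)
    return(rec)
  }
  x <- rec$samples
  k <- 1L
  while (k * cfg$notch_center < nyq) {
    f0 <- k * cfg$notch_center
    half <- cfg$notch_bandwidth / 2
    lo <- max(f0 - half, 1e-6)
    hi <- min(f0 + half, nyq * (1 - 1e-6))
    bf <- signal::butter(cfg$notch_order, c(lo, hi) / nyq, type = "stop")
    x <- zero_phase_filter(bf$b, bf$a, x,
                           npad = ceiling(4 * rec$fs / cfg$notch_bandwidth))
    k <- k + 1L
  }
  recording(x, fs = rec$fs, modality = rec$modality, label = rec$label)
}

#' Polynomial baseline-drift correction
#'
#' Fits a polynomial of the given order to the whole record by least
#' squares and subtracts it. The abscissa is rescaled to `[-1, 1]` and an
#' orthogonal polynomial basis is used for numerical conditioning; the
#' fitted baseline is identical to the raw-power-basis fit.
#'
#' @param rec A [recording()].
#' @param poly_order Non-negative integer; order 0 removes the mean.
#' @return A [recording()] with the fitted baseline subtracted.
#' @examples
#' r <- recording(seq(0, 1, length.out = 100), fs = 10)
#' max(abs(baseline_correct(r, 1)$samples))  # ~0: a ramp is fully removed
#' @export
baseline_correct <- function(rec, poly_order = 6) {
  stopifnot(inherits(rec, "recording"))
  n <- length(rec$samples)
  if (poly_order < 0) stop("'poly_order' must be >= 0", call. = FALSE)
  if (poly_order >= n)
    stop("'poly_order' must be smaller than the record length", call. = FALSE)
  x <- rec$samples
  if (poly_order == 0) {
    y <- x - mean(x)
  } else {
    tt <- seq(-1, 1, length.out = n)
    basis <- cbind(1, stats::poly(tt, degree = poly_order))
    fit <- stats::lm.fit(basis, x)
    if (fit$rank < ncol(basis))
      stop("baseline fit is rank deficient (degenerate design)", call. = FALSE)
    y <- x - fit$fitted.values
  }
  recording(y, fs = rec$fs, modality = rec$modality, label = rec$label)
}

#' Run the full preprocessing chain on one recording
#'
#' Stage order follows the acquisition pipeline: downsampling, then
#' power-line notch, then baseline-drift correction.
#'
#' @param rec A [recording()].
#' @param cfg A [preprocess_config()].
#' @return A preprocessed [recording()].
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "recording"), inherits(cfg, "preprocess_config"))
  if (cfg$apply_downsample && !is.null(cfg$target_fs) && cfg$target_fs < rec$fs)
    rec <- downsample(rec, cfg$target_fs)
  if (cfg$apply_notch)
    rec <- notch_filter(rec, cfg)
  if (cfg$apply_baseline)
    rec <- baseline_correct(rec, cfg$baseline_poly_order)
  rec
}

#' Preprocess both channels of a paired recording identically
#'
#' Both channels go through the same chain so that downstream metrics
#' compare like with like. Artifact epochs (in seconds) are unaffected by
#' resampling.
#'
#' @param pair A [paired_recording()].
#' @param cfg A [preprocess_config()].
#' @return A preprocessed [paired_recording()].
#' @export
preprocess_pair <- function(pair, cfg = preprocess_config()) {
  stopifnot(inherits(pair, "paired_recording"))
  paired_recording(
    preprocess_recording(pair$corrupted, cfg),
    preprocess_recording(pair$reference, cfg),
    artifact_epochs = pair$artifact_epochs
  )
}

#' Default preprocessing for a modality
#'
#' EEG recorded above 256 Hz is downsampled to 256 Hz; fNIRS keeps its
#' native rate (and the 50 Hz notch is skipped automatically because it
#' lies above the 12.5 Hz Nyquist frequency).
#'
#' @param modality `"EEG"` or `"fNIRS"`.
#' @param fs Native sampling rate of the recording, Hz.
#' @return A [preprocess_config()].
#' @export
default_preprocess <- function(modality = c("EEG", "fNIRS"), fs) {
  modality <- match.arg(modality)
  target <- if (modality == "EEG" && fs > 256) 256 else NULL
  preprocess_config(target_fs = target)
}
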