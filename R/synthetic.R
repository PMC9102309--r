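#' Configuration for the synthetic paired-recording generator
#'
#' Emulates the structure of the two-channel motion-artifact benchmark:
#' two simultaneously recorded, highly correlated channels, one impacted by
#' motion artifacts for 10-25 s at a regular 2 min interval over a ~9 min
#' record; EEG sampled at 2048 Hz, fNIRS at 25 Hz.
#'
#' @param modality `"EEG"` or `"fNIRS"`.
#' @param duration_s Record duration in seconds (default 540, ~9 min).
#' @param fs Sampling rate in Hz; defaults to 2048 (EEG) or 25 (fNIRS).
#' @param artifact_interval_s Spacing of artifact bursts in seconds
#'   (default 120).
#' @param artifact_duration_range_s Burst duration range in seconds,
#'   drawn uniformly (default `c(10, 25)`).
#' @param artifact_amplitude Ratio of the artifact's whole-record RMS to
#'   the clean signal's RMS (default 3). The artifact waveform is zero
#'   outside bursts, so its local RMS inside a burst is correspondingly
#'   larger — bursts are temporally localized with high local variance.
#' @param sensor_noise_level Ratio of independent reference-channel sensor
#'   noise RMS to clean RMS. Default 0, which makes the two channels
#'   identical outside artifact epochs (`rho_clean = 1`, matching the
#'   idealized eta formula).
#' @param seed Integer RNG seed; identical config + seed reproduces the
#'   recording exactly.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(modality = c("EEG", "fNIRS"),
                         duration_s = 540,
                         fs = NULL,
                         artifact_interval_s = 120,
                         artifact_duration_range_s = c(10, 25),
                         artifact_amplitude = 3,
                         sensor_noise_level = 0,
                         seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(fs)) fs <- if (modality == "EEG") 2048 else 25
  if (duration_s <= artifact_interval_s)
    stop("'duration_s' must exceed 'artifact_interval_s'", call. = FALSE)
  if (artifact_amplitude < 0)
    stop("'artifact_amplitude' must be >= 0", call. = FALSE)
  stopifnot(length(artifact_duration_range_s) == 2L,
            artifact_duration_range_s[1L] <= artifact_duration_range_s[2L])
  structure(
    list(modality = modality, duration_s = duration_s, fs = fs,
         artifact_interval_s = artifact_interval_s,
         artifact_duration_range_s = artifact_duration_range_s,
         artifact_amplitude = artifact_amplitude,
         sensor_noise_level = sensor_noise_level,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Gaussian noise band-limited to [f1, f2] Hz by FFT masking, with spectral
# amplitude weighted f^(-exponent/2) inside the band (exponent = 1 gives a
# 1/f power spectral density).
band_noise <- function(n, fs, f1, f2, exponent = 1) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  freq <- c(0, seq_len(n - 1L)) * fs / n
  freq <- pmin(freq, fs - freq)  # two-sided -> folded frequency
  amp <- numeric(n)
  inband <- freq >= f1 & freq <= f2
  amp[inband] <- freq[inband]^(-exponent / 2)
  x <- Re(stats::fft(spec * amp, inverse = TRUE)) / n
  x
}

rms <- function(x) sqrt(mean(x^2))

gen_clean_samples <- function(cfg) {
  n <- round(cfg$duration_s * cfg$fs)
  if (cfg$modality == "EEG") {
    # canonical EEG rhythm bands; 1/f spectral density gives each band a
    # power proportional to log(f_hi/f_lo)
    bands <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 80))
    x <- numeric(n)
    for (b in bands)
      x <- x + band_noise(n, cfg$fs, b[1L], b[2L], exponent = 1)
  } else {
    slow <- band_noise(n, cfg$fs, 0.005, 0.08, exponent = 1)
    slow <- slow / rms(slow)
    t <- (seq_len(n) - 1L) / cfg$fs
    cardiac <- 0.25 * sin(2 * pi * 1.1 * t + stats::runif(1, 0, 2 * pi))
    broadband <- band_noise(n, cfg$fs, 0.1, 5, exponent = 1)
    broadband <- 0.1 * broadband / rms(broadband)
    x <- slow + cardiac + broadband
  }
  x / rms(x)
}

# cosine-tapered (Tukey) window
tukey_window <- function(n, alpha = 0.4) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

gen_artifact <- function(cfg, n_total, clean_rms) {
  art <- numeric(n_total)
  epochs <- matrix(numeric(0), ncol = 2L)
  n_bursts <- floor(cfg$duration_s / cfg$artifact_interval_s)
  for (k in seq_len(n_bursts)) {
    start_s <- k * cfg$artifact_interval_s
    if (start_s >= cfg$duration_s - 1 / cfg$fs) next
    dur_s <- stats::runif(1, cfg$artifact_duration_range_s[1L],
                          cfg$artifact_duration_range_s[2L])
    end_s <- min(start_s + dur_s, cfg$duration_s)
    i0 <- floor(start_s * cfg$fs) + 1L
    i1 <- min(floor(end_s * cfg$fs), n_total)
    nb <- i1 - i0 + 1L
    if (nb < 2L) next
    # integrated white noise: smooth, low-frequency (~1/f^2 spectrum),
    # non-Gaussian over the record, high local variance
    w <- cumsum(stats::rnorm(nb))
    w <- (w - mean(w)) * tukey_window(nb, alpha = 0.4)
    art[i0:i1] <- art[i0:i1] + w
    epochs <- rbind(epochs, c(start_s, end_s))
  }
  if (cfg$artifact_amplitude > 0 && rms(art) > 0) {
    art <- art * cfg$artifact_amplitude * clean_rms / rms(art)
  } else {
    art[] <- 0
  }
  list(artifact = art, epochs = epochs)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a clean (artifact-free) synthetic recording
#'
#' EEG mode: sum of band-limited stochastic processes in the delta
#' (1-4 Hz), theta (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz) and gamma
#' (30-80 Hz) bands with a 1/f power spectral density, so band powers fall
#' off as log(f_hi/f_lo). fNIRS mode: slow hemodynamic oscillation
#' (< 0.1 Hz), a ~1 Hz cardiac component, and low-level broadband noise.
#' Output is normalized to unit RMS and is deterministic given the seed.
#'
#' @param cfg A [synth_config()].
#' @return A [recording()].
#' @export
generate_clean <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  x <- with_seed(cfg$seed, gen_clean_samples(cfg))
  recording(x, fs = cfg$fs, modality = cfg$modality,
            label = sprintf("synthetic clean (seed %d)", cfg$seed))
}

#' Generate a synthetic corrupted/reference pair
#'
#' The reference channel is the clean signal (plus optional independent
#' sensor noise); the corrupted channel is the clean signal plus a motion
#' artifact process: smooth high-amplitude low-frequency bursts
#' (integrated-noise walks under a tapered envelope), one per
#' `artifact_interval_s`, with durations drawn uniformly from
#' `artifact_duration_range_s`. Burst positions are recorded exactly in
#' `artifact_epochs`. With `sensor_noise_level = 0` the channels are
#' identical outside the artifact epochs.
#'
#' @param cfg A [synth_config()].
#' @return A [paired_recording()].
#' @examples
#' cfg <- synth_config(duration_s = 130, fs = 256, seed = 7)
#' pair <- generate_paired(cfg)
#' nrow(pair$artifact_epochs)  # floor(130 / 120) = 1 burst
#' @export
generate_paired <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    clean <- gen_clean_samples(cfg)
    n <- length(clean)
    art <- gen_artifact(cfg, n, rms(clean))
    ref <- clean
    if (cfg$sensor_noise_level > 0)
      ref <- ref + cfg$sensor_noise_level * rms(clean) * stats::rnorm(n)
    paired_recording(
      recording(clean + art$artifact, fs = cfg$fs, modality = cfg$modality,
                label = sprintf("synthetic corrupted (seed %d)", cfg$seed)),
      recording(ref, fs = cfg$fs, modality = cfg$modality,
                label = sprintf("synthetic reference (seed %d)", cfg$seed)),
      artifact_epochs = if (nrow(art$epochs)) art$epochs else NULL
    )
  })
}
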