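#' Single-channel recording
#'
#' A `recording` holds one uniformly sampled channel together with its
#' sampling rate and modality. Amplitude units are whatever the acquisition
#' produced (microvolts for EEG, optical density for fNIRS); nothing in the
#' package depends on the absolute scale.
#'
#' @param samples Numeric vector of samples. Must be finite and of length
#'   at least 2.
#' @param fs Sampling rate in Hz (> 0).
#' @param modality One of `"EEG"` or `"fNIRS"`.
#' @param label Free-text label carried through processing.
#'
#' @return An object of class `recording`: a list with elements `samples`,
#'   `fs`, `modality`, `label`.
#' @examples
#' rec <- recording(sin(2 * pi * 5 * (0:255) / 256), fs = 256)
#' duration(rec)
#' @export
recording <- function(samples, fs, modality = c("EEG", "fNIRS"), label = "") {
  modality <- match.arg(modality)
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("'samples' must have length >= 2", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("'samples' must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs), modality = modality,
         label = as.character(label)[1L]),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s, %d samples @ %g Hz (%.2f s)%s\n",
              x$modality, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  invisible(x)
}

#' @export
length.recording <- function(x) length(x$samples)

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @return Duration in seconds.
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  length(rec$samples) / rec$fs
}

#' Paired corrupted/reference recording
#'
#' Mirrors the two-channel benchmark protocol: two channels recorded
#' simultaneously in close proximity, one impacted by motion artifacts and
#' one left undisturbed (the reference "ground truth"). The two channels are
#' aligned sample-for-sample.
#'
#' @param corrupted A [recording()]: the motion-corrupted channel.
#' @param reference A [recording()]: the artifact-free reference channel.
#'   Must have the same length and sampling rate as `corrupted`.
#' @param artifact_epochs Two-column numeric matrix of `[start_s, end_s)`
#'   intervals in seconds where artifacts were applied, or `NULL` when
#'   unknown. Intervals must be sorted, non-overlapping, and lie within the
#'   record duration.
#'
#' @return An object of class `paired_recording`.
#' @export
paired_recording <- function(corrupted, reference, artifact_epochs = NULL) {
  stopifnot(inherits(corrupted, "recording"), inherits(reference, "recording"))
  if (length(corrupted$samples) != length(reference$samples))
    stop("corrupted and reference channels must have equal length", call. = FALSE)
  if (corrupted$fs != reference$fs)
    stop("corrupted and reference channels must have equal sampling rate",
         call. = FALSE)
  dur <- duration(corrupted)
  if (is.null(artifact_epochs)) {
    artifact_epochs <- matrix(numeric(0), ncol = 2L)
  } else {
    artifact_epochs <- matrix(as.numeric(artifact_epochs), ncol = 2L)
  }
  colnames(artifact_epochs) <- c("start_s", "end_s")
  if (nrow(artifact_epochs) > 0L) {
    if (any(artifact_epochs[, 1L] >= artifact_epochs[, 2L]))
      stop("artifact epochs must satisfy start_s < end_s", call. = FALSE)
    if (any(artifact_epochs < 0) || any(artifact_epochs > dur + 1e-9))
      stop("artifact epochs must lie within [0, duration]", call. = FALSE)
    if (is.unsorted(artifact_epochs[, 1L], strictly = TRUE) &&
        nrow(artifact_epochs) > 1L)
      stop("artifact epochs must be sorted by start time", call. = FALSE)
    if (nrow(artifact_epochs) > 1L &&
        any(artifact_epochs[-1L, 1L] < artifact_epochs[-nrow(artifact_epochs), 2L]))
      stop("artifact epochs must not overlap", call. = FALSE)
  }
  structure(
    list(corrupted = corrupted, reference = reference,
         artifact_epochs = artifact_epochs),
    class = "paired_recording"
  )
}

#' @export
print.paired_recording <- function(x, ...) {
  cat(sprintf("<paired_recording> %s, %d samples @ %g Hz, %d artifact epoch(s)\n",
              x$corrupted$modality, length(x$corrupted$samples),
              x$corrupted$fs, nrow(x$artifact_epochs)))
  invisible(x)
}

#' Logical mask of samples inside artifact epochs
#'
#' @param pair A [paired_recording()].
#' @return Logical vector, `TRUE` for samples whose time falls inside a
#'   declared artifact epoch.
#' @export
artifact_mask <- function(pair) {
  stopifnot(inherits(pair, "paired_recording"))
  n <- length(pair$corrupted$samples)
  t <- (seq_len(n) - 1L) / pair$corrupted$fs
  mask <- rep(FALSE, n)
  ep <- pair$artifact_epochs
  for (i in seq_len(nrow(ep)))
    mask <- mask | (t >= ep[i, 1L] & t < ep[i, 2L])
  mask
}
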