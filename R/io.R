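#' Read a paired recording from CSV
#'
#' The file must have a header with numeric columns `corrupted` and
#' `reference` (an optional `time` column is accepted and validated against
#' `fs`, but never used as the time base: the sampling-rate metadata
#' governs). Artifact epochs, when present, are read from the sidecar JSON
#' file written by [write_paired_csv()].
#'
#' @param path Path to a CSV file.
#' @param fs Sampling rate in Hz.
#' @param modality `"EEG"` or `"fNIRS"`.
#' @return A [paired_recording()].
#' @seealso [write_paired_csv()]
#' @export
read_paired_csv <- function(path, fs, modality = c("EEG", "fNIRS")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE)
  need <- c("corrupted", "reference")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (cn in intersect(c(need, "time"), names(df))) {
    if (!is.numeric(df[[cn]]))
      stop("non-numeric values in column '", cn, "'", call. = FALSE)
    if (anyNA(df[[cn]]))
      stop("missing/unparseable values in column '", cn, "'", call. = FALSE)
  }
  if ("time" %in% names(df) && nrow(df) >= 2L) {
    dt <- diff(df$time)
    if (any(abs(dt * fs - 1) > 1e-3))
      stop("'time' column is inconsistent with fs = ", fs,
           " Hz (beyond 0.1% tolerance)", call. = FALSE)
  }
  epochs <- NULL
  meta_path <- sidecar_path(path)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$artifact_epochs) && length(meta$artifact_epochs) > 0L)
      epochs <- matrix(unlist(meta$artifact_epochs), ncol = 2L, byrow = !is.matrix(meta$artifact_epochs))
    if (is.matrix(meta$artifact_epochs)) epochs <- meta$artifact_epochs
  }
  paired_recording(
    recording(df$corrupted, fs = fs, modality = modality, label = "corrupted"),
    recording(df$reference, fs = fs, modality = modality, label = "reference"),
    artifact_epochs = epochs
  )
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Write a paired recording to CSV
#'
#' Samples are written with 17 significant digits so that a write/read
#' round trip reproduces them to better than 1e-9. Artifact epochs and
#' channel metadata go to a JSON sidecar file `<path>.meta.json`.
#'
#' @param pair A [paired_recording()].
#' @param path Output CSV path.
#' @param time_column Write a `time` column (seconds)? Default `FALSE`.
#' @return Invisibly, `path`.
#' @export
write_paired_csv <- function(pair, path, time_column = FALSE) {
  stopifnot(inherits(pair, "paired_recording"))
  n <- length(pair$corrupted$samples)
  cols <- character(0)
  header <- c("corrupted", "reference")
  body <- cbind(sprintf("%.17g", pair$corrupted$samples),
                sprintf("%.17g", pair$reference$samples))
  if (time_column) {
    header <- c("time", header)
    body <- cbind(sprintf("%.17g", (seq_len(n) - 1L) / pair$corrupted$fs), body)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  ep <- pair$artifact_epochs
  meta <- list(
    fs = pair$corrupted$fs,
    modality = pair$corrupted$modality,
    artifact_epochs = if (nrow(ep) == 0L) list() else
      lapply(seq_len(nrow(ep)), function(i) c(ep[i, 1L], ep[i, 2L]))
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Metrics report for one denoising run
#'
#' @param delta_snr_db Signal-to-noise-ratio improvement in dB.
#' @param eta_pct Percentage reduction in motion artifacts.
#' @param rho_before Correlation of reference and corrupted signal.
#' @param rho_after Correlation of reference and cleaned signal.
#' @param method Free-text descriptor (wavelet, level, stages, selection).
#' @param rho_clean Correlation over artifact-free epochs used for the
#'   general eta formula, or `NA` when the idealized form (rho_clean = 1)
#'   was used.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(delta_snr_db, eta_pct, rho_before, rho_after,
                           method = "", rho_clean = NA_real_) {
  for (r in c(rho_before, rho_after)) {
    if (!is.na(r) && (r < -1 - 1e-12 || r > 1 + 1e-12))
      stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (is.finite(eta_pct) && eta_pct > 100 + 1e-9)
    warning("eta_pct exceeds 100% (rho_after > rho_clean)", call. = FALSE)
  structure(
    list(delta_snr_db = as.numeric(delta_snr_db),
         eta_pct = as.numeric(eta_pct),
         rho_before = as.numeric(rho_before),
         rho_after = as.numeric(rho_after),
         rho_clean = as.numeric(rho_clean),
         method = as.character(method)[1L]),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s\n", x$method))
  cat(sprintf("  delta SNR : %8.2f dB\n", x$delta_snr_db))
  cat(sprintf("  eta       : %8.2f %%\n", x$eta_pct))
  cat(sprintf("  rho before: %8.4f   rho after: %.4f\n",
              x$rho_before, x$rho_after))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report A [metrics_report()], or a list of them (each entry is
#'   written, together with an arithmetic-mean summary row).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics_json <- function(report, path) {
  as_row <- function(r) {
    stopifnot(inherits(r, "metrics_report"))
    unclass(r)
  }
  if (inherits(report, "metrics_report")) {
    payload <- as_row(report)
  } else {
    rows <- lapply(report, as_row)
    num <- c("delta_snr_db", "eta_pct", "rho_before", "rho_after")
    payload <- list(
      reports = rows,
      summary = lapply(stats::setNames(num, num), function(f)
        mean(vapply(rows, `[[`, numeric(1), f)))
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read back a metrics report written by [write_metrics_json()]
#' @param path JSON path.
#' @return A [metrics_report()] or, for batch files, a list with elements
#'   `reports` and `summary`.
#' @export
read_metrics_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(o) metrics_report(o$delta_snr_db, o$eta_pct, o$rho_before,
                                   o$rho_after, o$method,
                                   if (is.null(o$rho_clean)) NA_real_ else o$rho_clean)
  if (!is.null(obj$reports)) {
    reps <- if (is.data.frame(obj$reports)) {
      lapply(seq_len(nrow(obj$reports)), function(i) mk(as.list(obj$reports[i, ])))
    } else lapply(obj$reports, mk)
    list(reports = reps, summary = obj$summary)
  } else {
    mk(obj)
  }
}
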