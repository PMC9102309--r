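#' Greedy ground-truth-guided component rejection
#'
#' Hill-climbing over single-component removals: at every pass each
#' still-kept component is tentatively removed, the signal is rebuilt via
#' the supplied reconstruction contract, and its Pearson correlation with
#' the reference is evaluated. The component giving the largest strict
#' improvement is removed; passes repeat until no removal improves the
#' correlation by more than `tol`. Components are only ever discarded when
#' doing so raises the correlation with the reference, so the final
#' correlation can never fall below the no-removal baseline. The same
#' contract serves WPD sub-band columns (single-stage method) and CCA
#' sources (two-stage method).
#'
#' @param reconstruct Function taking an integer vector of removed
#'   component indices and returning the reconstructed signal.
#' @param n_components Number M of candidate components (M >= 2).
#' @param reference Numeric vector or [recording()]: the ground-truth
#'   signal, same length as the reconstructions.
#' @param tol Strict-improvement tolerance (default 1e-12), guarding
#'   against float-noise removals.
#' @return Object of class `selection_result`: `removed` (integer vector,
#'   possibly empty), `rho_trace` (data frame with one row per evaluated
#'   candidate: pass, candidate, rho_if_removed), `final_rho`, `rho_none`
#'   (correlation with nothing removed), `mode = "ground-truth"`.
#' @export
greedy_select <- function(reconstruct, n_components, reference, tol = 1e-12) {
  if (inherits(reference, "recording")) reference <- reference$samples
  reference <- as.numeric(reference)
  M <- as.integer(n_components)
  if (M < 2L) stop("need at least two candidate components", call. = FALSE)
  base <- reconstruct(integer(0))
  if (length(base) != length(reference))
    stop("reference length (", length(reference),
         ") does not match reconstruction length (", length(base), ")",
         call. = FALSE)
  rho_of <- function(sig) stats::cor(reference, sig)
  removed <- integer(0)
  rho_cur <- rho_of(base)
  rho_none <- rho_cur
  trace <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    kept <- setdiff(seq_len(M), removed)
    if (length(kept) <= 1L) break  # never remove the full component set
    best_c <- NA_integer_
    best_rho <- rho_cur
    for (cand in kept) {
      if (length(removed) + 1L >= M) next
      sig <- reconstruct(c(removed, cand))
      r <- rho_of(sig)
      trace[[length(trace) + 1L]] <-
        data.frame(pass = pass, candidate = cand, rho_if_removed = r)
      # best-improvement-first; ties broken by lowest component index
      if (!is.na(r) && r > best_rho + tol) {
        best_rho <- r
        best_c <- cand
      }
    }
    if (is.na(best_c)) break
    removed <- c(removed, best_c)
    rho_cur <- best_rho
  }
  structure(
    list(removed = sort(removed),
         rho_trace = if (length(trace)) do.call(rbind, trace) else
           data.frame(pass = integer(0), candidate = integer(0),
                      rho_if_removed = numeric(0)),
         final_rho = rho_cur, rho_none = rho_none, mode = "ground-truth"),
    class = "selection_result"
  )
}

#' Ground-truth-free selection: drop the approximation sub-band
#'
#' Discards the lowest-frequency (approximation) sub-band component and
#' keeps every detail sub-band. No reference signal is consulted, making
#' this the selection rule available when no ground-truth channel exists;
#' motion artifacts concentrate in the lowest band, so removing it alone
#' already reduces them substantially.
#'
#' @param subbands A [wp_subbands()] decomposition.
#' @return A `selection_result` with `removed` equal to the approximation
#'   column index and `final_rho = NA` (no reference was used).
#' @export
approx_drop_select <- function(subbands) {
  stopifnot(inherits(subbands, "wp_subbands"))
  structure(
    list(removed = subbands$approx_index,
         rho_trace = data.frame(pass = integer(0), candidate = integer(0),
                                rho_if_removed = numeric(0)),
         final_rho = NA_real_, rho_none = NA_real_, mode = "approx-drop"),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> mode=%s removed={%s}",
              x$mode, paste(x$removed, collapse = ",")))
  if (!is.na(x$final_rho))
    cat(sprintf(" rho %.4f -> %.4f", x$rho_none, x$final_rho))
  cat("\n")
  invisible(x)
}

#' Reconstruction contract over sub-band columns
#'
#' Returns the function mapping a removed-column index set to the summed
#' signal of the kept columns — the reconstruction contract used by
#' [greedy_select()] for the single-stage method.
#'
#' @param subbands A [wp_subbands()].
#' @return `function(removed) -> numeric`.
#' @export
subband_reconstructor <- function(subbands) {
  stopifnot(inherits(subbands, "wp_subbands"))
  comps <- subbands$components
  total <- rowSums(comps)
  function(removed) {
    if (length(removed) == 0L) return(total)
    total - rowSums(comps[, removed, drop = FALSE])
  }
}

#' Reconstruction contract over CCA sources
#'
#' Returns the function mapping a removed-source index set to the collapsed
#' (channel-summed) re-mixed signal — the reconstruction contract used by
#' [greedy_select()] for the two-stage method. The collapse of source r's
#' back-projection is `colSums(W_inv)[r] * sources[r, ]`, so candidates are
#' evaluated without re-mixing the full matrix.
#'
#' @param dec A [cca_fit()] decomposition.
#' @return `function(removed) -> numeric`.
#' @export
cca_reconstructor <- function(dec) {
  stopifnot(inherits(dec, "cca_decomposition"))
  full <- cca_collapse(cca_remix(dec, integer(0)))
  contrib <- colSums(dec$W_inv)  # per-source collapse weight
  function(removed) {
    if (length(removed) == 0L) return(full)
    out <- full
    for (r in removed) out <- out - contrib[r] * dec$sources[r, ]
    out
  }
}
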