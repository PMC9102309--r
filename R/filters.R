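# Orthonormal scaling (low-pass analysis) filter coefficients, standard
# published tables. Normalization: sum(h) = sqrt(2), sum(h^2) = 1. The
# high-pass filter is derived by the quadrature-mirror rule
# g_k = (-1)^k h_{L-1-k}, and the synthesis pair is the time reverse of the
# analysis pair (orthonormal bank).
.wp_scaling_filters <- list(
  db1 = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(0.48296291314453416, 0.83651630373780794,
          0.22414386804201339, -0.12940952255126037),
  db3 = c(0.33267055295008263, 0.80689150931109255, 0.45987750211849154,
          -0.13501102001025458, -0.085441273882026658, 0.035226291885709533),
  sym4 = c(0.032223100604042702, -0.012603967262037833, -0.099219543576847216,
           0.29785779560527736, 0.80373875180591614, 0.49761866763201545,
           -0.029635527645998510, -0.075765714789273325),
  sym5 = c(0.019538882735286728, -0.021101834024758855, -0.17532808990845047,
           0.016602105764522319, 0.63397896345821192, 0.72340769040242059,
           0.19939753397739360, -0.039134249302383094,
           0.029519490925774643, 0.027333068345077982),
  sym6 = c(-0.0078007083250341480, 0.0017677118642428036, 0.044724901770665779,
           -0.021060292512300564, -0.072637522786462516, 0.33792942172762180,
           0.78764114103019400, 0.49105594192674662, -0.048311742585632998,
           -0.11799011114819057, 0.0034907120842174702, 0.015404109327027373),
  coif1 = c(-0.072732619512526450, 0.33789766245748182, 0.85257202021160039,
            0.38486484686485778, -0.072732619512526450, -0.015655728135791993),
  coif2 = c(0.016387336463203641, -0.041464936786871777, -0.067372554723725595,
            0.38611006682276289, 0.81272363544941351, 0.41700518442323908,
            -0.076488599078280761, -0.059434418646431092, 0.023680171946847770,
            0.0056114348193688343, -0.0018232088709110323,
            -0.00072054944552034698),
  coif3 = c(-0.0037935128643808019, 0.0077825964256727463, 0.023452696142077168,
            -0.065771911281469364, -0.061123390002972552, 0.40517690240911824,
            0.79377722262608719, 0.42848347637737000, -0.071799821619154838,
            -0.082301927106299827, 0.034555027573297738, 0.015880544863669452,
            -0.0090079761367306242, -0.0025745176881367972,
            0.0011175187708306303, 0.00046621695982040288,
            -0.000070983302506379004, -0.000034599773197272781),
  fk4 = c(0.65392755398862654125, 0.753272494420626390586,
          0.0531792271979209831506, -0.0461657132340788661847),
  fk6 = c(0.427915030995577316118, 0.812919644766451180875,
          0.356369509557614628189, -0.14643867881781067698,
          -0.0771777593666444199069, 0.0406258152379070205062),
  fk8 = c(0.349235407068826525971, 0.782683017852373819737,
          0.475267452407557511214, -0.0996795648217106622479,
          -0.159981599623402124468, 0.0431051098975844827358,
          0.0425855213335656116831, -0.0190017817417001158241)
)

#' Supported wavelet packet names
#'
#' @return Character vector of the 12 supported wavelet identifiers
#'   (Daubechies db1-db3, Symlet sym4-sym6, Coiflet coif1-coif3,
#'   Fejer-Korovkin fk4/fk6/fk8).
#' @export
wp_wavelets <- function() names(.wp_scaling_filters)

#' Wavelets admitted in the two-stage WPD-CCA method
#'
#' The two-stage method restricts the wavelet choice to the Daubechies and
#' Fejer-Korovkin families, which perform best in the single-stage method.
#' @return Character vector of 6 wavelet identifiers.
#' @export
wp_cca_wavelets <- function() c("db1", "db2", "db3", "fk4", "fk6", "fk8")

#' Construct an orthonormal analysis/synthesis filter bank
#'
#' Returns the low-pass (scaling) and high-pass (wavelet) analysis filters
#' for one of the supported wavelet packets, together with their synthesis
#' counterparts (time-reversed, as the bank is orthonormal). The
#' coefficients are validated at construction: `sum(h) = sqrt(2)`,
#' `sum(h^2) = sum(g^2) = 1`, the quadrature-mirror relation
#' `g_k = (-1)^k h_{L-1-k}`, `sum(g) = 0`, and double-shift orthogonality.
#'
#' @param name One of [wp_wavelets()].
#' @return An object of class `wp_filter_bank` with elements `name`, `h`,
#'   `g`, `h_syn`, `g_syn`.
#' @examples
#' wp_filter_bank("db1")$h  # c(1, 1) / sqrt(2)
#' @export
wp_filter_bank <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% names(.wp_scaling_filters)))
    stop("unknown wavelet '", paste(name, collapse = ","), "'; valid names: ",
         paste(names(.wp_scaling_filters), collapse = ", "), call. = FALSE)
  h <- .wp_scaling_filters[[name]]
  L <- length(h)
  k <- seq_len(L) - 1L
  g <- (-1)^k * h[L - k]
  tol <- 1e-10
  stopifnot(
    abs(sum(h) - sqrt(2)) < tol,
    abs(sum(h^2) - 1) < tol,
    abs(sum(g^2) - 1) < tol,
    abs(sum(g)) < tol
  )
  for (m in seq_len(L / 2 - 1)) {
    if (abs(sum(h[seq_len(L - 2 * m)] * h[seq_len(L - 2 * m) + 2 * m])) >= tol)
      stop("filter table for '", name, "' violates double-shift orthogonality",
           call. = FALSE)
  }
  structure(
    list(name = name, h = h, g = g, h_syn = rev(h), g_syn = rev(g)),
    class = "wp_filter_bank"
  )
}

#' @export
print.wp_filter_bank <- function(x, ...) {
  cat(sprintf("<wp_filter_bank> %s (%d taps)\n", x$name, length(x$h)))
  invisible(x)
}
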