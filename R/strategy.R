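#' Define a shade-avoidance plasticity strategy
#'
#' A strategy is the heritable trait under selection: the curvature
#' `alpha` of the response curve mapping locally perceived R:FR to a
#' relative organ growth factor, together with the exponent `n_exponent`
#' that sets the strength of the lamina sink down-regulation relative to
#' petiole elongation, and the reference (control) R:FR at which the curve
#' equals 1.
#'
#' @param alpha Dimensionless curvature of the response curve. The canonical
#'   grid is 0 to 0.7 in steps of 0.1, but any finite value is accepted.
#' @param n_exponent Dimensionless lamina-response strength (>= 0). The
#'   scenarios are Average `n = 2`, Weak `n = 1`, Strong `n = 4`.
#' @param rfr_control Reference R:FR of the unshaded light source (> 0),
#'   default 2.3.
#' @return An object of class `plasticity_strategy`.
#' @examples
#' s <- plasticity_strategy(0.5)
#' response_factor(1.15, s)
#' @export
plasticity_strategy <- function(alpha, n_exponent = 2, rfr_control = 2.3) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (!is.finite(n_exponent) || n_exponent < 0)
    stop("n_exponent must be finite and >= 0")
  if (!is.finite(rfr_control) || rfr_control <= 0)
    stop("rfr_control must be > 0")
  structure(list(alpha = alpha, n_exponent = n_exponent,
                 rfr_control = rfr_control),
            class = "plasticity_strategy")
}

#' @export
print.plasticity_strategy <- function(x, ...) {
  cat(sprintf(
    "<plasticity_strategy> alpha = %g, n = %g, control R:FR = %g\n",
    x$alpha, x$n_exponent, x$rfr_control))
  invisible(x)
}

#' Relative organ growth factor from perceived R:FR
#'
#' The plastic response curve: `F = min(2, (rfr / rfr_control)^(-alpha))`.
#' `F` is 1 for a non-plastic strategy (`alpha = 0`) or at the control R:FR,
#' rises as perceived R:FR falls below the control, and is capped at 2 so an
#' organ can at most double its own size within one day.
#'
#' @param rfr Perceived R:FR ratio (> 0); vectorised.
#' @param strategy A [plasticity_strategy], or a bare numeric `alpha`.
#' @param cap Upper bound on `F` (default 2).
#' @return The response factor(s) `F`, in `(0, cap]`.
#' @export
response_factor <- function(rfr, strategy, cap = 2) {
  if (is.numeric(strategy)) strategy <- plasticity_strategy(strategy)
  if (any(!is.finite(rfr)) || any(rfr <= 0))
    stop("rfr must be finite and > 0")
  pmin(cap, (rfr / strategy$rfr_control)^(-strategy$alpha))
}

#' Down-regulated lamina carbon demand
#'
#' `D = D_p / F^n`: the actual lamina demand after the shade signal scales
#' the potential (beta-growth) demand down by the response factor raised to
#' the scenario exponent. With `n = 0` the lamina response is disabled and
#' only petioles respond.
#'
#' @param d_p Potential lamina carbon demand (mg / day, >= 0); vectorised.
#' @param f Response factor from [response_factor()] (> 0).
#' @param n Scenario exponent (>= 0).
#' @return Actual demand (mg / day).
#' @export
lamina_demand <- function(d_p, f, n) {
  stopifnot(all(d_p >= 0), all(f > 0), length(n) == 1L, n >= 0)
  d_p / f^n
}
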