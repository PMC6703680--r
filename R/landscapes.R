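# Synthetic fitness landscapes: performance matrices with analytically
# known adaptive-dynamics structure, so the whole game-analysis pipeline can
# be validated without running a single stand simulation.

#' Specify a synthetic quadratic fitness landscape
#'
#' The minimal family spanning all four singular-strategy classes with
#' independent knobs:
#' `s(m, r) = k * (a_star - r) * (m - r) - h * (m - r)^2`.
#' The selection gradient is `k * (a_star - r)` (so `a_star` is the unique
#' singular strategy), the ESS curvature is `-2h` and the convergence slope
#' is `-k`: `k > 0, h > 0` gives a cESS, `k > 0, h < 0` a branching point,
#' `k < 0, h > 0` an ESS that is not an attractor, `k < 0, h < 0` a
#' repeller. This family is test scaffolding — no claim is made that the
#' stand simulator's true fitness surface is quadratic.
#'
#' @param a_star Target singular strategy (inside the grid range).
#' @param k Convergence coefficient.
#' @param h ESS curvature coefficient.
#' @param baseline Resident performance (mg, > 0).
#' @param replicate_cv Log-normal coefficient of variation of replicate
#'   noise (>= 0); 0.1 matches the replicate scatter of desk-preset stand
#'   simulations.
#' @param grid Strategy grid (default 0 to 0.7 by 0.1).
#' @param replicates Replicates per cell (default 20).
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(a_star, k = 1, h = 1, baseline = 1000,
                           replicate_cv = 0.1,
                           grid = seq(0, 0.7, by = 0.1), replicates = 20) {
  stopifnot(baseline > 0, replicate_cv >= 0, length(grid) >= 2)
  structure(list(a_star = a_star, k = k, h = h, baseline = baseline,
                 replicate_cv = replicate_cv, grid = grid,
                 replicates = as.integer(replicates)),
            class = "landscape_spec")
}

#' Closed-form invasion fitness of a synthetic landscape
#'
#' @param spec A [landscape_spec()].
#' @param m,r Mutant and resident strategies (vectorised).
#' @return `s(m, r)`.
#' @export
landscape_truth <- function(spec, m, r) {
  spec$k * (spec$a_star - r) * (m - r) - spec$h * (m - r)^2
}

#' Generate a performance matrix from a synthetic landscape
#'
#' Resident performance is `baseline`; a mutant replicate draws
#' `baseline * exp(s(m, r))` times multiplicative log-normal noise with
#' coefficient of variation `replicate_cv`. Diagonal cells reuse the
#' resident draws (mutant and resident are the same plants), so the
#' estimated diagonal exponent is exactly zero.
#'
#' @param spec A [landscape_spec()].
#' @return A [performance_matrix()].
#' @export
generate_matrix <- function(spec) {
  g <- spec$grid
  kk <- length(g)
  nrep <- spec$replicates
  sigma <- sqrt(log(1 + spec$replicate_cv^2))
  reps <- array(NA_real_, c(kk, kk, nrep))
  for (r in seq_len(kk)) {
    res_draws <- spec$baseline * exp(rnorm(nrep, 0, sigma))
    for (m in seq_len(kk)) {
      if (m == r) {
        reps[m, r, ] <- res_draws
      } else {
        s <- landscape_truth(spec, g[m], g[r])
        reps[m, r, ] <- spec$baseline * exp(s) * exp(rnorm(nrep, 0, sigma))
      }
    }
  }
  performance_matrix(reps, g)
}

#' Analytic classification of a synthetic landscape
#'
#' @param spec A [landscape_spec()].
#' @return Character: the class the pipeline should recover.
#' @export
landscape_classification <- function(spec) {
  if (spec$h == 0 || spec$k == 0) return("indeterminate")
  if (spec$k > 0 && spec$h > 0) "cESS"
  else if (spec$k > 0 && spec$h < 0) "branching"
  else if (spec$k < 0 && spec$h > 0) "ESS-not-convergent"
  else "repeller"
}
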