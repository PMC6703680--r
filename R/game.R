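# Adaptive dynamics on performance matrices: discrete and smoothed pairwise
# invasibility plots, isoclines, singular strategies and their
# classification.

#' Performance matrix over a strategy grid
#'
#' Per-cell replicate performances of a mutant strategy (rows) invading a
#' resident strategy (columns), for one (density, scenario).
#'
#' @param reps 3-D array `[mutant, resident, replicate]` of focal-plant
#'   biomass (mg).
#' @param strategies Strategy grid.
#' @param density,scenario_n Design coordinates (metadata).
#' @return An object of class `performance_matrix` with `mean`, `sd`,
#'   `reps`, `strategies`, `n`.
#' @export
performance_matrix <- function(reps, strategies, density = NA,
                               scenario_n = NA) {
  stopifnot(length(dim(reps)) == 3,
            dim(reps)[1] == length(strategies),
            dim(reps)[2] == length(strategies))
  structure(list(
    strategies = strategies,
    reps = reps,
    mean = apply(reps, c(1, 2), mean, na.rm = TRUE),
    sd = apply(reps, c(1, 2), sd, na.rm = TRUE),
    n = dim(reps)[3], density = density, scenario_n = scenario_n),
    class = "performance_matrix")
}

performance_matrix_from_runs <- function(runs, strategies, density,
                                         scenario_n) {
  nrep <- max(runs$replicate)
  reps <- array(NA_real_, c(length(strategies), length(strategies), nrep))
  for (i in seq_along(strategies)) for (j in seq_along(strategies)) {
    v <- runs$focal_biomass_mg[
      abs(runs$mutant_alpha - strategies[i]) < 1e-9 &
        abs(runs$resident_alpha - strategies[j]) < 1e-9]
    reps[i, j, seq_along(v)] <- v
  }
  performance_matrix(reps, strategies, density, scenario_n)
}

#' @export
print.performance_matrix <- function(x, ...) {
  cat(sprintf("<performance_matrix> %d x %d strategies, %d replicates\n",
              length(x$strategies), length(x$strategies), x$n))
  print(round(x$mean, 1))
  invisible(x)
}

#' Discrete invasion-exponent matrix
#'
#' Cell (m, r) is `log(mean(mutant m in resident r) / mean(resident r in
#' resident r))` (natural log): positive values mean the mutant can invade.
#' The diagonal is zero by construction and forced exactly. Cells with a
#' non-positive mean are flagged undefined (`NA`). Per-cell confidence
#' intervals follow [invasion_ci()].
#'
#' @param pm A [performance_matrix()].
#' @return An object of class `invasion_matrix`: `exponent`, `ci_lo`,
#'   `ci_hi`, `includes_zero`, `strategies`, `n`.
#' @export
invasion_exponent <- function(pm) {
  k <- length(pm$strategies)
  ex <- matrix(NA_real_, k, k)
  lo <- hi <- matrix(NA_real_, k, k)
  inc0 <- matrix(NA, k, k)
  for (r in seq_len(k)) {
    res_mean <- pm$mean[r, r]
    for (m in seq_len(k)) {
      mu <- pm$mean[m, r]
      if (is.finite(mu) && is.finite(res_mean) && mu > 0 && res_mean > 0) {
        ex[m, r] <- log(mu / res_mean)
        reps <- pm$reps[m, r, ]
        reps <- reps[is.finite(reps)]
        if (length(reps) >= 2) {
          ci <- invasion_ci(reps, res_mean)
          lo[m, r] <- ci[1]; hi[m, r] <- ci[2]
          inc0[m, r] <- ci[1] <= 0 && ci[2] >= 0
        }
      }
    }
    ex[r, r] <- 0
  }
  structure(list(exponent = ex, ci_lo = lo, ci_hi = hi,
                 includes_zero = inc0, strategies = pm$strategies,
                 n = pm$n, density = pm$density, scenario_n = pm$scenario_n),
            class = "invasion_matrix")
}

#' Replicate-based confidence interval of an invasion exponent
#'
#' Per replicate `x_i = log(perf_i / resident_mean)`; the interval is
#' `mean(x) +/- sd(x) / sqrt(n - 1)`. Cells whose interval includes zero
#' are inconclusive.
#'
#' @param mutant_reps Replicate performances of the mutant (n >= 2).
#' @param resident_mean Mean resident performance (> 0).
#' @return `c(lo, hi)`.
#' @export
invasion_ci <- function(mutant_reps, resident_mean) {
  n <- length(mutant_reps)
  if (n < 2) stop("need at least 2 replicates")
  stopifnot(resident_mean > 0, all(mutant_reps > 0))
  x <- log(mutant_reps / resident_mean)
  half <- sd(x) / sqrt(n - 1)
  c(mean(x) - half, mean(x) + half)
}

#' Smooth a performance matrix into a continuous invasion surface
#'
#' Fits a tensor-product penalized P-spline (a generalized additive model)
#' to log performance over the (mutant, resident) grid — all replicates
#' when available, so the penalty is chosen against the true replicate
#' scatter — and forms the smoothed invasion surface
#' `s(m, r) = log(w(m, r) / w(r, r))` from the fitted performance:
#' smoothing performance first and taking the log ratio afterwards. The
#' diagonal is zero by construction. The log scale matches the positive,
#' multiplicatively noisy biomass data.
#'
#' @param pm A [performance_matrix()] on at least a 4x4 grid.
#' @param k Basis dimension per margin (default: grid size capped at 8).
#' @return An object of class `smoothed_pip`: `surface(m, r)` (vectorised
#'   closure), `s(m, r)` (invasion surface closure), `fit` (the mgcv fit),
#'   `strategies`, `range`.
#' @export
smooth_performance <- function(pm, k = NULL) {
  g <- pm$strategies
  if (length(g) < 4) stop("need at least a 4x4 strategy grid")
  if (is.null(k)) k <- min(length(g), 8)
  if (is.null(pm$reps)) {
    dat <- expand.grid(m = g, r = g)
    dat$w <- as.vector(pm$mean)
  } else {
    dat <- do.call(rbind, lapply(seq_len(dim(pm$reps)[3]), function(i) {
      d <- expand.grid(m = g, r = g)
      d$w <- as.vector(pm$reps[, , i])
      d
    }))
  }
  dat <- dat[is.finite(dat$w) & dat$w > 0, ]
  if (sd(log(dat$w)) < 1e-12) {
    # degenerate flat surface: REML has nothing to estimate
    const <- mean(log(dat$w))
    fit <- NULL
    eta <- function(m, r) rep(const, max(length(m), length(r)))
  } else {
    fit <- mgcv::gam(log(w) ~ te(m, r, k = c(k, k), bs = "ps"), data = dat,
                     method = "REML", gamma = 1.4)
    eta <- function(m, r) {
      as.numeric(predict(fit, newdata = data.frame(m = m, r = r)))
    }
  }
  wfun <- function(m, r) exp(eta(m, r))
  sfun <- function(m, r) {
    n <- max(length(m), length(r))
    m <- rep_len(m, n); r <- rep_len(r, n)
    eta(m, r) - eta(r, r)
  }
  structure(list(surface = wfun, s = sfun, fit = fit, strategies = g,
                 range = range(g), density = pm$density,
                 scenario_n = pm$scenario_n),
            class = "smoothed_pip")
}

#' Local selection gradient of a smoothed PIP
#'
#' `g(r) = ds/dm` at `m = r`, by central finite differences with step
#' `h` (default 1/200 of the strategy range).
#'
#' @param pip A [smooth_performance()] result.
#' @param r Resident strategies (vectorised).
#' @param h Finite-difference step.
#' @return Gradient values.
#' @export
selection_gradient <- function(pip, r, h = diff(pip$range) / 200) {
  (pip$s(r + h, r) - pip$s(r - h, r)) / (2 * h)
}

#' Locate singular strategies on a smoothed PIP
#'
#' Scans the selection gradient on a fine mesh inside the analysed range,
#' brackets sign changes and refines each root by bisection. No
#' extrapolation: when the gradient keeps one sign over the whole range the
#' verdict is that any singular strategy lies beyond the tested values (in
#' the direction of the gradient's sign).
#'
#' @param pip A [smooth_performance()] result.
#' @param mesh_n Mesh size (default 201).
#' @param tol Bisection tolerance on the strategy axis.
#' @return A list: `roots` (numeric, possibly empty), `verdict` one of
#'   `"roots-found"`, `"beyond-range-high"`, `"beyond-range-low"`,
#'   `"degenerate"`, and `gradient` (mesh values, for diagnostics).
#' @export
find_singular_strategies <- function(pip, mesh_n = 201, tol = 1e-5) {
  h <- diff(pip$range) / 200
  lo <- pip$range[1] + h; hi <- pip$range[2] - h
  mesh <- seq(lo, hi, length.out = mesh_n)
  gv <- selection_gradient(pip, mesh, h)
  if (all(abs(gv) < 1e-12))
    return(list(roots = numeric(), verdict = "degenerate", gradient = gv))
  roots <- numeric()
  sign_change <- which(gv[-1] * gv[-mesh_n] < 0)
  for (i in sign_change) {
    a <- mesh[i]; b <- mesh[i + 1]
    fa <- gv[i]
    while (b - a > tol) {
      mid <- (a + b) / 2
      fm <- selection_gradient(pip, mid, h)
      if (is.na(fm)) break
      if (fa * fm <= 0) b <- mid else { a <- mid; fa <- fm }
    }
    roots <- c(roots, (a + b) / 2)
  }
  # exact zeros on the mesh
  roots <- sort(unique(c(roots, mesh[gv == 0])))
  verdict <- if (length(roots)) "roots-found"
  else if (all(gv > 0, na.rm = TRUE)) "beyond-range-high"
  else if (all(gv < 0, na.rm = TRUE)) "beyond-range-low"
  else "degenerate"
  list(roots = roots, verdict = verdict, gradient = gv)
}

#' Classify a singular strategy
#'
#' Standard adaptive-dynamics second-order conditions, estimated by finite
#' differences on the smoothed surface: evolutionary stability requires
#' `d2s/dm2 < 0` at `(a*, a*)`; convergence stability requires
#' `dg/dr < 0` at `a*`. Both give a convergence-stable ESS (cESS); the
#' other sign combinations give a branching point (convergent, invasible),
#' an ESS that is not an attractor (garden of Eden) or a repeller.
#' Estimates whose magnitude falls below the indeterminacy tolerance give
#' the verdict `"indeterminate"` — the complex-PIP outcome.
#'
#' @param pip A [smooth_performance()] result.
#' @param a_star Singular strategy from [find_singular_strategies()].
#' @param h Finite-difference step (default 1/200 of the range).
#' @param tol Absolute indeterminacy tolerance on the two second
#'   derivatives. When `boot_se` is supplied (per-derivative bootstrap
#'   standard errors over replicates), the tolerance becomes
#'   `max(tol, 2 * boot_se)`.
#' @param boot_se Optional length-2 numeric `(se_ess, se_conv)`.
#' @return An object of class `singular_strategy`: `value`,
#'   `classification` in `c("cESS", "branching", "ESS-not-convergent",
#'   "repeller", "indeterminate")`, `ess_curvature` (d2s/dm2),
#'   `convergence_slope` (dg/dr).
#' @export
classify_singular <- function(pip, a_star, h = diff(pip$range) / 200,
                              tol = 1e-10, boot_se = NULL) {
  if (a_star <= pip$range[1] + h || a_star >= pip$range[2] - h)
    stop("singular strategy on the boundary of the analysed range; ",
         "classification refused")
  # d2s/dm2 at m = r = a*; s(a*, a*) = 0 by construction
  e2 <- (pip$s(a_star + h, a_star) + pip$s(a_star - h, a_star)) / h^2
  cg <- (selection_gradient(pip, a_star + h, h) -
           selection_gradient(pip, a_star - h, h)) / (2 * h)
  tol_e <- tol; tol_c <- tol
  if (!is.null(boot_se)) {
    tol_e <- max(tol, 2 * boot_se[1])
    tol_c <- max(tol, 2 * boot_se[2])
  }
  cls <- if (abs(e2) < tol_e || abs(cg) < tol_c) "indeterminate"
  else if (e2 < 0 && cg < 0) "cESS"
  else if (e2 > 0 && cg < 0) "branching"
  else if (e2 < 0 && cg > 0) "ESS-not-convergent"
  else "repeller"
  structure(list(value = a_star, classification = cls, ess_curvature = e2,
                 convergence_slope = cg),
            class = "singular_strategy")
}

#' @export
print.singular_strategy <- function(x, ...) {
  cat(sprintf("<singular_strategy> a* = %.4f: %s (d2s/dm2 = %.3g, dg/dr = %.3g)\n",
              x$value, x$classification, x$ess_curvature,
              x$convergence_slope))
  invisible(x)
}

#' Bootstrap standard errors of the classification derivatives
#'
#' Resamples replicates within every matrix cell, recomputes cell means,
#' refits the smoother and re-estimates the two second derivatives at
#' `a_star`.
#'
#' @param pm A [performance_matrix()].
#' @param a_star Singular strategy.
#' @param B Bootstrap draws.
#' @param k Basis dimension passed to [smooth_performance()].
#' @return `c(se_ess, se_conv)`.
#' @export
bootstrap_derivative_se <- function(pm, a_star, B = 40, k = NULL) {
  h <- diff(range(pm$strategies)) / 200
  est <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    idx <- sample.int(pm$n, pm$n, replace = TRUE)
    pmb <- performance_matrix(pm$reps[, , idx, drop = FALSE],
                              pm$strategies, pm$density, pm$scenario_n)
    pb <- try(smooth_performance(pmb, k), silent = TRUE)
    if (inherits(pb, "try-error")) next
    est[b, 1] <- (pb$s(a_star + h, a_star) + pb$s(a_star - h, a_star)) / h^2
    est[b, 2] <- (selection_gradient(pb, a_star + h, h) -
                    selection_gradient(pb, a_star - h, h)) / (2 * h)
  }
  apply(est, 2, sd, na.rm = TRUE)
}

#' Full PIP analysis of one performance matrix
#'
#' Convenience wrapper: discrete exponents, smoothed surface, singular
#' strategies and their classification.
#'
#' @param pm A [performance_matrix()].
#' @param k Basis dimension for the smoother.
#' @param boot Bootstrap draws for indeterminacy tolerances (0 = off).
#' @return A list: `discrete`, `smoothed`, `singular` (list of
#'   `singular_strategy`), `verdict`.
#' @export
analyse_pip <- function(pm, k = NULL, boot = 0) {
  disc <- invasion_exponent(pm)
  sm <- smooth_performance(pm, k)
  ss <- find_singular_strategies(sm)
  sing <- lapply(ss$roots, function(a) {
    se <- if (boot > 0) bootstrap_derivative_se(pm, a, boot, k) else NULL
    tryCatch(classify_singular(sm, a, boot_se = se),
             error = function(e) structure(
               list(value = a, classification = "indeterminate",
                    ess_curvature = NA_real_, convergence_slope = NA_real_),
               class = "singular_strategy"))
  })
  list(discrete = disc, smoothed = sm, singular = sing,
       verdict = ss$verdict)
}

#' Export a PIP analysis as CSV (and optionally plots)
#'
#' Writes the discrete cell table (exponent, CI, zero-inclusion flag) and a
#' smoothed-surface grid; with `plot = TRUE` also writes PNG panels using
#' a diverging red-blue palette centred on zero with the identity line
#' drawn.
#'
#' @param discrete An [invasion_exponent()] result.
#' @param smoothed A [smooth_performance()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param grid_n Resolution of the smoothed-surface grid.
#' @param plot Also write PNG figures.
#' @return Invisibly, the paths written.
#' @export
pip_export <- function(discrete, smoothed = NULL, dir = ".",
                       prefix = "pip", grid_n = 81, plot = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- discrete$strategies
  cells <- expand.grid(mutant = g, resident = g)
  cells$exponent <- as.vector(discrete$exponent)
  cells$ci_lo <- as.vector(discrete$ci_lo)
  cells$ci_hi <- as.vector(discrete$ci_hi)
  cells$includes_zero <- as.vector(discrete$includes_zero)
  p1 <- file.path(dir, paste0(prefix, "_discrete.csv"))
  write.csv(cells, p1, row.names = FALSE)
  paths <- p1
  if (!is.null(smoothed)) {
    gg <- seq(min(g), max(g), length.out = grid_n)
    surf <- expand.grid(mutant = gg, resident = gg)
    surf$s <- smoothed$s(surf$mutant, surf$resident)
    p2 <- file.path(dir, paste0(prefix, "_smoothed.csv"))
    write.csv(surf, p2, row.names = FALSE)
    paths <- c(paths, p2)
  }
  if (plot) {
    p3 <- file.path(dir, paste0(prefix, ".png"))
    grDevices::png(p3, width = if (is.null(smoothed)) 600 else 1200,
                   height = 600)
    print(plot_pip(discrete, smoothed))
    grDevices::dev.off()
    paths <- c(paths, p3)
  }
  invisible(paths)
}
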