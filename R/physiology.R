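# Carbon physiology: beta-growth sink demands, photosynthesis, the central
# pool, relative-sink-strength allocation, and the carbon side of the
# petiole and lamina plastic responses.

check_beta_params <- function(w_max, t_e, t_m) {
  if (any(w_max <= 0) || any(t_e <= 0) || any(t_m <= 0) || any(t_m >= t_e))
    stop("beta growth requires w_max > 0 and 0 < t_m < t_e")
}

#' Determinate organ growth: the beta growth function
#'
#' Expected organ mass at age `t`:
#' `W(t) = W_max * (1 + (t_e - t)/(t_e - t_m)) * (t/t_e)^(t_e/(t_e - t_m))`
#' for `0 <= t <= t_e`, and `W_max` beyond. Its derivative (the potential
#' growth rate) peaks at the inflection age `t_m` and defines the organ's
#' sink strength.
#'
#' @param t Organ age in days (>= 0); vectorised.
#' @param w_max Final organ mass (mg).
#' @param t_e Growth duration (days).
#' @param t_m Inflection age (days), `0 < t_m < t_e`.
#' @return Mass in mg (`beta_growth_mass`) or growth rate in mg/day
#'   (`beta_growth_rate`, zero outside `(0, t_e)`).
#' @export
beta_growth_mass <- function(t, w_max, t_e, t_m) {
  check_beta_params(w_max, t_e, t_m)
  if (any(t < 0)) stop("t must be >= 0")
  tt <- pmin(t, t_e)
  ex <- t_e / (t_e - t_m)
  w_max * (1 + (t_e - tt) / (t_e - t_m)) * (tt / t_e)^ex
}

#' @rdname beta_growth_mass
#' @export
beta_growth_rate <- function(t, w_max, t_e, t_m) {
  check_beta_params(w_max, t_e, t_m)
  if (any(t < 0)) stop("t must be >= 0")
  ex <- t_e / (t_e - t_m)
  inside <- t > 0 & t < t_e
  r <- numeric(length(t))
  tt <- t[inside]
  # d/dt [ (1 + (t_e - t)/(t_e - t_m)) * (t/t_e)^ex ]
  r[inside] <- w_max * (
    -(tt / t_e)^ex / (t_e - t_m) +
      (1 + (t_e - tt) / (t_e - t_m)) * ex * tt^(ex - 1) / t_e^ex)
  r
}

#' Daily assimilation of one lamina
#'
#' Negative-exponential light response:
#' `A = p_max * (1 - exp(-phi * I / p_max))` (umol CO2 m-2 s-1), scaled by
#' lamina area, photoperiod seconds and the carbon-to-biomass conversion.
#'
#' @param absorbed_par Absorbed PAR flux on the lamina (umol m-2 s-1).
#' @param lamina_area Lamina area (m2).
#' @param params [default_params()] list (`p_max`, `phi`,
#'   `carbon_conversion`).
#' @param photoperiod Hours of light per day.
#' @return Assimilate in mg biomass per day; vectorised.
#' @export
photosynthesis <- function(absorbed_par, lamina_area,
                           params = default_params(), photoperiod = 9) {
  stopifnot(all(absorbed_par >= 0), all(lamina_area >= 0), photoperiod >= 0)
  a <- params$p_max * (1 - exp(-params$phi * absorbed_par / params$p_max))
  a * lamina_area * photoperiod * 3600 * params$carbon_conversion
}

#' Relative sink strength carbon allocation
#'
#' If the pool is short of total demand, every sink receives
#' `pool * D_i / sum(D)` (its relative sink strength share). If the pool
#' covers all demands, each sink receives its demand and the surplus is
#' split: `surplus_root_fraction` to the root, the rest over laminas pro
#' rata by their demand (or all surplus to the root when no lamina is
#' growing). The allocations always sum to the pool exactly.
#'
#' @param pool Available carbon (mg, >= 0).
#' @param demands Per-sink demands (mg/day, >= 0).
#' @param is_lamina Logical per sink, marking lamina sinks for the surplus
#'   split; the root sink is identified by `root_index`.
#' @param root_index Index of the root sink within `demands`.
#' @param surplus_root_fraction Share of surplus sent to the root.
#' @return Numeric vector of allocations, same length as `demands`.
#' @export
allocate <- function(pool, demands, is_lamina = NULL, root_index = NULL,
                     surplus_root_fraction = 0.5) {
  stopifnot(pool >= 0, all(demands >= 0))
  n <- length(demands)
  alloc <- numeric(n)
  total <- sum(demands)
  if (pool <= 0) return(alloc)
  if (total <= 0) {
    if (!is.null(root_index)) alloc[root_index] <- pool
    return(alloc)
  }
  if (pool < total) {
    alloc <- pool * demands / total
  } else {
    alloc <- demands
    surplus <- pool - total
    lam <- if (is.null(is_lamina)) rep(FALSE, n) else is_lamina
    lam_d <- sum(demands[lam])
    if (lam_d > 0 && !is.null(root_index)) {
      alloc[root_index] <- alloc[root_index] + surplus_root_fraction * surplus
      alloc[lam] <- alloc[lam] +
        (1 - surplus_root_fraction) * surplus * demands[lam] / lam_d
    } else if (!is.null(root_index)) {
      alloc[root_index] <- alloc[root_index] + surplus
    } else if (lam_d > 0) {
      alloc[lam] <- alloc[lam] + surplus * demands[lam] / lam_d
    } else {
      alloc <- alloc + surplus * demands / total
    }
  }
  alloc
}

#' Petiole elongation response
#'
#' Multiplies the petiole length of growing petioles by their response
#' factor `F` (applied after the day's sink-strength growth) and queues the
#' carbon cost of the added length, `(F - 1) * old_length *
#' petiole_density`, as extra sink demand for the next day. The length
#' change is not rolled back if that payment is later rationed.
#'
#' @param leaves Leaf data frame.
#' @param f Per-leaf response factor from the petiole's perceived R:FR.
#' @param params [default_params()] list.
#' @return Updated leaf data frame (`petiole_length`,
#'   `petiole_extra_demand`).
#' @export
apply_petiole_plasticity <- function(leaves, f, params = default_params()) {
  act <- leaves$petiole_growing & !leaves$senesced & is.finite(f)
  old <- leaves$petiole_length[act]
  leaves$petiole_length[act] <- old * f[act]
  leaves$petiole_extra_demand[act] <- leaves$petiole_extra_demand[act] +
    (f[act] - 1) * old * params$petiole_density
  leaves
}

#' Convert allocated carbon into organ dimensions
#'
#' Lamina area grows by `allocated * sla`; petiole length grows by the part
#' of its allocation that pays for new sink-strength growth (not the
#' queued elongation debt) divided by the linear density. Biomasses grow by
#' the full allocations.
#'
#' @param leaves Leaf data frame.
#' @param alloc_lamina,alloc_petiole Per-leaf allocations (mg).
#' @param petiole_growth_fraction Fraction of each petiole allocation that
#'   is new growth rather than elongation-debt repayment.
#' @param params [default_params()] list.
#' @return Updated leaf data frame.
#' @export
dimension_update <- function(leaves, alloc_lamina, alloc_petiole,
                             petiole_growth_fraction = 1,
                             params = default_params()) {
  stopifnot(all(alloc_lamina >= 0), all(alloc_petiole >= 0))
  leaves$lamina_biomass <- leaves$lamina_biomass + alloc_lamina
  leaves$lamina_area <- leaves$lamina_area + alloc_lamina * params$sla
  leaves$petiole_biomass <- leaves$petiole_biomass + alloc_petiole
  leaves$petiole_length <- leaves$petiole_length +
    alloc_petiole * petiole_growth_fraction / params$petiole_density
  leaves
}

#' Percentage of whole-plant biomass in a compartment
#'
#' Whole-plant biomass is petioles + laminas + the single root (senesced
#' organs included: biomass is never shed).
#'
#' @param compartment One of `"petiole"`, `"lamina"`, `"root"`.
#' @param petiole_biomass,lamina_biomass Per-leaf biomasses (mg).
#' @param root_biomass Root biomass (mg).
#' @return Percentage (0-100), or `NA` for a zero-biomass plant.
#' @export
percent_biomass_in <- function(compartment = c("petiole", "lamina", "root"),
                               petiole_biomass, lamina_biomass,
                               root_biomass) {
  compartment <- match.arg(compartment)
  tot <- sum(petiole_biomass) + sum(lamina_biomass) + root_biomass
  if (tot <= 0) return(NA_real_)
  part <- switch(compartment,
                 petiole = sum(petiole_biomass),
                 lamina = sum(lamina_biomass),
                 root = root_biomass)
  100 * part / tot
}
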