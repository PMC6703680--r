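# Stand simulation: the 46-day daily loop coupling architecture, light and
# carbon physiology, plus the mutant-in-resident experiment designs.

#' Configuration of one stand run
#'
#' One canopy: a resident population with strategy `resident_alpha` filling
#' a regular grid, and the focal centre plant carrying `mutant_alpha` (equal
#' values give a monomorphic stand). Performance is read from the focal
#' plant only, emulating a rare invader in a large population while
#' avoiding edge effects (the tile wraps toroidally).
#'
#' @param density Plants per m2.
#' @param resident_alpha,mutant_alpha Plasticity strategies.
#' @param scenario_n Lamina-response exponent: 2 Average, 1 Weak, 4 Strong.
#' @param days Run length in days (default 46).
#' @param rows,cols Stand dimensions (odd, default 7x7).
#' @param seed Integer seed; every source of randomness in the run (initial
#'   leaf azimuths, Monte Carlo rays) derives from it.
#' @param params [default_params()] list.
#' @param source [light_source()].
#' @param light_dump `"none"`, `"focal"` or `"all"`: collect per-organ
#'   daily light records (day, plant, rank, absorbed PAR, lamina and
#'   petiole R:FR) for diagnostics such as the cue-reliability query.
#' @return A list of class `stand_config`.
#' @export
stand_config <- function(density, resident_alpha, mutant_alpha = resident_alpha,
                         scenario_n = 2, days = 46, rows = 7, cols = 7,
                         seed = 1, params = default_params(),
                         source = light_source(),
                         light_dump = c("none", "focal", "all")) {
  stopifnot(days >= 1)
  structure(list(density = density, resident_alpha = resident_alpha,
                 mutant_alpha = mutant_alpha, scenario_n = scenario_n,
                 days = as.integer(days), rows = rows, cols = cols,
                 seed = as.integer(seed), params = params, source = source,
                 light_dump = match.arg(light_dump)),
            class = "stand_config")
}

#' Deterministic seed for one cell of the experiment design
#'
#' A stable 31-bit linear congruential fold of the base seed and the design
#' coordinates, so any single run of a large design can be reproduced in
#' isolation.
#'
#' @param seed_base Integer base seed.
#' @param ... Numeric design coordinates (density, scenario, strategies,
#'   replicate); folded in order after scaling to integers.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed_base, ...) {
  m <- 2147483647
  h <- abs(seed_base) %% m
  for (k in vapply(list(...), as.numeric, 1)) {
    h <- (h * 69069 + (round(k * 1000) %% m)) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

first_leaf_day <- function(params) {
  ceiling(params$germination_day + params$plastochron)
}

#' Simulate one stand
#'
#' Runs the daily loop: (1) organ initiation, (2) canopy light
#' computation, (3) photosynthesis into each plant's carbon pool (plus the
#' seed reserve in the establishment phase), (4) response factors from each
#' organ's perceived R:FR, (5) sink-demand assembly (beta-growth increments,
#' lamina down-regulation, queued petiole elongation debt, root sink) and
#' relative-sink-strength allocation, (6) dimension updates, (7) petiole
#' elongation with next-day extra demand, (8) hyponastic angle update,
#' (9) senescence. Deterministic for a fixed seed.
#'
#' @param config A [stand_config()].
#' @return A list of class `stand_result`: `performance` (focal plant total
#'   biomass, mg, at the final day), `trajectory` (per-day focal-plant
#'   series: mean perceived R:FR, biomass, percent petiole / lamina, LAI,
#'   mean leaf angle, daily carbon input), `audit` (per-day light energy
#'   closure), `leaves`, `plants`, `seed`, `config`, and `light_dump` when
#'   requested.
#' @export
simulate_stand <- function(config) {
  p <- config$params
  src <- config$source
  layout <- stand_layout(config$density, config$rows, config$cols)
  pos <- grid_positions(layout)
  focal <- attr(pos, "focal")
  n_plants <- nrow(pos)

  set.seed(config$seed)
  plants <- data.frame(
    plant = seq_len(n_plants), x = pos[, 1], y = pos[, 2],
    alpha = ifelse(seq_len(n_plants) == focal,
                   config$mutant_alpha, config$resident_alpha),
    base_azimuth = runif(n_plants, 0, 360),
    root_biomass = p$root_init_mg,
    is_focal = seq_len(n_plants) == focal)
  leaves <- leaf_columns()

  traj <- data.frame(day = seq_len(config$days), mean_rfr = NA_real_,
                     stand_mean_rfr = NA_real_,
                     biomass = NA_real_, pct_petiole = NA_real_,
                     pct_lamina = NA_real_, lai = NA_real_,
                     mean_angle = NA_real_, carbon_input = NA_real_)
  audits <- vector("list", config$days)
  dumps <- if (config$light_dump == "none") NULL else vector("list", config$days)
  reserve_start <- first_leaf_day(p)

  for (day in seq_len(config$days)) {
    n_before <- sum(leaves$plant == focal)
    leaves <- initiate_organs(leaves, plants, day, p)
    if (nrow(leaves)) leaves$age <- day - leaves$emergence_day
    # seed-scale initial organ masses enter the books as that day's input
    init_mass_focal <- (sum(leaves$plant == focal) - n_before) *
      (p$lamina_init_mg + p$petiole_init_mg)

    light <- NULL
    min_dist <- rep(NA_real_, nrow(leaves))
    if (nrow(leaves)) {
      geom <- leaf_geometry(leaves, pos, p)
      light <- compute_light(geom, layout, src)
      alive <- which(!leaves$senesced)
      if (length(alive) > 1) {
        md <- min_tip_distance_cpp(geom$tip[alive, , drop = FALSE],
                                   layout$Lx, layout$Ly)
        min_dist[alive] <- md
      }
      leaves$lamina_par <- light$lamina_par
      leaves$lamina_rfr <- light$lamina_rfr
      leaves$petiole_rfr <- light$petiole_rfr
      audits[[day]] <- cbind(day = day, light$audit)
    }

    # --- carbon input ---
    pool <- numeric(n_plants)
    if (nrow(leaves)) {
      act <- !leaves$senesced
      assim <- numeric(nrow(leaves))
      assim[act] <- photosynthesis(leaves$lamina_par[act],
                                   leaves$lamina_area[act], p,
                                   src$photoperiod)
      pool <- pool + as.numeric(tapply(assim, factor(leaves$plant,
                                                     levels = plants$plant),
                                       sum, default = 0))
    }
    if (day >= reserve_start && day < reserve_start + p$seed_reserve_days)
      pool <- pool + p$seed_reserve_mg / p$seed_reserve_days

    # --- responses and demands ---
    if (nrow(leaves)) {
      leaves$lamina_growing <- !leaves$senesced & leaves$age < p$lamina_te
      leaves$petiole_growing <- !leaves$senesced & leaves$age < p$petiole_te

      alpha_leaf <- plants$alpha[leaves$plant]
      f_lam <- rep(1, nrow(leaves))
      f_pet <- rep(1, nrow(leaves))
      ok_l <- !is.na(leaves$lamina_rfr) & leaves$lamina_rfr > 0
      ok_p <- !is.na(leaves$petiole_rfr) & leaves$petiole_rfr > 0
      f_lam[ok_l] <- pmin(2, (leaves$lamina_rfr[ok_l] / p_rfr_control(src))^
                            (-alpha_leaf[ok_l]))
      f_pet[ok_p] <- pmin(2, (leaves$petiole_rfr[ok_p] / p_rfr_control(src))^
                            (-alpha_leaf[ok_p]))

      dp_lam <- ifelse(leaves$lamina_growing,
                       beta_growth_mass(pmin(leaves$age + 1, p$lamina_te),
                                        p$lamina_wmax, p$lamina_te,
                                        p$lamina_tm) -
                         beta_growth_mass(leaves$age, p$lamina_wmax,
                                          p$lamina_te, p$lamina_tm), 0)
      d_lam <- lamina_demand(dp_lam, f_lam, config$scenario_n)
      d_lam[!leaves$lamina_growing] <- 0
      dp_pet <- ifelse(leaves$petiole_growing,
                       beta_growth_mass(pmin(leaves$age + 1, p$petiole_te),
                                        p$petiole_wmax, p$petiole_te,
                                        p$petiole_tm) -
                         beta_growth_mass(leaves$age, p$petiole_wmax,
                                          p$petiole_te, p$petiole_tm), 0)
      d_pet <- dp_pet + ifelse(leaves$senesced, 0,
                               leaves$petiole_extra_demand)

      alloc_lam <- numeric(nrow(leaves))
      alloc_pet <- numeric(nrow(leaves))
      for (pl in seq_len(n_plants)) {
        idx <- which(leaves$plant == pl)
        d_root <- p$root_sink_fraction * sum(dp_lam[idx] + dp_pet[idx])
        demands <- c(d_lam[idx], d_pet[idx], d_root)
        nl <- length(idx)
        al <- allocate(pool[pl], demands,
                       is_lamina = c(rep(TRUE, nl), rep(FALSE, nl + 1)),
                       root_index = 2 * nl + 1,
                       surplus_root_fraction = p$surplus_root_fraction)
        alloc_lam[idx] <- al[seq_len(nl)]
        alloc_pet[idx] <- al[nl + seq_len(nl)]
        plants$root_biomass[pl] <- plants$root_biomass[pl] + al[2 * nl + 1]
      }
      growth_frac <- ifelse(d_pet > 0, dp_pet / d_pet, 1)
      leaves <- dimension_update(leaves, alloc_lam, alloc_pet, growth_frac, p)
      leaves$petiole_extra_demand <- 0

      leaves <- apply_petiole_plasticity(leaves, f_pet, p)
      leaves <- update_leaf_angle(leaves, min_dist, leaves$lamina_rfr, p)
      leaves <- senesce(leaves, p)

      bad <- !is.finite(leaves$lamina_area) | !is.finite(leaves$petiole_length)
      if (any(bad))
        stop(sprintf("non-finite organ state on day %d, plant %d",
                     day, leaves$plant[which(bad)[1]]))
    }

    # --- focal trajectory ---
    fl <- leaves$plant == focal
    fb <- sum(leaves$petiole_biomass[fl]) + sum(leaves$lamina_biomass[fl]) +
      plants$root_biomass[focal]
    traj$biomass[day] <- fb
    traj$carbon_input[day] <- pool[focal] + init_mass_focal
    traj$pct_petiole[day] <- percent_biomass_in(
      "petiole", leaves$petiole_biomass[fl], leaves$lamina_biomass[fl],
      plants$root_biomass[focal])
    traj$pct_lamina[day] <- percent_biomass_in(
      "lamina", leaves$petiole_biomass[fl], leaves$lamina_biomass[fl],
      plants$root_biomass[focal])
    traj$lai[day] <- compute_lai(leaves$lamina_area[fl], leaves$senesced[fl],
                                 config$density)
    live_f <- fl & !leaves$senesced
    traj$mean_angle[day] <- if (any(live_f))
      mean(leaves$elevation_angle[live_f]) else NA_real_
    if (!is.null(light) && any(live_f)) {
      is_lam <- geom$sensor_organ == "lamina"
      sl <- geom$sensor_leaf
      pick <- leaves$plant[sl] == focal & !leaves$senesced[sl]
      # whole-plant ratio: total perceived amounts (flux x organ area),
      # summed over organ sensors before division; petioles enter at their
      # projected area (length x nominal 1 mm width)
      s_area <- ifelse(is_lam, leaves$lamina_area[sl],
                       leaves$petiole_length[sl] * 1e-3)
      traj$mean_rfr[day] <- mean_plant_rfr(
        (light$sensor_red * s_area)[pick],
        (light$sensor_farred * s_area)[pick])
      # same quantity averaged over every plant in the stand: a
      # lower-variance diagnostic of the canopy light climate
      alive_s <- !leaves$senesced[sl]
      traj$stand_mean_rfr[day] <- mean_plant_rfr(
        (light$sensor_red * s_area)[alive_s],
        (light$sensor_farred * s_area)[alive_s])
    }

    if (!is.null(dumps)) {
      keep <- if (config$light_dump == "all") rep(TRUE, nrow(leaves)) else fl
      if (any(keep))
        dumps[[day]] <- data.frame(
          day = day, plant = leaves$plant[keep], rank = leaves$rank[keep],
          senesced = leaves$senesced[keep],
          lamina_par = leaves$lamina_par[keep],
          lamina_rfr = leaves$lamina_rfr[keep],
          petiole_rfr = leaves$petiole_rfr[keep])
    }
  }

  structure(list(
    performance = traj$biomass[config$days],
    trajectory = traj,
    audit = do.call(rbind, audits[!vapply(audits, is.null, TRUE)]),
    leaves = leaves, plants = plants, seed = config$seed, config = config,
    light_dump = if (is.null(dumps)) NULL
                 else do.call(rbind, dumps[!vapply(dumps, is.null, TRUE)])),
    class = "stand_result")
}

p_rfr_control <- function(source) source$rfr_ratio

#' @export
print.stand_result <- function(x, ...) {
  cat(sprintf(
    "<stand_result> density %g, resident %.2f, mutant %.2f, n %g: %.1f mg\n",
    x$config$density, x$config$resident_alpha, x$config$mutant_alpha,
    x$config$scenario_n, x$performance))
  invisible(x)
}

#' Run a mutant-in-resident experiment design
#'
#' Simulates every (mutant, resident, density, scenario, replicate) cell of
#' the design and assembles one [performance_matrix()] per (density,
#' scenario). Seeds derive deterministically from `seed_base` and the cell
#' coordinates via [derive_seed()]. Monomorphic cells sit on the diagonal.
#'
#' @param strategies Strategy grid (vector of alpha values).
#' @param densities Planting densities (plants per m2).
#' @param scenarios Lamina-response exponents `n`.
#' @param replicates Replicates per cell.
#' @param seed_base Base seed for the whole experiment.
#' @param days,rows,cols,params,source Passed to [stand_config()].
#' @param light_dump Per-organ dump setting for each run.
#' @param progress Print one line per completed cell.
#' @return A list with `runs` (long data frame: density, scenario_n,
#'   mutant_alpha, resident_alpha, replicate, seed, focal_biomass_mg) and
#'   `matrices` (list of `performance_matrix`, named
#'   `d<density>_n<scenario>`). Cells whose run fails are recorded with
#'   `NA` performance and the run continues.
#' @export
run_experiment <- function(strategies, densities, scenarios = 2,
                           replicates = 20, seed_base = 1, days = 46,
                           rows = 7, cols = 7, params = default_params(),
                           source = light_source(),
                           light_dump = "none", progress = FALSE) {
  stopifnot(length(strategies) >= 1)
  grid <- expand.grid(replicate = seq_len(replicates),
                      mutant = strategies, resident = strategies,
                      density = densities, scenario = scenarios)
  rows_out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    seed <- derive_seed(seed_base, g$density, g$scenario, g$mutant,
                        g$resident, g$replicate)
    perf <- tryCatch({
      r <- simulate_stand(stand_config(
        g$density, g$resident, g$mutant, g$scenario, days = days,
        rows = rows, cols = cols, seed = seed, params = params,
        source = source, light_dump = light_dump))
      r$performance
    }, error = function(e) {
      warning(sprintf("run failed (density %g, m %.2f, r %.2f, rep %d): %s",
                      g$density, g$mutant, g$resident, g$replicate,
                      conditionMessage(e)))
      NA_real_
    })
    rows_out[[i]] <- data.frame(
      density = g$density, scenario_n = g$scenario, mutant_alpha = g$mutant,
      resident_alpha = g$resident, replicate = g$replicate, seed = seed,
      focal_biomass_mg = perf)
    if (progress && g$replicate == replicates)
      message(sprintf("done: d=%g n=%g m=%.2f r=%.2f", g$density,
                      g$scenario, g$mutant, g$resident))
  }
  runs <- do.call(rbind, rows_out)
  matrices <- list()
  for (d in densities) for (s in scenarios) {
    sub <- runs[runs$density == d & runs$scenario_n == s, ]
    matrices[[sprintf("d%g_n%g", d, s)]] <-
      performance_matrix_from_runs(sub, strategies, d, s)
  }
  list(runs = runs, matrices = matrices)
}

#' Cue-reliability query: lamina PAR at a fixed petiole R:FR
#'
#' Collects the absorbed PAR of laminas whose petiole perceived an R:FR
#' inside the window, grouped by density: how much light a leaf actually
#' receives when its petiole reports a given proximity cue. Across
#' densities this quantifies how unreliable a single R:FR value is as a
#' shading forecast.
#'
#' @param dump Per-organ light dump (rows from `stand_result$light_dump`,
#'   with a `density` column added when combining stands).
#' @param rfr_window Two-sided window on petiole R:FR (default
#'   `c(0.95, 1.05)`).
#' @return A data frame per density: `n_leaves`, `mean_par`, `median_par`,
#'   `q25`, `q75`; zero-row selections yield a zero-row summary with a
#'   warning.
#' @export
cue_reliability_query <- function(dump, rfr_window = c(0.95, 1.05)) {
  stopifnot(!is.null(dump$density))
  sel <- dump[!is.na(dump$petiole_rfr) &
                dump$petiole_rfr >= rfr_window[1] &
                dump$petiole_rfr <= rfr_window[2] & !dump$senesced, ]
  if (nrow(sel) == 0) {
    warning("no laminas fall inside the petiole R:FR window")
    return(data.frame(density = numeric(), n_leaves = integer(),
                      mean_par = numeric(), median_par = numeric(),
                      q25 = numeric(), q75 = numeric()))
  }
  out <- lapply(split(sel, sel$density), function(s) data.frame(
    density = s$density[1], n_leaves = nrow(s),
    mean_par = mean(s$lamina_par), median_par = median(s$lamina_par),
    q25 = quantile(s$lamina_par, 0.25), q75 = quantile(s$lamina_par, 0.75)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$density), ]
}
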