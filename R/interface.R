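# Experiment configuration, presets, dry-run planning and figure
# generation.

#' Preset experiment configurations
#'
#' `"paper"` is the full published design: strategy grid 0-0.7 by 0.1 (8
#' strategies, 64 mutant-resident cells), densities 100, 400, 711, 1600 and
#' 6400 plants m-2, scenarios n = 2 (Average), 1 (Weak) and 4 (Strong), 20
#' replicates, 46 days, 7x7 stands, 20x20 tile replication. `"desk"` is the
#' scaled-down configuration used for routine validation: strategies
#' {0, 0.2, 0.4, 0.6}, densities {100, 1600, 6400}, Average scenario, 5
#' replicates, 5x5 stands and a reduced ray budget.
#'
#' @param preset `"paper"` or `"desk"`.
#' @param ... Overrides of any configuration field.
#' @return A list of class `run_config`.
#' @export
preset_config <- function(preset = c("paper", "desk"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    paper = list(
      name = "paper",
      strategies = seq(0, 0.7, by = 0.1),
      densities = c(100, 400, 711, 1600, 6400),
      scenarios = c(Average = 2, Weak = 1, Strong = 4),
      replicates = 20, days = 46, rows = 7, cols = 7,
      tile_extent = 20,
      source = light_source(),
      params = default_params(),
      seed_base = 1),
    desk = list(
      name = "desk",
      strategies = c(0, 0.2, 0.4, 0.6),
      densities = c(100, 1600, 6400),
      scenarios = c(Average = 2),
      replicates = 5, days = 46, rows = 5, cols = 5,
      tile_extent = 20,
      source = light_source(ray_count = 3000, gather_rays = 8),
      params = default_params(),
      seed_base = 1))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(validate_config(cfg), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every field and fails with a message naming the offending field.
#'
#' @param cfg A configuration list.
#' @return The validated configuration, invisibly usable.
#' @export
validate_config <- function(cfg) {
  need <- c("strategies", "densities", "scenarios", "replicates", "days",
            "rows", "cols")
  for (f in need)
    if (is.null(cfg[[f]])) stop("config field missing: ", f)
  if (!length(cfg$strategies) || any(!is.finite(cfg$strategies)))
    stop("invalid field 'strategies'")
  if (any(cfg$densities <= 0)) stop("invalid field 'densities': must be > 0")
  if (any(cfg$scenarios < 0)) stop("invalid field 'scenarios': n must be >= 0")
  if (cfg$replicates < 1) stop("invalid field 'replicates'")
  if (cfg$days < 1) stop("invalid field 'days'")
  if (cfg$rows %% 2 != 1 || cfg$cols %% 2 != 1)
    stop("invalid field 'rows'/'cols': stand dimensions must be odd")
  cfg
}

#' Dry-run plan of an experiment configuration
#'
#' Enumerates the runs a configuration implies without simulating
#' anything.
#'
#' @param cfg A [preset_config()] result.
#' @return A list: `n_cells` (mutant-resident cells per matrix),
#'   `n_monomorphic`, `n_mixed`, `n_matrices`, `n_runs` (total
#'   simulations), `n_tiles` (replicated canopies per light computation,
#'   `tile_extent^2`).
#' @export
plan_experiment <- function(cfg) {
  k <- length(cfg$strategies)
  n_cells <- k * k
  n_matrices <- length(cfg$densities) * length(cfg$scenarios)
  list(n_cells = n_cells,
       n_monomorphic = k,
       n_mixed = n_cells - k,
       n_matrices = n_matrices,
       n_runs = n_cells * cfg$replicates * n_matrices,
       n_tiles = cfg$tile_extent^2)
}

#' Write / read a run configuration as YAML
#'
#' The light source and physiology parameter blocks are stored inline, so
#' the YAML file is a complete, self-contained echo of a run.
#'
#' @param cfg A [preset_config()] result.
#' @param path File path.
#' @return `read_config_yaml()` returns a validated `run_config`.
#' @export
write_config_yaml <- function(cfg, path) {
  out <- cfg
  out$source <- unclass(out$source)
  out$source$absorptance <- as.list(out$source$absorptance)
  out$params <- unclass(out$params)
  out$scenarios <- as.list(out$scenarios)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$scenarios <- unlist(raw$scenarios)
  if (!is.null(raw$params)) raw$params <- do.call(default_params, raw$params)
  if (!is.null(raw$source)) {
    raw$source$absorptance <- unlist(raw$source$absorptance)
    raw$source <- do.call(light_source, raw$source)
  }
  structure(validate_config(raw), class = "run_config")
}

# ---- figures -------------------------------------------------------------

#' PIP panel figure
#'
#' Discrete (and optionally smoothed) pairwise invasibility plots with a
#' diverging red-blue palette centred on zero and the identity line drawn.
#'
#' @param discrete An [invasion_exponent()] result.
#' @param smoothed Optional [smooth_performance()] result.
#' @param grid_n Smoothed-surface resolution.
#' @return A ggplot object.
#' @export
plot_pip <- function(discrete, smoothed = NULL, grid_n = 81) {
  g <- discrete$strategies
  cells <- expand.grid(resident = g, mutant = g)
  cells$s <- as.vector(t(discrete$exponent))
  cells$panel <- "discrete"
  if (!is.null(smoothed)) {
    gg <- seq(min(g), max(g), length.out = grid_n)
    surf <- expand.grid(resident = gg, mutant = gg)
    surf$s <- smoothed$s(surf$mutant, surf$resident)
    surf$panel <- "smoothed"
    cells <- rbind(cells, surf)
  }
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$resident, y = .data$mutant,
                                      fill = .data$s)) +
    ggplot2::geom_tile() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white",
                                  high = "darkblue", midpoint = 0,
                                  name = "invasion\nexponent") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "resident strategy", y = "mutant strategy") +
    ggplot2::theme_minimal()
}

#' Trajectory panels for monomorphic stands
#'
#' Mean perceived R:FR, focal biomass and percent petiole biomass against
#' day, coloured by density.
#'
#' @param results List of `stand_result` objects.
#' @return A ggplot object (three facets).
#' @export
plot_trajectories <- function(results) {
  dat <- do.call(rbind, lapply(results, function(r) {
    tr <- r$trajectory
    data.frame(day = tr$day, density = r$config$density,
               `mean R:FR` = tr$mean_rfr, `biomass (mg)` = tr$biomass,
               `% petiole` = tr$pct_petiole, check.names = FALSE)
  }))
  long <- stats::reshape(dat, direction = "long",
                         varying = list(3:5),
                         times = names(dat)[3:5], v.names = "value",
                         timevar = "variable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value,
                                     colour = factor(.data$density),
                                     group = interaction(.data$density))) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(colour = "density (m-2)", x = "day", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cue-reliability boxplot figure
#'
#' Absorbed lamina PAR, for laminas whose petiole perceived an R:FR inside
#' the window, by density.
#'
#' @param dump Combined light dump with `density` column.
#' @param rfr_window Petiole R:FR window.
#' @return A ggplot object.
#' @export
plot_cue_reliability <- function(dump, rfr_window = c(0.95, 1.05)) {
  sel <- dump[!is.na(dump$petiole_rfr) &
                dump$petiole_rfr >= rfr_window[1] &
                dump$petiole_rfr <= rfr_window[2] & !dump$senesced, ]
  ggplot2::ggplot(sel, ggplot2::aes(x = factor(.data$density),
                                    y = .data$lamina_par)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 17) +
    ggplot2::labs(x = "density (plants m-2)",
                  y = "lamina PAR (umol m-2 s-1)") +
    ggplot2::theme_minimal()
}

#' Write long-format performance runs as CSV
#'
#' @param runs The `runs` data frame from [run_experiment()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_performance_csv <- function(runs, path) {
  write.csv(runs, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format performance CSV back into matrices
#'
#' Drop-in for simulator or synthetic-landscape output.
#'
#' @param path CSV path.
#' @return A data frame of runs.
#' @export
read_performance_csv <- function(path) {
  utils::read.csv(path)
}
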