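# Shared fixtures: small deterministic scenes and reduced light budgets so
# unit tests stay fast. All randomness is seeded explicitly in the tests.

fast_source <- function(...) {
  light_source(ray_count = 2000, gather_rays = 8, ...)
}

# a minimal leaf table with sensible defaults, overridable per column
make_leaves <- function(n = 1, ...) {
  df <- data.frame(
    plant = 1L, rank = seq_len(n), emergence_day = 1, age = 10,
    petiole_length = 0.01, petiole_biomass = 5, lamina_area = 3e-4,
    lamina_biomass = 10, elevation_angle = 20, azimuth = 0,
    petiole_growing = TRUE, lamina_growing = TRUE, senesced = FALSE,
    petiole_extra_demand = 0, petiole_rfr = NA_real_,
    lamina_rfr = NA_real_, lamina_par = 0)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

# single-plant positions matrix for geometry tests
one_plant_positions <- function(x = 0.25, y = 0.25) {
  matrix(c(x, y), 1, 2, dimnames = list(NULL, c("x", "y")))
}
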