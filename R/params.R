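#' Default physiological and architectural parameters
#'
#' The organ-level constants of the growth model. None of these are part of
#' the trait under selection; they define the background plant. Defaults are
#' calibrated so that sparse stands approach potential organ sizes by the end
#' of a 46-day run while dense stands become carbon-limited well before it —
#' the two regimes the analysis depends on. Every entry can be overridden,
#' either via `...` here or by editing a YAML copy (see
#' [write_params_yaml()] / [read_params_yaml()]).
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list of class `physiology_params`.
#' @section Parameters:
#' \describe{
#'   \item{plastochron}{Days between successive leaf initiations (1.5).}
#'   \item{germination_day}{Day at which leaf initiation starts (3).}
#'   \item{senescence_age}{Leaf age in days after which it senesces (40).}
#'   \item{lamina_wmax, lamina_te, lamina_tm}{Beta-growth parameters of a
#'     lamina: final mass 30 mg, growth duration 20 d, inflection 8 d.}
#'   \item{petiole_wmax, petiole_te, petiole_tm}{Beta-growth parameters of a
#'     petiole: 8 mg, 15 d, 6 d.}
#'   \item{sla}{Lamina area gained per allocated mg (3e-5 m2/mg).}
#'   \item{petiole_density}{Petiole linear density (500 mg/m).}
#'   \item{lamina_init_mg, petiole_init_mg}{Seed-scale initial organ masses.}
#'   \item{root_init_mg}{Initial root mass.}
#'   \item{root_sink_fraction}{Root demand as a fraction of total leaf
#'     potential demand (0.1).}
#'   \item{surplus_root_fraction}{Share of surplus carbon sent to the root
#'     when the pool exceeds total demand (0.5; the rest goes to laminas
#'     pro rata by their sink strength).}
#'   \item{seed_reserve_mg, seed_reserve_days}{Carbon reserve released
#'     evenly over the first days after germination, standing in for
#'     cotyledon support.}
#'   \item{p_max}{Light-saturated photosynthesis (umol CO2 m-2 s-1).}
#'   \item{phi}{Initial slope of the light response
#'     (umol CO2 per umol photons).}
#'   \item{carbon_conversion}{Biomass per assimilated CO2 (mg per umol).}
#'   \item{init_angle, angle_step, angle_max}{Leaf elevation: initial 25
#'     degrees, hyponastic step 16 degrees, maximum 80 degrees.}
#'   \item{touch_distance}{Lamina-tip proximity that triggers hyponasty
#'     (0.002 m).}
#'   \item{rfr_angle_threshold}{Lamina R:FR below which hyponasty triggers
#'     (0.5).}
#'   \item{hyponasty_growth_only}{Restrict hyponasty to leaves whose
#'     petiole is still growing (TRUE): leaf-angle movement is driven by
#'     differential petiole growth.}
#'   \item{divergence_angle}{Phyllotactic divergence (137.5 degrees).}
#'   \item{lamina_aspect}{Lamina ellipse major:minor aspect ratio (2).}
#' }
#' @export
default_params <- function(...) {
  p <- list(
    plastochron = 1.5,
    germination_day = 3,
    senescence_age = 40,
    lamina_wmax = 30, lamina_te = 20, lamina_tm = 8,
    petiole_wmax = 8, petiole_te = 15, petiole_tm = 6,
    sla = 3e-5,
    petiole_density = 500,
    lamina_init_mg = 0.1,
    petiole_init_mg = 0.02,
    root_init_mg = 0.05,
    root_sink_fraction = 0.1,
    surplus_root_fraction = 0.5,
    seed_reserve_mg = 2,
    seed_reserve_days = 6,
    p_max = 14,
    phi = 0.05,
    carbon_conversion = 0.03,
    init_angle = 25,
    angle_step = 16,
    angle_max = 80,
    touch_distance = 0.002,
    rfr_angle_threshold = 0.5,
    hyponasty_growth_only = TRUE,
    divergence_angle = 137.5,
    lamina_aspect = 2
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  structure(p, class = "physiology_params")
}

#' Write / read the parameter set as YAML
#'
#' @param params A list from [default_params()].
#' @param path File path.
#' @return `read_params_yaml()` returns a `physiology_params` list;
#'   `write_params_yaml()` returns `path` invisibly.
#' @export
write_params_yaml <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_params, vals)
}

#' Light source specification
#'
#' Growth-chamber-like diffuse light: R:FR 2.3 at 220 umol m-2 s-1 PAR for
#' 9 h per day. Red and far-red are carried in relative flux units whose
#' ratio is `rfr_ratio`.
#'
#' @param par_intensity PAR flux on a horizontal plane (umol m-2 s-1).
#' @param rfr_ratio Source red : far-red ratio.
#' @param photoperiod Hours of light per day.
#' @param ray_count Forward Monte Carlo rays per daily light computation.
#' @param gather_rays Upward sample rays per organ sensor for perceived
#'   red / far-red.
#' @param max_bounces Scattering depth of the forward pass (>= 1 so
#'   far-red reflection can reach neighbours laterally).
#' @param absorptance Per-band lamina absorptance, named `red`, `farred`,
#'   `par`; the remainder is split equally between reflection and
#'   transmission. Red absorptance exceeds far-red so canopies lower R:FR.
#' @return An object of class `light_source`.
#' @export
light_source <- function(par_intensity = 220, rfr_ratio = 2.3,
                         photoperiod = 9, ray_count = 20000,
                         gather_rays = 12, max_bounces = 2,
                         absorptance = c(red = 0.85, farred = 0.15,
                                         par = 0.85)) {
  stopifnot(par_intensity > 0, rfr_ratio > 0, photoperiod > 0,
            ray_count >= 1, gather_rays >= 1, max_bounces >= 0,
            all(absorptance > 0 & absorptance < 1))
  structure(list(par_intensity = par_intensity, rfr_ratio = rfr_ratio,
                 photoperiod = photoperiod, ray_count = as.integer(ray_count),
                 gather_rays = as.integer(gather_rays),
                 max_bounces = as.integer(max_bounces),
                 absorptance = absorptance),
            class = "light_source")
}
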