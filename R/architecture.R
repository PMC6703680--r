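# Rosette architecture: organ initiation, phyllotaxis, leaf geometry,
# hyponastic angle dynamics and senescence. A stand's leaves are kept in one
# data frame (one row per leaf) so all per-organ rules vectorise.

leaf_columns <- function() {
  data.frame(
    plant = integer(), rank = integer(), emergence_day = numeric(),
    age = numeric(), petiole_length = numeric(), petiole_biomass = numeric(),
    lamina_area = numeric(), lamina_biomass = numeric(),
    elevation_angle = numeric(), azimuth = numeric(),
    petiole_growing = logical(), lamina_growing = logical(),
    senesced = logical(), petiole_extra_demand = numeric(),
    petiole_rfr = numeric(), lamina_rfr = numeric(),
    lamina_par = numeric(), stringsAsFactors = FALSE)
}

#' Phyllotactic azimuth of a leaf rank
#'
#' Leaves are placed in a spiral: `azimuth = (base + (rank - 1) *
#' divergence) mod 360`, with the golden-angle divergence 137.5 degrees by
#' default.
#'
#' @param rank Leaf rank (integer >= 1); vectorised.
#' @param base First-leaf azimuth in degrees.
#' @param divergence Divergence angle in degrees.
#' @return Azimuth in degrees, in `[0, 360)`.
#' @export
phyllotaxis_azimuth <- function(rank, base = 0, divergence = 137.5) {
  if (any(rank < 1)) stop("rank must be >= 1")
  (base + (rank - 1) * divergence) %% 360
}

#' Initiate new leaves up to the current day
#'
#' Appends one leaf per elapsed plastochron since germination: at day `d`
#' the plant carries `floor((d - germination_day) / plastochron)` leaves
#' (none before germination). New leaves get consecutive ranks, spiral
#' azimuths from the plant's random base azimuth, seed-scale initial organ
#' masses, and the configured initial elevation angle. Idempotent within a
#' day; existing leaves are untouched.
#'
#' @param leaves Leaf data frame of the stand.
#' @param plants Plant table with columns `plant` and `base_azimuth`.
#' @param day Current day.
#' @param params [default_params()] list.
#' @return The leaf data frame with any newly emerged leaves appended.
#' @export
initiate_organs <- function(leaves, plants, day, params = default_params()) {
  n_target <- max(0L, floor((day - params$germination_day) / params$plastochron))
  if (n_target == 0L) return(leaves)
  new_rows <- list()
  for (i in seq_len(nrow(plants))) {
    pid <- plants$plant[i]
    have <- sum(leaves$plant == pid)
    if (have >= n_target) next
    ranks <- seq.int(have + 1L, n_target)
    nr <- data.frame(
      plant = pid, rank = as.integer(ranks), emergence_day = day, age = 0,
      petiole_length = params$petiole_init_mg / params$petiole_density,
      petiole_biomass = params$petiole_init_mg,
      lamina_area = params$lamina_init_mg * params$sla,
      lamina_biomass = params$lamina_init_mg,
      elevation_angle = params$init_angle,
      azimuth = phyllotaxis_azimuth(ranks, plants$base_azimuth[i],
                                    params$divergence_angle),
      petiole_growing = TRUE, lamina_growing = TRUE, senesced = FALSE,
      petiole_extra_demand = 0,
      petiole_rfr = NA_real_, lamina_rfr = NA_real_, lamina_par = 0,
      stringsAsFactors = FALSE)
    new_rows[[length(new_rows) + 1L]] <- nr
  }
  if (length(new_rows)) leaves <- rbind(leaves, do.call(rbind, new_rows))
  leaves
}

#' Hyponastic leaf-angle update
#'
#' A leaf raises its elevation angle by `angle_step` (16 degrees per day)
#' when the distance to the nearest neighbouring leaf tip is below
#' `touch_distance` (2 mm) or when the R:FR perceived at its lamina is below
#' `rfr_angle_threshold` (0.5); the angle is clamped at `angle_max`.
#' Senesced leaves are left unchanged. With `hyponasty_growth_only` (the
#' default) only leaves whose petiole is still in its growth phase can
#' move: hyponasty is differential petiole growth, so a leaf whose petiole
#' has finished growing can no longer reorient.
#'
#' @param leaves Leaf data frame (or any data frame with columns
#'   `elevation_angle` and `senesced`).
#' @param min_neighbour_distance Per-leaf distance to the nearest other
#'   leaf tip (m).
#' @param lamina_rfr Per-leaf R:FR perceived at the lamina; `NA` is treated
#'   as no low-R:FR trigger.
#' @param params [default_params()] list.
#' @return The leaf data frame with updated `elevation_angle`.
#' @export
update_leaf_angle <- function(leaves, min_neighbour_distance, lamina_rfr,
                              params = default_params()) {
  if (any(min_neighbour_distance < 0, na.rm = TRUE))
    stop("negative neighbour distance")
  eligible <- !leaves$senesced
  if (isTRUE(params$hyponasty_growth_only) &&
      !is.null(leaves$petiole_growing))
    eligible <- eligible & leaves$petiole_growing
  trig <- eligible &
    ((!is.na(min_neighbour_distance) &
        min_neighbour_distance < params$touch_distance) |
       (!is.na(lamina_rfr) & lamina_rfr < params$rfr_angle_threshold))
  leaves$elevation_angle[trig] <-
    pmin(params$angle_max, leaves$elevation_angle[trig] + params$angle_step)
  leaves
}

#' Flag leaves older than the senescence age
#'
#' Leaves senesce strictly after `senescence_age` days (default 40): a
#' senesced leaf stops growing, no longer absorbs or blocks light and
#' exerts no sink demand, but its biomass stays in the plant total.
#'
#' @param leaves Leaf data frame.
#' @param params [default_params()] list.
#' @return Updated leaf data frame.
#' @export
senesce <- function(leaves, params = default_params()) {
  old <- leaves$age > params$senescence_age
  leaves$senesced[old] <- TRUE
  leaves$petiole_growing[old] <- FALSE
  leaves$lamina_growing[old] <- FALSE
  leaves
}

#' 3D surface patches of a leaf
#'
#' The petiole is a thin inclined segment from the rosette centre with the
#' leaf's elevation and azimuth; the lamina is a planar ellipse of the
#' leaf's area (aspect ratio `lamina_aspect`:1, major axis continuing the
#' petiole direction) attached at the petiole tip. Petioles carry a
#' mid-point R:FR sensor but intercept no light (negligible area).
#'
#' @param leaves Leaf data frame.
#' @param positions Matrix of plant positions, one row `(x, y)` per plant id.
#' @param params [default_params()] list.
#' @return A list with `patches` (one row per non-senesced lamina: centre,
#'   unit axes, semi-axes, organ index), `sensors` (lamina centres and
#'   petiole midpoints with their organ index), `tip` (lamina tip points)
#'   and `attach_height` (petiole tip height, m).
#' @export
leaf_geometry <- function(leaves, positions, params = default_params()) {
  n <- nrow(leaves)
  el <- leaves$elevation_angle * pi / 180
  az <- leaves$azimuth * pi / 180
  dx <- cos(az) * cos(el); dy <- sin(az) * cos(el); dz <- sin(el)
  px <- positions[leaves$plant, 1]; py <- positions[leaves$plant, 2]
  L <- leaves$petiole_length
  tipx <- px + L * dx; tipy <- py + L * dy; tipz <- L * dz
  asp <- params$lamina_aspect
  b <- sqrt(pmax(leaves$lamina_area, 0) / (pi * asp))
  a <- asp * b
  cx <- tipx + a * dx; cy <- tipy + a * dy; cz <- tipz + a * dz
  vx <- -sin(az); vy <- cos(az); vz <- rep(0, n)
  live <- !leaves$senesced & leaves$lamina_area > 0
  patches <- cbind(cx, cy, cz, dx, dy, dz, vx, vy, vz, a, b,
                   seq_len(n) - 1L)[live, , drop = FALSE]
  colnames(patches) <- c("cx", "cy", "cz", "ux", "uy", "uz",
                         "vx", "vy", "vz", "a", "b", "organ")
  # sensors: lamina centre (own patch excluded from its gather rays, gather
  # hemisphere about the blade normal) and petiole midpoint (vertical
  # hemisphere), for every non-senesced leaf
  ns <- which(!leaves$senesced)
  k <- length(ns)
  nx <- -sin(el) * cos(az); ny <- -sin(el) * sin(az); nz <- cos(el)
  sensors <- rbind(
    cbind(cx[ns], cy[ns], cz[ns] + 1e-6, ns - 1L, nx[ns], ny[ns], nz[ns]),
    cbind(px[ns] + 0.5 * L[ns] * dx[ns], py[ns] + 0.5 * L[ns] * dy[ns],
          0.5 * L[ns] * dz[ns], rep(-1, k), rep(0, k), rep(0, k),
          rep(1, k)))
  list(patches = patches, sensors = sensors,
       sensor_leaf = c(ns, ns), sensor_organ = rep(c("lamina", "petiole"),
                                                   each = length(ns)),
       tip = cbind(tipx + 2 * a * dx, tipy + 2 * a * dy, tipz + 2 * a * dz),
       attach_height = tipz)
}
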