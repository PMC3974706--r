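#' Configuration for the synthetic seascape generator
#'
#' Parameterises a Baltic-Proper-like survey grid of 0.5 x 1 degree
#' rectangles observed annually. The defaults emulate the regime shift the
#' analysis is designed to detect: an early era of spatially homogeneous
#' density and condition at low abundance, followed by progressive
#' concentration of the population toward the north-east with condition
#' suppressed where density is high (so maximum condition sits toward the
#' south-west).
#'
#' Density in cell i of year t is
#' `A(t) * exp(kappa(t) * g_t(i)) * eps`, where `g_t` is a unit gradient
#' (1 at the year's hotspot, 0 at the cell farthest from it), `A(t)` the
#' abundance trajectory and `eps` lognormal observation noise. The hotspot
#' drifts linearly from the grid centre to the north-east corner. Condition
#' is `K0 * (1 - beta * density_norm) + eta` with `density_norm` a saturating
#' function of density relative to a run-wide carrying-capacity scale (see
#' [attach_condition()]; `beta` stays unit-free) and `eta` Gaussian noise,
#' floored at `0.1 * K0`.
#'
#' @param n_rows,n_cols Grid size in cells (0.5 deg lat x 1 deg lon).
#' @param lat0,lon0 South-west corner of the grid (degrees).
#' @param years Number of survey years.
#' @param start_year First calendar year.
#' @param abundance Per-year total density multiplier A(t); default a linear
#'   ramp 100 to 1000 (number per squared nautical mile scale).
#' @param kappa Per-year patch-concentration >= 0; default linear ramp 0 to 3.
#' @param drift_start,drift_end Hotspot position at the first and last year,
#'   as (row, col) fractions in [0,1]; default centre to NE corner.
#' @param beta Density-to-condition suppression strength in [0, 1].
#' @param k0 Baseline Fulton's K (TW in g, TL in cm, no x100 scaling).
#' @param noise_sd Lognormal sd of density observation noise.
#' @param condition_noise_sd Gaussian sd of condition noise (K units).
#' @param fish_per_cell Fish records emitted per cell per year.
#' @param fish_noise_sd Lognormal sd of individual weight noise.
#' @param seed RNG seed (mandatory; every draw is reproducible from it).
#' @return Object of class `seascape_config`.
#' @export
seascape_config <- function(n_rows = 10, n_cols = 10,
                            lat0 = 54.5, lon0 = 14,
                            years = 25, start_year = 1985,
                            abundance = seq(100, 1000, length.out = years),
                            kappa = seq(0, 3, length.out = years),
                            drift_start = c(0.5, 0.5),
                            drift_end = c(1, 1),
                            beta = 0.6, k0 = 0.007,
                            noise_sd = 0.3, condition_noise_sd = 2e-4,
                            fish_per_cell = 20, fish_noise_sd = 0.01,
                            seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_rows >= 3, n_cols >= 3, years >= 2,
            length(abundance) == years, length(kappa) == years,
            all(kappa >= 0), beta >= 0, k0 > 0,
            noise_sd >= 0, condition_noise_sd >= 0,
            fish_per_cell >= 0, fish_noise_sd >= 0)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, lat0 = lat0, lon0 = lon0,
         years = years, start_year = start_year,
         abundance = abundance, kappa = kappa,
         drift_start = drift_start, drift_end = drift_end,
         beta = beta, k0 = k0, noise_sd = noise_sd,
         condition_noise_sd = condition_noise_sd,
         fish_per_cell = fish_per_cell, fish_noise_sd = fish_noise_sd,
         seed = as.integer(seed)),
    class = "seascape_config")
}

# cell-centre grid with ICES codes
seascape_grid <- function(config) {
  g <- expand.grid(row = seq_len(config$n_rows), col = seq_len(config$n_cols))
  lat <- config$lat0 + (g$row - 1) * 0.5 + 0.25
  lon <- config$lon0 + (g$col - 1) * 1 + 0.5
  tibble::tibble(rect = centre_to_rect(lat, lon), lat = lat, lon = lon,
                 row = g$row, col = g$col)
}

# expected (noise-free) density surface for one year
density_expectation <- function(config, t, grid = seascape_grid(config)) {
  frac <- if (config$years == 1) 0 else (t - 1) / (config$years - 1)
  hot_row <- 1 + (config$drift_start[1] * (1 - frac) +
                  config$drift_end[1] * frac) * (config$n_rows - 1)
  hot_col <- 1 + (config$drift_start[2] * (1 - frac) +
                  config$drift_end[2] * frac) * (config$n_cols - 1)
  # distance in cell units; gradient 1 at the hotspot, 0 at the farthest cell
  d <- sqrt((grid$row - hot_row)^2 + (grid$col - hot_col)^2)
  g <- 1 - d / max(d)
  config$abundance[t] * exp(config$kappa[t] * g)
}

#' Generate yearly density maps
#'
#' @param config A [seascape_config()].
#' @return Observation tibble `year, rect, lat, lon, density`, reproducible
#'   bit-for-bit from `config$seed`.
#' @export
generate_density_maps <- function(config) {
  stopifnot(inherits(config, "seascape_config"))
  set.seed(config$seed)
  grid <- seascape_grid(config)
  maps <- lapply(seq_len(config$years), function(t) {
    mu <- density_expectation(config, t, grid)
    eps <- stats::rlnorm(nrow(grid), meanlog = 0, sdlog = config$noise_sd)
    tibble::tibble(year = config$start_year + t - 1L,
                   rect = grid$rect, lat = grid$lat, lon = grid$lon,
                   density = mu * eps)
  })
  dplyr::bind_rows(maps)
}

#' Attach condition to density maps
#'
#' Condition is suppressed where density is high:
#' `K0 * (1 - beta * density_norm) + eta`, with
#' `density_norm = 1 - exp(-density / d_ref)`, where `d_ref` is the maximum
#' of the noise-free expected density surface over the whole run.
#' Normalising against a single run-wide reference (a carrying-capacity
#' scale) rather than within each year makes crowding *absolute*: in
#' low-abundance years every cell is far from the reference and condition is
#' uniformly high, while in crowded years the dense cells are pushed down.
#' This is what lets the generator reproduce both the temporal decline of
#' mean condition with mean density and the steepening of the within-year
#' density-condition gradient. The saturating form keeps `density_norm` in
#' [0, 1) while staying *strictly* increasing in density, so with `beta > 0`
#' and no noise the within-year density-condition rank correlation is exactly
#' -1. `eta ~ N(0, condition_noise_sd)`; condition is floored at `0.1 * K0`
#' (floored cells counted in `attr(, "n_floored")`).
#'
#' @param obs Output of [generate_density_maps()].
#' @param config The same [seascape_config()].
#' @return `obs` with a `condition` column.
#' @export
attach_condition <- function(obs, config) {
  stopifnot(inherits(config, "seascape_config"), "density" %in% names(obs))
  set.seed(config$seed + 1L)
  grid <- seascape_grid(config)
  d_ref <- max(vapply(seq_len(config$years),
                      function(t) max(density_expectation(config, t, grid)),
                      numeric(1)))
  dnorm_ <- 1 - exp(-obs$density / d_ref)
  eta <- stats::rnorm(nrow(obs), 0, config$condition_noise_sd)
  cond <- config$k0 * (1 - config$beta * dnorm_) + eta
  floor_k <- 0.1 * config$k0
  n_floored <- sum(cond < floor_k)
  out <- obs
  out$condition <- pmax(cond, floor_k)
  attr(out, "n_floored") <- n_floored
  out
}

#' Emit individual fish records consistent with a seascape
#'
#' For each (year, cell), draws `fish_per_cell` fish with total length uniform
#' on the 0.5 cm measurement grid between 120 and 130 mm, and weight
#' `K_cell * TL_cm^3` perturbed by lognormal noise. Records are emitted
#' unrounded; [round_measurements()] applies the survey protocol. Running the
#' condition module on these records recovers each cell's condition up to
#' measurement rounding, closing the loop for end-to-end tests.
#'
#' @param obs Output of [attach_condition()].
#' @param config The same [seascape_config()].
#' @return Tibble `year, rect, length_mm, weight_g`.
#' @export
emit_fish_records <- function(obs, config) {
  stopifnot(inherits(config, "seascape_config"), "condition" %in% names(obs))
  if (config$fish_per_cell == 0) {
    return(tibble::tibble(year = integer(), rect = character(),
                          length_mm = double(), weight_g = double()))
  }
  set.seed(config$seed + 2L)
  n_cell <- config$fish_per_cell
  lengths_mm <- sample(seq(120, 130, by = 5), nrow(obs) * n_cell,
                       replace = TRUE)
  noise <- stats::rlnorm(nrow(obs) * n_cell, 0, config$fish_noise_sd)
  tibble::tibble(
    year = rep(obs$year, each = n_cell),
    rect = rep(obs$rect, each = n_cell),
    length_mm = lengths_mm,
    weight_g = rep(obs$condition, each = n_cell) * (lengths_mm / 10)^3 * noise)
}

#' Simulate a full synthetic seascape
#'
#' Convenience wrapper: density maps, condition, and fish records in one call.
#'
#' @param config A [seascape_config()].
#' @return List with `observations` (year, rect, lat, lon, density,
#'   condition) and `fish_records` (year, rect, length_mm, weight_g).
#' @export
simulate_seascape <- function(config) {
  obs <- attach_condition(generate_density_maps(config), config)
  fish <- emit_fish_records(obs, config)
  list(observations = obs, fish_records = fish)
}

#' A homogeneous-regime configuration (null seascape)
#'
#' No spatial gradient (kappa = 0), no density-condition coupling (beta = 0)
#' and a flat abundance trajectory: the early-era regime in which density and
#' condition are spatially and temporally structureless apart from noise.
#' Used as the null case against which the divergent-regime fingerprint is
#' contrasted.
#'
#' @param seed RNG seed.
#' @param ... Overrides passed to [seascape_config()].
#' @return A `seascape_config`.
#' @export
null_seascape_config <- function(seed, ...) {
  args <- list(...)
  years <- args$years %||% 25
  defaults <- list(kappa = rep(0, years), beta = 0,
                   abundance = rep(300, years), years = years, seed = seed)
  do.call(seascape_config, utils::modifyList(defaults, args))
}
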