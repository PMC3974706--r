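test_that("the generator is bit-reproducible from its seed", {
  a <- simulate_seascape(seascape_config(seed = 123, years = 5,
                                         abundance = rep(100, 5),
                                         kappa = rep(1, 5)))
  b <- simulate_seascape(seascape_config(seed = 123, years = 5,
                                         abundance = rep(100, 5),
                                         kappa = rep(1, 5)))
  expect_identical(a$observations, b$observations)
  expect_identical(a$fish_records, b$fish_records)
})

test_that("a flat seascape has no spatial structure beyond noise", {
  cfg <- null_seascape_config(seed = 55, years = 8)
  obs <- generate_density_maps(cfg)
  # expected density equal across cells: per-year spread is noise only
  by_year <- yearly_means(obs)
  expect_true(all(abs(by_year$mean_density / 300 - 1) < 0.2))
  # Moran's I hovers at the null expectation -1/(n-1)
  ms <- moran_series(obs)
  expect_lt(abs(mean(ms$I) - (-1 / 99)), 3 * sd(ms$I) / sqrt(nrow(ms)))
})

test_that("a concentrated north-east hotspot pulls the density centre NE", {
  cfg <- seascape_config(seed = 7, years = 4,
                         abundance = rep(100, 4), kappa = rep(4, 4),
                         drift_start = c(1, 1), drift_end = c(1, 1),
                         noise_sd = 0.1)
  obs <- generate_density_maps(cfg)
  grid_centre_lat <- 54.5 + 10 * 0.5 / 2
  grid_centre_lon <- 14 + 10 * 1 / 2
  for (yr in unique(obs$year)) {
    g <- centre_of_gravity(obs[obs$year == yr, ], "density")
    expect_gt(g[["lat"]], grid_centre_lat)
    expect_gt(g[["lon"]], grid_centre_lon)
  }
})

test_that("noise-free coupling makes condition a strict inverse of density", {
  cfg <- seascape_config(seed = 3, years = 3, abundance = rep(200, 3),
                         kappa = rep(2, 3), condition_noise_sd = 0)
  obs <- attach_condition(generate_density_maps(cfg), cfg)
  rho <- spatial_correlation_by_year(obs)
  expect_equal(rho$rho, rep(-1, 3))
  # beta = 0 instead gives constant condition at the baseline
  cfg0 <- seascape_config(seed = 3, years = 3, abundance = rep(200, 3),
                          kappa = rep(2, 3), beta = 0,
                          condition_noise_sd = 0)
  obs0 <- attach_condition(generate_density_maps(cfg0), cfg0)
  expect_true(all(obs0$condition == cfg0$k0))
})

test_that("condition and density centres split across the grid centre", {
  cfg <- seascape_config(seed = 21, noise_sd = 0.1)
  obs <- attach_condition(generate_density_maps(cfg), cfg)
  late <- obs[obs$year == max(obs$year), ]
  g_d <- centre_of_gravity(above_median_filter(late, "density"), "density")
  g_c <- centre_of_gravity(above_median_filter(late, "condition"), "condition")
  centre_lat <- mean(range(late$lat)); centre_lon <- mean(range(late$lon))
  expect_gt(g_d[["lat"]], centre_lat)
  expect_gt(g_d[["lon"]], centre_lon)
  expect_lt(g_c[["lat"]], g_d[["lat"]])
  expect_lt(g_c[["lon"]], g_d[["lon"]])
})

test_that("fish records close the loop back to per-cell condition", {
  cfg <- seascape_config(seed = 17, years = 3, n_rows = 4, n_cols = 4,
                         abundance = rep(300, 3), kappa = rep(1, 3),
                         fish_per_cell = 30, fish_noise_sd = 0)
  sim <- simulate_seascape(cfg)
  rounded <- round_measurements(sim$fish_records)
  # generative exponent is 3; with it, recovery error is bounded by the
  # 1 g weight rounding (lengths are emitted on the 0.5 cm grid already)
  b3 <- structure(list(b = 3), class = "lw_fit")
  rec <- condition_by_cell(rounded, b3)
  truth <- sim$observations[, c("year", "rect", "condition")]
  j <- dplyr::inner_join(rec, truth, by = c("year", "rect"))
  expect_equal(nrow(j), 3 * 16)
  w_min <- min(rounded$weight_g)
  expect_true(all(abs(j$condition.x / j$condition.y - 1) <= 0.5 / w_min))
})

test_that("zero fish per cell emits an empty record table", {
  cfg <- seascape_config(seed = 5, years = 2, abundance = c(1, 1),
                         kappa = c(0, 0), fish_per_cell = 0)
  sim <- simulate_seascape(cfg)
  expect_equal(nrow(sim$fish_records), 0)
})

test_that("density patchiness rises with the concentration parameter", {
  kappas <- c(0, 0.75, 1.5, 2.25, 3)
  mean_I <- vapply(kappas, function(k) {
    cfg <- seascape_config(seed = 400, years = 6,
                           abundance = rep(300, 6), kappa = rep(k, 6),
                           drift_start = c(1, 1), drift_end = c(1, 1),
                           fish_per_cell = 0)
    obs <- generate_density_maps(cfg)
    mean(moran_series(obs, "density")$I)
  }, numeric(1))
  expect_true(all(diff(mean_I) > 0))
})
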