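test_that("yearly means average the available cells", {
  obs <- tibble::tibble(year = c(2000L, 2000L, 2001L),
                        density = c(10, 30, 7),
                        condition = c(1, NA, 2))
  m <- yearly_means(obs)
  expect_equal(m$mean_density, c(20, 7))
  expect_equal(m$mean_condition, c(1, 2))  # missing condition cells skipped
  expect_equal(m$n_cells, c(2L, 1L))
})

test_that("perfect monotone coupling gives spatial rho of exactly +/-1", {
  set.seed(2)
  d <- rlnorm(12)
  obs <- tibble::tibble(year = 2000L, density = d, condition = 5 - sqrt(d))
  expect_equal(spatial_correlation_by_year(obs)$rho, -1)
  obs$condition <- d^3  # any strictly increasing transform
  expect_equal(spatial_correlation_by_year(obs)$rho, 1)
})

test_that("independent density and condition give small spatial rho", {
  set.seed(5)
  d <- rlnorm(40)
  obs <- tibble::tibble(year = 2000L, density = d, condition = sample(d))
  # |rho| below the simulated null 99.9% quantile at n = 40 (~0.45)
  expect_lt(abs(spatial_correlation_by_year(obs)$rho), 0.45)
})

test_that("years with too few complete pairs are omitted with a warning", {
  obs <- tibble::tibble(year = c(rep(2000L, 5), rep(2001L, 5)),
                        density = rep(1:5, 2),
                        condition = c(5:1, 2, 1, NA, NA, NA))
  expect_warning(out <- spatial_correlation_by_year(obs), "2001")
  expect_equal(out$year, 2000)
  expect_equal(out$rho, -1)
})

test_that("identical series give rho 1 with a vanishing p-value", {
  set.seed(1)
  x <- tibble::tibble(year = 2001:2020, value = cumsum(rnorm(20)))
  r <- adjusted_spearman(x, x)
  expect_equal(r$rho, 1)
  expect_equal(r$p_adjusted, 0)
  expect_lte(r$n_eff, r$n)
  expect_gte(r$n_eff, 2)
})

test_that("effective sample size shrinks for autocorrelated series only", {
  set.seed(31)
  n <- 25
  # strongly AR(1), phi = 0.9 in both series
  ar_x <- as.numeric(arima.sim(list(ar = 0.9), n))
  ar_y <- as.numeric(arima.sim(list(ar = 0.9), n))
  r_ar <- adjusted_spearman(ar_x, ar_y)
  expect_lt(r_ar$n_eff, n)
  # white noise keeps most of the sample
  r_wn <- adjusted_spearman(rnorm(n), rnorm(n))
  expect_gte(r_wn$n_eff, 0.7 * n)
  expect_lte(r_wn$n_eff, n)
  # direct recomputation of the estimator on the ranks
  J <- floor(n / 5)
  rx <- stats::acf(rank(ar_x), lag.max = J, plot = FALSE)$acf[-1]
  ry <- stats::acf(rank(ar_y), lag.max = J, plot = FALSE)$acf[-1]
  expect_equal(r_ar$n_eff,
               min(max(1 / (1 / n + (2 / n) * sum(rx * ry)), 2), n),
               tolerance = 1e-12)
})

test_that("adjustment never increases significance", {
  set.seed(12)
  for (i in 1:10) {
    x <- as.numeric(arima.sim(list(ar = 0.8), 25))
    y <- as.numeric(arima.sim(list(ar = 0.8), 25))
    r <- adjusted_spearman(x, y)
    expect_lte(r$n_eff, r$n)
    expect_gte(r$p_adjusted, r$p_raw - 1e-12)
  }
})

test_that("rank correlation ignores monotone transforms of either series", {
  set.seed(8)
  x <- rnorm(20); y <- rnorm(20)
  r0 <- adjusted_spearman(x, y)$rho
  expect_equal(adjusted_spearman(exp(x), y)$rho, r0)
  expect_equal(adjusted_spearman(x, y^3 + 5 * y)$rho, r0)
})

test_that("too short an overlap is refused", {
  a <- tibble::tibble(year = 2001:2004, value = 1:4)
  expect_error(adjusted_spearman(a, a), "insufficient")
})

test_that("permutation p-values agree with the t-approximation in rank", {
  set.seed(13)
  x <- rnorm(20)
  y <- x + rnorm(20, 0, 0.4)     # strong association
  y2 <- rnorm(20)                # none
  expect_lt(spearman_permutation_p(x, y), 0.01)
  expect_gt(spearman_permutation_p(x, y2), 0.05)
})

test_that("headline associations are reported for every pair", {
  sim <- simulate_seascape(seascape_config(seed = 99, fish_per_cell = 0))
  obs <- sim$observations
  assoc <- headline_associations(
    yearly_means(obs),
    cog_series(obs, "density"),
    cog_series(obs, "condition"),
    spatial_correlation_by_year(obs),
    moran_series(obs))
  expect_equal(nrow(assoc), 8)
  expect_true(all(abs(assoc$rho) <= 1, na.rm = TRUE))
  expect_true(all(assoc$n_eff <= assoc$n, na.rm = TRUE))
  # the generator builds in the negative density-condition coupling
  expect_lt(assoc$rho[assoc$pair == "mean_density_vs_mean_condition"], 0)
})

test_that("single-year input propagates insufficient-data markers", {
  sim <- simulate_seascape(seascape_config(seed = 99, years = 2,
                                           abundance = c(100, 100),
                                           kappa = c(0, 0),
                                           fish_per_cell = 0))
  obs <- sim$observations
  assoc <- suppressWarnings(headline_associations(
    yearly_means(obs),
    cog_series(obs, "density"),
    cog_series(obs, "condition"),
    spatial_correlation_by_year(obs),
    moran_series(obs)))
  expect_true(all(is.na(assoc$rho)))
})
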