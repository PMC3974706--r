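#' Yearly means of density and condition over the survey area
#'
#' Unweighted mean over the rectangles available each year; rectangles lacking
#' condition contribute to the density mean only.
#'
#' @param obs Observation tibble (`year, density[, condition]`).
#' @return Tibble `year, mean_density, mean_condition, n_cells`.
#' @export
yearly_means <- function(obs) {
  stopifnot(nrow(obs) >= 1)
  has_cond <- "condition" %in% names(obs)
  obs |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      mean_density = mean(.data$density, na.rm = TRUE),
      mean_condition = if (has_cond) mean(.data$condition, na.rm = TRUE)
                       else NA_real_,
      n_cells = dplyr::n(),
      .groups = "drop") |>
    dplyr::arrange(.data$year)
}

#' Per-year spatial correlation between density and condition
#'
#' For each year, Spearman's rank correlation of density against condition
#' across the rectangles (pairwise-complete: cells lacking either value are
#' dropped). Years with fewer than `min_pairs` complete cells are omitted
#' with a warning.
#'
#' @param obs Observation tibble with both `density` and `condition`.
#' @param min_pairs Minimum complete cells per year (default 4).
#' @return Tibble `year, rho, n_cells`.
#' @export
spatial_correlation_by_year <- function(obs, min_pairs = 4) {
  stopifnot(all(c("density", "condition") %in% names(obs)))
  res <- obs |>
    dplyr::filter(!is.na(.data$density), !is.na(.data$condition)) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     rho = if (dplyr::n() >= min_pairs)
                       stats::cor(.data$density, .data$condition,
                                  method = "spearman")
                     else NA_real_,
                     .groups = "drop")
  dropped <- res$year[is.na(res$rho)]
  if (length(dropped) > 0) {
    warning("years omitted (fewer than ", min_pairs, " complete cells): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  res |>
    dplyr::filter(!is.na(.data$rho)) |>
    dplyr::select("year", "rho", "n_cells")
}

# Effective sample size for a correlation between two autocorrelated series
# (modified Chelton estimator): 1/n_eff = 1/n + (2/n) * sum_j rxx(j) ryy(j),
# lags 1..max_lag. Autocorrelations are computed on the ranks, consistent
# with testing a Spearman coefficient.
effective_n <- function(x, y, max_lag = floor(length(x) / 5)) {
  n <- length(x)
  if (max_lag < 1) return(n)
  rx <- stats::acf(rank(x), lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[-1]
  ry <- stats::acf(rank(y), lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[-1]
  n_eff <- 1 / (1 / n + (2 / n) * sum(rx * ry))
  min(max(n_eff, 2), n)
}

#' Spearman correlation with autocorrelation-adjusted significance
#'
#' Rank correlation between two year-indexed series, with the significance
#' test corrected for serial autocorrelation by replacing n with an effective
#' sample size: 1/n_eff = 1/n + (2/n) * sum_{j=1}^{floor(n/5)} r_xx(j) r_yy(j)
#' (modified Chelton estimator; autocorrelations taken on the ranks). The
#' p-value uses the t-approximation with n_eff - 2 degrees of freedom, which
#' accepts fractional df; `p_raw` is the same test at the nominal n.
#'
#' @param x,y Tibbles with columns `year` and `value`, or plain numeric
#'   vectors of equal length (then assumed aligned).
#' @param max_lag Lag truncation for the estimator; default `floor(n/5)`.
#' @return Tibble `rho, n, n_eff, p_raw, p_adjusted`.
#' @export
adjusted_spearman <- function(x, y, max_lag = NULL) {
  if (is.data.frame(x)) {
    j <- dplyr::inner_join(x, y, by = "year", suffix = c("_x", "_y")) |>
      dplyr::arrange(.data$year)
    xv <- j$value_x
    yv <- j$value_y
  } else {
    stopifnot(length(x) == length(y))
    xv <- x
    yv <- y
  }
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 5) stop("insufficient data: need >= 5 overlapping years", call. = FALSE)
  rho <- stats::cor(xv, yv, method = "spearman")
  if (is.null(max_lag)) max_lag <- floor(n / 5)
  n_eff <- effective_n(xv, yv, max_lag)
  tibble::tibble(rho = rho, n = n, n_eff = n_eff,
                 p_raw = spearman_t_p(rho, n),
                 p_adjusted = spearman_t_p(rho, n_eff))
}

# two-sided p for Spearman rho via the t-approximation with n - 2 df;
# n may be fractional (adjusted df)
spearman_t_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Permutation p-value for an (unadjusted) Spearman correlation
#'
#' Companion to [adjusted_spearman()] for small-n checks where the
#' t-approximation is doubtful; permutes one series.
#'
#' @param x,y Numeric vectors.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return Two-sided permutation p-value.
#' @export
spearman_permutation_p <- function(x, y, n_perm = 999, seed = 1) {
  obs <- stats::cor(x, y, method = "spearman")
  set.seed(seed)
  null <- replicate(n_perm, stats::cor(x, sample(y), method = "spearman"))
  (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
}

#' The headline association tests of the pipeline
#'
#' Given the series the pipeline produces, runs the autocorrelation-adjusted
#' Spearman tests that summarise spatial density-dependence:
#' yearly mean density vs mean condition; latitude and longitude of the
#' density centre of gravity vs those of the condition centre; the yearly
#' spatial density-condition correlation vs mean density; Moran's I of
#' density vs mean density; and the centre-of-gravity separation vs year
#' (total distance in degree space, plus the absolute latitude and longitude
#' components).
#'
#' @param means [yearly_means()] output.
#' @param cogs_density,cogs_condition [cog_series()] outputs.
#' @param spatial_rho [spatial_correlation_by_year()] output.
#' @param moran [moran_series()] output.
#' @return Tibble `pair, rho, n, n_eff, p_raw, p_adjusted`; pairs whose
#'   series overlap on fewer than 5 years are reported with NA statistics.
#' @export
headline_associations <- function(means, cogs_density, cogs_condition,
                                  spatial_rho, moran) {
  sep <- cog_separation(cogs_density, cogs_condition)
  series <- function(d, col) tibble::tibble(year = d$year, value = d[[col]])
  cogs_d <- dplyr::filter(cogs_density, !.data$excluded)
  cogs_c <- dplyr::filter(cogs_condition, !.data$excluded)
  moran_d <- dplyr::filter(moran, .data$variable == "density")
  pairs <- list(
    mean_density_vs_mean_condition =
      list(series(means, "mean_density"), series(means, "mean_condition")),
    cog_lat_density_vs_condition =
      list(series(cogs_d, "lat"), series(cogs_c, "lat")),
    cog_lon_density_vs_condition =
      list(series(cogs_d, "lon"), series(cogs_c, "lon")),
    spatial_rho_vs_mean_density =
      list(series(spatial_rho, "rho"), series(means, "mean_density")),
    moran_density_vs_mean_density =
      list(series(moran_d, "I"), series(means, "mean_density")),
    cog_separation_vs_year =
      list(tibble::tibble(year = sep$year,
                          value = sqrt(sep$dlat^2 + sep$dlon^2)),
           tibble::tibble(year = sep$year, value = sep$year)),
    cog_separation_lat_vs_year =
      list(series(sep, "abs_dlat"), tibble::tibble(year = sep$year,
                                                   value = sep$year)),
    cog_separation_lon_vs_year =
      list(series(sep, "abs_dlon"), tibble::tibble(year = sep$year,
                                                   value = sep$year))
  )
  rows <- lapply(names(pairs), function(nm) {
    res <- tryCatch(adjusted_spearman(pairs[[nm]][[1]], pairs[[nm]][[2]]),
                    error = function(e) tibble::tibble(
                      rho = NA_real_, n = NA_integer_, n_eff = NA_real_,
                      p_raw = NA_real_, p_adjusted = NA_real_))
    dplyr::mutate(res, pair = nm, .before = 1)
  })
  dplyr::bind_rows(rows)
}
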