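#' Restrict a yearly map to cells above the within-year median
#'
#' Focuses the centre-of-gravity analysis on the region of *maximum* density
#' (or condition): only cells whose value is strictly greater than that year's
#' median are retained, so ties at the median drop out. If every cell carries
#' the same value the year is degenerate (no "above" exists) and an empty
#' subset is returned with a warning.
#'
#' @param map Tibble with one year's observations (`lat`, `lon` and the
#'   variable column).
#' @param variable Column name, `"density"` or `"condition"`.
#' @return The subset of rows above the median.
#' @export
above_median_filter <- function(map, variable) {
  v <- map[[variable]]
  stopifnot(!is.null(v))
  keep <- !is.na(v)
  v <- v[keep]
  map <- map[keep, , drop = FALSE]
  if (length(v) < 2) stop("need at least 2 cells with ", variable, call. = FALSE)
  out <- map[v > stats::median(v), , drop = FALSE]
  if (nrow(out) == 0) {
    warning("degenerate year: no values above the median of ", variable,
            call. = FALSE)
  }
  out
}

#' Weighted centre of gravity of a map
#'
#' The average of cell-centre latitudes and longitudes, weighted by the chosen
#' variable: (sum(w*lat)/sum(w), sum(w*lon)/sum(w)).
#'
#' @param map Tibble with `lat`, `lon` and the weight variable.
#' @param variable Weight column name.
#' @return Named numeric vector `c(lat =, lon =)`.
#' @export
centre_of_gravity <- function(map, variable) {
  w <- map[[variable]]
  stopifnot(nrow(map) >= 1, !is.null(w), all(w >= 0))
  if (sum(w) == 0) stop("undefined centre of gravity: all weights zero",
                        call. = FALSE)
  c(lat = sum(w * map$lat) / sum(w), lon = sum(w * map$lon) / sum(w))
}

#' Centre of gravity with leave-one-out confidence interval
#'
#' Applies the above-median restriction, then recomputes the centre of gravity
#' with each cell deleted in turn ("minus one data value", enumerated over
#' every cell, so the procedure is deterministic). The point estimate is the
#' coordinate-wise median of the n leave-one-out centres and the confidence
#' interval the percentile interval of that distribution. Years whose
#' above-median subset has fewer than `min_cells` cells lack the spatial
#' coverage for a stable centre and return an exclusion marker instead.
#'
#' @param map One year's observations.
#' @param variable Weight variable (`"density"` or `"condition"`).
#' @param min_cells Minimum above-median cells required (default 10).
#' @param level Confidence level (default 0.95).
#' @return One-row tibble `year, variable, lat, lon, lat_lo, lat_hi, lon_lo,
#'   lon_hi, n_used, excluded`.
#' @export
jackknife_cog <- function(map, variable, min_cells = 10, level = 0.95) {
  year <- map$year[1]
  sub <- above_median_filter(map, variable)
  n <- nrow(sub)
  if (n < min_cells) {
    return(tibble::tibble(year = year, variable = variable,
                          lat = NA_real_, lon = NA_real_,
                          lat_lo = NA_real_, lat_hi = NA_real_,
                          lon_lo = NA_real_, lon_hi = NA_real_,
                          n_used = n, excluded = TRUE))
  }
  loo <- vapply(seq_len(n),
                function(i) centre_of_gravity(sub[-i, , drop = FALSE], variable),
                numeric(2))
  alpha <- (1 - level) / 2
  ci_lat <- stats::quantile(loo["lat", ], c(alpha, 1 - alpha), names = FALSE)
  ci_lon <- stats::quantile(loo["lon", ], c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(year = year, variable = variable,
                 lat = stats::median(loo["lat", ]),
                 lon = stats::median(loo["lon", ]),
                 lat_lo = ci_lat[1], lat_hi = ci_lat[2],
                 lon_lo = ci_lon[1], lon_hi = ci_lon[2],
                 n_used = n, excluded = FALSE)
}

#' Centre-of-gravity series for all years of an observation table
#'
#' @param obs Observation tibble (`year, rect, lat, lon, density[, condition]`).
#' @param variable Weight variable.
#' @inheritParams jackknife_cog
#' @return Tibble of [jackknife_cog()] rows, one per year with the variable
#'   present.
#' @export
cog_series <- function(obs, variable, min_cells = 10, level = 0.95) {
  obs |>
    dplyr::filter(!is.na(.data[[variable]])) |>
    dplyr::group_by(.data$year) |>
    dplyr::group_map(~ jackknife_cog(.x |> dplyr::mutate(year = .y$year),
                                     variable, min_cells, level)) |>
    dplyr::bind_rows()
}

#' Separation between two centre-of-gravity trajectories
#'
#' Per-year signed and absolute differences, coordinate by coordinate, between
#' two centre-of-gravity series (e.g. density vs condition). Years are matched
#' by inner join; excluded years drop out.
#'
#' @param cogs_a,cogs_b Tibbles from [cog_series()] (or any tibble with
#'   `year, lat, lon`).
#' @return Tibble `year, dlat, dlon, abs_dlat, abs_dlon` (a minus b).
#' @export
cog_separation <- function(cogs_a, cogs_b) {
  a <- dplyr::filter(cogs_a, !is.na(.data$lat))
  b <- dplyr::filter(cogs_b, !is.na(.data$lat))
  j <- dplyr::inner_join(a, b, by = "year", suffix = c("_a", "_b"))
  if (nrow(j) == 0) {
    warning("no overlapping years between the two series", call. = FALSE)
    return(tibble::tibble(year = integer(), dlat = double(), dlon = double(),
                          abs_dlat = double(), abs_dlon = double()))
  }
  tibble::tibble(year = j$year,
                 dlat = j$lat_a - j$lat_b,
                 dlon = j$lon_a - j$lon_b,
                 abs_dlat = abs(j$lat_a - j$lat_b),
                 abs_dlon = abs(j$lon_a - j$lon_b))
}
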