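#' Read an observation table
#'
#' Accepts `year,rect,density[,condition]` (coordinates derived from the
#' rectangle code) or `year,lat,lon,density[,condition]`.
#'
#' @param path CSV file path.
#' @return Observation tibble `year, rect, lat, lon, density[, condition]`.
#' @export
read_observations <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE)
  if ("rect" %in% names(obs) && !all(c("lat", "lon") %in% names(obs))) {
    cc <- rect_to_centre(obs$rect)
    obs$lat <- cc$lat
    obs$lon <- cc$lon
  }
  stopifnot(all(c("year", "lat", "lon", "density") %in% names(obs)))
  if (!"rect" %in% names(obs)) obs$rect <- centre_to_rect(obs$lat, obs$lon)
  dplyr::relocate(obs, "year", "rect", "lat", "lon", "density")
}

#' Validate an input CSV against the pipeline schema
#'
#' Row-level checks for observation tables (`year,rect,density[,condition]`
#' or `year,lat,lon,...`) and fish-record tables (`year,rect,length_mm,
#' weight_g`): parseable rectangle codes, non-negative density, positive
#' length/weight, numeric fields.
#'
#' @param path CSV file path.
#' @param schema `"observations"` or `"fish_records"`.
#' @return List of class `validation_report`: `ok` (logical), `n_rows`,
#'   `issues` (tibble `line, column, problem`; `line` counts data rows from
#'   1, header excluded).
#' @export
validate_inputs <- function(path, schema = c("observations", "fish_records")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  issues <- list()
  flag <- function(rows, column, problem) {
    if (length(rows) > 0) {
      issues[[length(issues) + 1]] <<- tibble::tibble(
        line = rows, column = column, problem = problem)
    }
  }
  need <- if (schema == "observations") {
    if (all(c("lat", "lon") %in% names(d))) c("year", "lat", "lon", "density")
    else c("year", "rect", "density")
  } else c("year", "rect", "length_mm", "weight_g")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    flag(0L, missing_cols, "missing column")
  } else {
    num_cols <- setdiff(need, "rect")
    for (col in num_cols) {
      v <- suppressWarnings(as.numeric(d[[col]]))
      flag(which(is.na(v)), col, "non-numeric or missing")
      if (col == "density") flag(which(v < 0), col, "negative density")
      if (col %in% c("length_mm", "weight_g")) {
        flag(which(v <= 0), col, "non-positive measurement")
      }
    }
    if ("rect" %in% names(d)) {
      bad <- which(is.na(d$rect) | !grepl("^[0-9]{2}[A-HJ-M][0-9]$", d$rect))
      flag(bad, "rect", "invalid ICES rectangle code")
    }
  }
  issues <- dplyr::bind_rows(issues)
  structure(list(ok = nrow(issues) == 0, n_rows = nrow(d), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation: %s (%d rows, %d issues)\n",
              if (x$ok) "PASS" else "FAIL", x$n_rows, nrow(x$issues)))
  if (!x$ok) print(x$issues)
  invisible(x)
}

#' Run configuration for the analysis pipeline
#'
#' @param length_window Condition length window in mm (inclusive).
#' @param min_cells Minimum above-median cells for a centre-of-gravity year.
#' @param ci_level Confidence level for leave-one-out intervals.
#' @param min_pairs Minimum complete cells for a yearly spatial correlation.
#' @param max_lag_rule Lag truncation for the effective-df estimator, as a
#'   function of n; default `floor(n/5)`.
#' @return List of class `run_config`.
#' @export
run_config <- function(length_window = c(120, 130), min_cells = 10,
                       ci_level = 0.95, min_pairs = 4,
                       max_lag_rule = function(n) floor(n / 5)) {
  stopifnot(ci_level > 0, ci_level < 1, min_cells >= 3)
  structure(list(length_window = length_window, min_cells = min_cells,
                 ci_level = ci_level, min_pairs = min_pairs,
                 max_lag_rule = max_lag_rule),
            class = "run_config")
}

#' Run the full density-dependence analysis
#'
#' Orchestrates condition computation (if fish records are supplied),
#' centre-of-gravity series with leave-one-out intervals, centre separation,
#' Moran's I patchiness, yearly means, per-year spatial correlations, and the
#' headline association tests. Everything downstream of the inputs is
#' deterministic: the jackknife is an exact enumeration and no RNG is used.
#'
#' If `fish_records` is supplied, condition is recomputed from it and
#' overrides any `condition` column already present in `obs` (with a
#' warning).
#'
#' @param obs Observation tibble or CSV path.
#' @param fish_records Optional fish-record tibble or CSV path.
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, all result tables are
#'   written as CSV plus a `manifest.json`.
#' @return List with `observations`, `lw_fit`, `yearly_means`, `cog`,
#'   `cog_separation`, `moran`, `spatial_rho`, `associations`, `manifest`.
#' @export
run_analysis <- function(obs, fish_records = NULL, config = run_config(),
                         outdir = NULL) {
  if (is.character(obs)) obs <- read_observations(obs)
  obs <- tibble::as_tibble(obs)
  stopifnot(all(c("year", "lat", "lon", "density") %in% names(obs)))
  lw <- NULL
  if (!is.null(fish_records)) {
    if (is.character(fish_records)) {
      fish_records <- readr::read_csv(fish_records, show_col_types = FALSE)
    }
    if ("condition" %in% names(obs)) {
      warning("fish records supplied: recomputed condition overrides the ",
              "condition column in the observation table", call. = FALSE)
      obs$condition <- NULL
    }
    rounded <- round_measurements(fish_records)
    lw <- fit_length_weight(rounded)
    cond <- condition_by_cell(rounded, lw, config$length_window)
    obs <- dplyr::left_join(obs, cond[, c("year", "rect", "condition")],
                            by = c("year", "rect"))
  }
  has_cond <- "condition" %in% names(obs)

  means <- yearly_means(obs)
  cog_d <- cog_series(obs, "density", config$min_cells, config$ci_level)
  cog_c <- if (has_cond) {
    cog_series(obs, "condition", config$min_cells, config$ci_level)
  } else cog_d[0, ]
  sep <- if (has_cond) suppressWarnings(cog_separation(cog_d, cog_c)) else NULL
  moran <- moran_series(obs)
  srho <- if (has_cond) {
    suppressWarnings(spatial_correlation_by_year(obs, config$min_pairs))
  } else tibble::tibble(year = integer(), rho = double(), n_cells = integer())
  assoc <- if (has_cond && nrow(srho) >= 5) {
    headline_associations(means, cog_d, cog_c, srho, moran)
  } else NULL

  excluded <- dplyr::bind_rows(cog_d, cog_c) |>
    dplyr::filter(.data$excluded) |>
    dplyr::transmute(.data$year, .data$variable,
                     reason = sprintf("above-median cells %d < min_cells %d",
                                      .data$n_used, config$min_cells))
  manifest <- list(
    package_version = as.character(utils::packageVersion("seascapeDD")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = list(length_window = config$length_window,
                  min_cells = config$min_cells, ci_level = config$ci_level,
                  min_pairs = config$min_pairs),
    n_observations = nrow(obs),
    years = sort(unique(obs$year)),
    excluded_years = excluded)

  result <- list(observations = obs, lw_fit = lw, yearly_means = means,
                 cog = dplyr::bind_rows(cog_d, cog_c),
                 cog_separation = sep, moran = moran, spatial_rho = srho,
                 associations = assoc, manifest = manifest)
  if (!is.null(outdir)) write_results(result, outdir)
  result
}

#' Write a result bundle to disk
#'
#' One CSV per table plus `manifest.json`; byte-identical across reruns on
#' identical inputs.
#'
#' @param result Output of [run_analysis()].
#' @param outdir Directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_results <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, name) {
    if (!is.null(d) && nrow(d) > 0) {
      readr::write_csv(d, file.path(outdir, name))
    }
  }
  w(result$yearly_means, "yearly_means.csv")
  w(result$cog, "cog.csv")
  w(result$cog_separation, "cog_separation.csv")
  w(result$moran, "moran.csv")
  w(result$spatial_rho, "spatial_rho.csv")
  w(result$associations, "associations.csv")
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
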