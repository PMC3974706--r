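#' Distance-decay spatial weight matrix
#'
#' w_ij = 1 - d_ij / d_max, with d the Euclidean distance between cell centres
#' in (lat, lon) degree space and d_max the largest distance observed among
#' the supplied points. The diagonal is forced to zero (self-pairs are
#' excluded from the index) and the most distant pair gets weight zero, so all
#' entries lie in [0, 1]. d_max is taken per map: each yearly map carries its
#' own weight matrix.
#'
#' @param coords Matrix or data.frame with columns `lat`, `lon` (>= 2 distinct
#'   points).
#' @return Symmetric n x n weight matrix.
#' @export
moran_weights <- function(coords) {
  coords <- as.data.frame(coords)
  stopifnot(all(c("lat", "lon") %in% names(coords)), nrow(coords) >= 2)
  d <- as.matrix(stats::dist(coords[, c("lat", "lon")]))
  dmax <- max(d)
  if (dmax == 0) stop("all points coincident: maximum distance is zero",
                      call. = FALSE)
  w <- 1 - d / dmax
  diag(w) <- 0
  w
}

#' Moran's I spatial autocorrelation index
#'
#' I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2,
#' with S0 the sum of all weights. Used here as a patchiness proxy: values
#' toward 1 indicate clustering into large patches, values toward -1
#' dispersion; the null expectation under no spatial structure is -1/(n-1).
#'
#' @param values Numeric vector (one value per point; variance must be > 0).
#' @param weights Weight matrix from [moran_weights()].
#' @return List of class `moran_result`: `I`, `n`, `expected_null`.
#' @export
moran_i <- function(values, weights) {
  n <- length(values)
  stopifnot(n >= 3, is.matrix(weights), all(dim(weights) == n))
  dev <- values - mean(values)
  denom <- sum(dev^2)
  if (denom == 0) stop("undefined Moran's I: values have zero variance",
                       call. = FALSE)
  s0 <- sum(weights)
  i <- (n / s0) * as.numeric(dev %*% weights %*% dev) / denom
  structure(list(I = i, n = n, expected_null = -1 / (n - 1)),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (n = %d, E[I] under null = %.4f)\n",
              x$I, x$n, x$expected_null))
  invisible(x)
}

#' Moran's I per year and variable over an observation table
#'
#' @param obs Observation tibble (`year, lat, lon, density[, condition]`).
#' @param variables Columns to index (default both density and condition
#'   where present).
#' @return Tibble `year, variable, I, n, expected_null`; years where a
#'   variable is constant or has < 3 cells are skipped.
#' @export
moran_series <- function(obs, variables = intersect(c("density", "condition"),
                                                    names(obs))) {
  res <- list()
  for (yr in sort(unique(obs$year))) {
    map <- obs[obs$year == yr, , drop = FALSE]
    for (v in variables) {
      x <- map[[v]]
      keep <- !is.na(x)
      if (sum(keep) < 3 || stats::var(x[keep]) == 0) next
      w <- moran_weights(map[keep, c("lat", "lon")])
      m <- moran_i(x[keep], w)
      res[[length(res) + 1]] <- tibble::tibble(
        year = yr, variable = v, I = m$I, n = m$n,
        expected_null = m$expected_null)
    }
  }
  dplyr::bind_rows(res)
}
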