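#' Apply survey measurement conventions to raw fish records
#'
#' Survey measurement protocol: body weight is recorded to the nearest gram
#' (exact halves round up) and total length is recorded *down* to the nearest
#' 0.5 cm. Lengths are stored in mm throughout, so the length rule is a floor
#' to the nearest 5 mm.
#'
#' Records with non-positive length or weight cannot be measured fish; they are
#' dropped and reported via the `"rejected"` attribute (a tibble with a
#' `reason` column) and a warning.
#'
#' @param records Tibble/data.frame with columns `year`, `rect`, `length_mm`,
#'   `weight_g` (raw measurements).
#' @return The records with `length_mm` and `weight_g` rounded per protocol.
#'   Rejected rows are attached as `attr(, "rejected")`.
#' @examples
#' round_measurements(tibble::tibble(
#'   year = 2000, rect = "44G6", length_mm = 127, weight_g = 13.4
#' ))
#' @export
round_measurements <- function(records) {
  stopifnot(all(c("length_mm", "weight_g") %in% names(records)))
  records <- tibble::as_tibble(records)
  bad_len <- !is.finite(records$length_mm) | records$length_mm <= 0
  bad_wt <- !is.finite(records$weight_g) | records$weight_g <= 0
  bad <- bad_len | bad_wt
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- ifelse(bad_len[bad], "non-positive length",
                              "non-positive weight")
    warning(sprintf("%d record(s) rejected (non-positive length/weight)",
                    nrow(rejected)), call. = FALSE)
  }
  out <- records[!bad, , drop = FALSE]
  # half-up at exact .5 g; round() would round half-to-even
  out$weight_g <- floor(out$weight_g + 0.5)
  # floor to 0.5 cm == floor to 5 mm; nudge guards against 12.5cm stored as
  # 124.99999999 after upstream unit conversions
  out$length_mm <- floor(out$length_mm / 5 + 1e-9) * 5
  attr(out, "rejected") <- rejected
  out
}

#' Fit the pooled ln-ln length-weight relationship
#'
#' Ordinary least-squares regression of ln(weight) on ln(length in cm), pooled
#' across all years and cells. The slope `b` is the allometric exponent used in
#' Fulton's condition factor K = TW / TL^b.
#'
#' @param records Rounded fish records (see [round_measurements()]).
#' @return Object of class `lw_fit`: list with `b`, `intercept` (log-scale,
#'   length in cm), `n`, `r_squared`.
#' @export
fit_length_weight <- function(records) {
  stopifnot(nrow(records) >= 3)
  len_cm <- records$length_mm / 10
  if (length(unique(len_cm)) < 2) {
    stop("degenerate length-weight fit: all lengths identical", call. = FALSE)
  }
  y <- log(records$weight_g)
  fit <- stats::lm(y ~ log(len_cm))
  # R^2 computed directly; summary.lm() warns on exact power-law input
  tss <- sum((y - mean(y))^2)
  structure(
    list(
      b = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      n = nrow(records),
      r_squared = if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
    ),
    class = "lw_fit"
  )
}

#' @export
print.lw_fit <- function(x, ...) {
  cat(sprintf("Length-weight fit: b = %.4f, ln-intercept = %.4f, n = %d, R^2 = %.4f\n",
              x$b, x$intercept, x$n, x$r_squared))
  invisible(x)
}

#' Fulton's condition factor
#'
#' K = TW / TL^b with TW in g and TL in cm. No x100 scaling constant is
#' applied; all downstream comparisons are rank-based, so the scale of K is
#' immaterial (see the methods vignette).
#'
#' @param weight_g Total weight (g).
#' @param length_cm Total length (cm).
#' @param b Allometric exponent, usually from [fit_length_weight()].
#' @return Numeric vector of condition values.
#' @export
fulton_k <- function(weight_g, length_cm, b) {
  if (any(length_cm <= 0)) stop("length must be positive", call. = FALSE)
  if (any(weight_g <= 0)) stop("weight must be positive", call. = FALSE)
  weight_g / length_cm^b
}

#' Mean condition per (year, rectangle)
#'
#' Restricts to the reference length window (default 120-130 mm inclusive,
#' the modal size class present in all years and rectangles) and averages
#' Fulton's K per (year, rect). Cells with no in-window fish are absent from
#' the output, never reported as zero.
#'
#' @param records Rounded fish records.
#' @param fit A `lw_fit` (for the exponent `b`).
#' @param length_window Inclusive window in mm, default `c(120, 130)`.
#' @return Tibble `year, rect, condition, n_fish`.
#' @export
condition_by_cell <- function(records, fit, length_window = c(120, 130)) {
  if (nrow(records) == 0) {
    warning("no fish records supplied", call. = FALSE)
    return(tibble::tibble(year = integer(), rect = character(),
                          condition = double(), n_fish = integer()))
  }
  stopifnot(inherits(fit, "lw_fit"), length(length_window) == 2)
  records |>
    dplyr::filter(.data$length_mm >= length_window[1],
                  .data$length_mm <= length_window[2]) |>
    dplyr::mutate(k = fulton_k(.data$weight_g, .data$length_mm / 10, fit$b)) |>
    dplyr::group_by(.data$year, .data$rect) |>
    dplyr::summarise(condition = mean(.data$k), n_fish = dplyr::n(),
                     .groups = "drop")
}
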