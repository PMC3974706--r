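#' Centre coordinates of an ICES statistical rectangle
#'
#' ICES statistical rectangles are 0.5 degrees of latitude by 1 degree of
#' longitude, coded `RRLd`: a two-digit row counted in 0.5-degree steps
#' northwards from 36 degrees N (row 01 spans 36-36.5 N), then a column
#' letter-digit where letters label 10-degree longitude blocks eastwards
#' (A covers 44-40 W and carries digits 0-3 only; B starts at 40 W; the
#' letter I is never used) and the digit the 1-degree column within the
#' block (F0 spans 0-1 E, G6 spans 16-17 E).
#'
#' @param code Character vector of rectangle codes, e.g. `"44G6"`.
#' @return Tibble `rect, lat, lon` with cell-centre coordinates.
#' @examples
#' rect_to_centre("44G6") # 57.75 N, 16.5 E
#' @export
rect_to_centre <- function(code) {
  code <- toupper(as.character(code))
  ok <- grepl("^[0-9]{2}[A-HJ-M][0-9]$", code)
  if (any(!ok)) {
    stop("malformed ICES rectangle code(s): ",
         paste(unique(code[!ok]), collapse = ", "), call. = FALSE)
  }
  row <- as.integer(substr(code, 1, 2))
  letter <- substr(code, 3, 3)
  digit <- as.integer(substr(code, 4, 4))
  if (any(row < 1)) {
    stop("rectangle row out of grid: rows start at 01 (36 degrees N)",
         call. = FALSE)
  }
  letters_used <- c("A", "B", "C", "D", "E", "F", "G", "H", "J", "K", "L", "M")
  idx <- match(letter, letters_used)
  # A block is truncated: only A0-A3 (44-40 W) exist
  if (any(idx == 1 & digit > 3)) {
    stop("rectangle column out of grid: A block carries digits 0-3 only",
         call. = FALSE)
  }
  lon_west <- ifelse(idx == 1, -44 + digit, (idx - 2) * 10 - 40 + digit)
  lat_south <- 36 + (row - 1) * 0.5
  tibble::tibble(rect = code, lat = lat_south + 0.25, lon = lon_west + 0.5)
}

#' ICES rectangle code for a coordinate
#'
#' Inverse of [rect_to_centre()] for points east of 40 W; used by the
#' synthetic seascape generator to label grid cells.
#'
#' @param lat,lon Coordinates (degrees N / degrees E) anywhere inside the cell.
#' @return Character vector of rectangle codes.
#' @export
centre_to_rect <- function(lat, lon) {
  stopifnot(all(lat >= 36), all(lat < 85.5), all(lon >= -44), all(lon < 70))
  row <- floor((lat - 36) / 0.5) + 1
  letters_used <- c("A", "B", "C", "D", "E", "F", "G", "H", "J", "K", "L", "M")
  col1 <- floor(lon) # 1-degree column, west edge
  idx <- ifelse(col1 < -40, 1, floor((col1 + 40) / 10) + 2)
  digit <- ifelse(idx == 1, col1 + 44, col1 - ((idx - 2) * 10 - 40))
  sprintf("%02d%s%d", row, letters_used[idx], digit)
}
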