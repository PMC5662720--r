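#' Construct a hydrophone array table
#'
#' A hydrophone array is a tibble with one row per receiver and columns
#' `hydro` (unique label), `x` and `y` (planar coordinates in meters).
#' All positioning functions take this table; coordinates must already be
#' projected (no geographic CRS handling is done).
#'
#' @param x,y Numeric vectors of receiver coordinates (m).
#' @param hydro Receiver labels; defaults to `h1, h2, ...`.
#' @return A tibble with columns `hydro`, `x`, `y`.
#' @examples
#' hydrophone_array(c(0, 100), c(0, 0))
#' @export
hydrophone_array <- function(x, y, hydro = paste0("h", seq_along(x))) {
  arr <- tibble::tibble(hydro = as.character(hydro), x = as.numeric(x), y = as.numeric(y))
  validate_array(arr)
}

#' The benchmark five-hydrophone array
#'
#' Five receivers on the corners and centre of a 100 x 100 m quadrant, the
#' layout used throughout the simulation benchmark.
#'
#' @return A tibble with columns `hydro`, `x`, `y` (5 rows).
#' @examples
#' benchmark_array()
#' @export
benchmark_array <- function() {
  hydrophone_array(x = c(0, 0, 100, 100, 50),
                   y = c(0, 100, 0, 100, 50))
}

validate_array <- function(array) {
  if (!is.data.frame(array) || !all(c("hydro", "x", "y") %in% names(array)))
    abort("`array` must be a data frame with columns hydro, x, y")
  array <- tibble::as_tibble(array)
  array$hydro <- as.character(array$hydro)
  if (nrow(array) < 1) abort("array must contain at least one hydrophone")
  if (anyDuplicated(array$hydro)) abort("hydrophone ids must be unique")
  if (!all(is.finite(array$x)) || !all(is.finite(array$y)))
    abort("hydrophone coordinates must be finite")
  array
}

#' Centroid of a hydrophone array
#'
#' The array centre used when reporting deviation as a function of distance
#' to the array: the mean of the receiver coordinates.
#'
#' @param array Hydrophone array table (see [hydrophone_array()]).
#' @return Named numeric vector `c(x =, y =)`.
#' @export
array_centre <- function(array) {
  array <- validate_array(array)
  c(x = mean(array$x), y = mean(array$y))
}
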