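#' Vocal-tract area function
#'
#' An area function describes the cross-sectional area of the tract as a
#' function of the axial distance from the glottis. It is the classical 1D
#' representation of tract geometry and the input both to the tube-mesh
#' generator ([build_tube_mesh()]) and to the 1D transmission-line solver
#' ([segment_chain()]).
#'
#' @param station Axial positions in m, strictly increasing, length >= 2.
#' @param area Cross-sectional areas in m2, all positive, same length as
#'   `station`.
#' @return An object of class `area_function`: a data frame with columns
#'   `station` and `area`.
#' @export
#' @examples
#' # a uniform 17.5 cm tube of 1.5 cm radius
#' area_function(c(0, 0.175), rep(pi * 0.015^2, 2))
area_function <- function(station, area) {
  station <- as.numeric(station)
  area <- as.numeric(area)
  if (length(station) < 2L)
    stop("an area function needs at least 2 stations")
  if (length(area) != length(station))
    stop("`station` and `area` must have the same length")
  if (any(!is.finite(station)) || any(!is.finite(area)))
    stop("stations and areas must be finite")
  if (any(diff(station) <= 0))
    stop("stations must be strictly increasing")
  if (any(area <= 0))
    stop("all areas must be positive")
  if (diff(range(station)) <= 0)
    stop("degenerate area function: zero axial length")
  structure(data.frame(station = station, area = area),
            class = c("area_function", "data.frame"))
}

#' Evaluate an area function by linear interpolation
#'
#' @param af An [area_function()].
#' @param x Axial positions in m (clamped to the station range).
#' @return Interpolated areas in m2.
#' @export
interp_area <- function(af, x) {
  stopifnot(inherits(af, "area_function"))
  stats::approx(af$station, af$area, xout = x, rule = 2)$y
}

#' @export
print.area_function <- function(x, ...) {
  cat(sprintf("<area_function> %d stations, length %.4g m, areas %.3g-%.3g m2\n",
              nrow(x), diff(range(x$station)), min(x$area), max(x$area)))
  invisible(x)
}
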