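#' Acoustic medium properties
#'
#' Properties of the air inside the tract. The defaults correspond to warm,
#' humid air as found in the vocal tract: a speed of sound of 350 m/s and a
#' density of 1.15 kg/m3.
#'
#' @param c Speed of sound in m/s.
#' @param rho0 Density in kg/m3.
#' @return An object of class `medium_props`.
#' @export
#' @examples
#' medium_props()
medium_props <- function(c = 350, rho0 = 1.15) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c), c > 0,
            is.numeric(rho0), length(rho0) == 1L, is.finite(rho0), rho0 > 0)
  structure(list(c = c, rho0 = rho0), class = "medium_props")
}

#' @export
print.medium_props <- function(x, ...) {
  cat(sprintf("<medium_props> c = %g m/s, rho0 = %g kg/m3\n", x$c, x$rho0))
  invisible(x)
}

as_medium <- function(medium) {
  if (is.null(medium)) return(medium_props())
  if (inherits(medium, "medium_props")) return(medium)
  if (is.list(medium) && all(c("c", "rho0") %in% names(medium)))
    return(medium_props(medium$c, medium$rho0))
  stop("`medium` must be created with medium_props()")
}
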