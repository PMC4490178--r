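#' One-dimensional segment chain of a tract
#'
#' Discretizes an area function into a stack of straightened uniform
#' cylinders for the classical transmission-line (chain-matrix) model.
#' Each segment carries a length, a cross-sectional area sampled at the
#' segment midpoint, and the perimeter of the equivalent circular section.
#' Serves as an independent low-order cross-check of the 3D FEM.
#'
#' @param area_fn An [area_function()].
#' @param wall A [wall_spec()]: wall admittance enters the line as a
#'   distributed shunt admittance per unit length, `perimeter / Z_wall(f)`.
#' @param radiation A [radiation_spec()] terminating the mouth end.
#' @param medium A [medium_props()].
#' @param n_segments Number of uniform segments (default 64).
#' @return An object of class `segment_chain`.
#' @export
segment_chain <- function(area_fn, wall = wall_spec("hard"),
                          radiation = radiation_spec("hard"),
                          medium = medium_props(), n_segments = 64L) {
  stopifnot(inherits(area_fn, "area_function"), n_segments >= 1L)
  L <- diff(range(area_fn$station))
  x0 <- min(area_fn$station)
  len <- rep(L / n_segments, n_segments)
  mid <- x0 + (seq_len(n_segments) - 0.5) * L / n_segments
  area <- interp_area(area_fn, mid)
  structure(list(length = len, area = area,
                 perimeter = 2 * sqrt(pi * area),
                 wall = wall, radiation = radiation,
                 medium = as_medium(medium)),
            class = "segment_chain")
}

#' Transfer function of a 1D segment chain
#'
#' For each frequency, each segment is a lossy transmission line with
#' series impedance per unit length `j w rho0 / A`, shunt admittance per
#' unit length `j w A / (rho0 c^2) + perimeter / Z_wall` (the yielding wall
#' adds to the compliance branch), chained by ABCD matrices from glottis to
#' mouth and terminated by the radiation impedance `Z_mouth / A_end`
#' (a `hard` radiation model blocks the mouth flow). The chain is driven by
#' a unit volume velocity at the glottis and the output is
#' `|p_mouth / (j w)|`, the same mouth-pressure-based magnitude the FEM
#' transfer function uses.
#'
#' @param chain A [segment_chain()].
#' @param sweep A [sweep_config()] (frequencies must be positive).
#' @return A [transfer_function()].
#' @export
chain_tf <- function(chain, sweep) {
  stopifnot(inherits(chain, "segment_chain"),
            inherits(sweep, "sweep_config"))
  freqs <- sweep_freqs(sweep)
  freqs <- freqs[freqs > 0]
  med <- chain$medium
  ns <- length(chain$length)
  wall_hard <- is_hard_wall(chain$wall)
  mouth_hard <- chain$radiation$model == "hard"
  if (!wall_hard) Zw <- z_wall(freqs, chain$wall)
  if (!mouth_hard) Zm <- z_radiation(freqs, chain$radiation, med)
  A_end <- chain$area[ns]

  mag <- numeric(length(freqs))
  for (k in seq_along(freqs)) {
    w <- 2 * pi * freqs[k]
    T11 <- 1 + 0i; T12 <- 0 + 0i; T21 <- 0 + 0i; T22 <- 1 + 0i
    for (s in seq_len(ns)) {
      A <- chain$area[s]
      zl <- 1i * w * med$rho0 / A
      yl <- 1i * w * A / (med$rho0 * med$c^2)
      if (!wall_hard) yl <- yl + chain$perimeter[s] / Zw[k]
      gam <- sqrt(zl * yl)
      Zc <- sqrt(zl / yl)
      gl <- gam * chain$length[s]
      ch <- cosh(gl); sh <- sinh(gl)
      a11 <- ch; a12 <- Zc * sh; a21 <- sh / Zc; a22 <- ch
      # accumulate glottis-side transfer: T <- T %*% Aseg
      t11 <- T11 * a11 + T12 * a21; t12 <- T11 * a12 + T12 * a22
      t21 <- T21 * a11 + T22 * a21; t22 <- T21 * a12 + T22 * a22
      T11 <- t11; T12 <- t12; T21 <- t21; T22 <- t22
    }
    if (mouth_hard) {
      # U_mouth = 0: take p_mouth = 1, scale by the glottal flow
      U_g <- T21
      p_mouth <- 1 / U_g
    } else {
      Za <- Zm[k] / A_end
      U_g <- T21 * Za + T22
      p_mouth <- Za / U_g
    }
    mag[k] <- Mod(p_mouth) / w
  }
  structure(list(freqs = freqs, magnitude = mag,
                 db = 20 * log10(mag / max(mag))),
            class = "transfer_function")
}
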