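#' Radiation boundary specification for the mouth opening
#'
#' Three radiation models approximate the load seen by the mouth opening:
#' \describe{
#'   \item{`sphere`}{a radiating half-sphere of the same cross-sectional
#'     area as the lip opening (absorption of spherical waves);}
#'   \item{`piston`}{a rigid circular piston in an infinite baffle
#'     (Bessel/Struve form);}
#'   \item{`lf_piston`}{the two-term low-frequency expansion of the piston;}
#'   \item{`hard`}{no radiation: the mouth is acoustically closed
#'     (homogeneous Neumann condition).}
#' }
#'
#' @param model One of `"sphere"`, `"piston"`, `"lf_piston"`, `"hard"`.
#' @param mouth_area Area of the mouth opening in m2 (required unless
#'   `model = "hard"`).
#' @return An object of class `radiation_spec`.
#' @export
radiation_spec <- function(model = c("sphere", "piston", "lf_piston", "hard"),
                           mouth_area = NULL) {
  model <- match.arg(model)
  if (model != "hard") {
    if (is.null(mouth_area) || !is.numeric(mouth_area) ||
        length(mouth_area) != 1L || !is.finite(mouth_area) || mouth_area <= 0)
      stop("`mouth_area` must be a positive scalar for model \"", model, "\"")
  }
  structure(list(model = model, mouth_area = mouth_area),
            class = "radiation_spec")
}

#' Equivalent radiator radius for a mouth opening
#'
#' The half-sphere model uses the radius of a hemisphere whose curved
#' cross-section equals the mouth area, `sqrt(A / (2*pi))`; the piston
#' models use the radius of a flat disk of the same area, `sqrt(A / pi)`.
#'
#' @param mouth_area Mouth-opening area in m2.
#' @param model Radiation model name (not `"hard"`).
#' @return Radius in m.
#' @export
#' @examples
#' radiation_radius(2 * pi, "sphere")  # 1 m
#' radiation_radius(pi, "piston")      # 1 m
radiation_radius <- function(mouth_area,
                             model = c("sphere", "piston", "lf_piston")) {
  if (identical(model, "hard"))
    stop("no radiator radius is defined for model \"hard\"")
  model <- match.arg(model)
  stopifnot(is.numeric(mouth_area), all(mouth_area > 0))
  if (model == "sphere") sqrt(mouth_area / (2 * pi)) else sqrt(mouth_area / pi)
}

#' Half-sphere radiation impedance
#'
#' Specific impedance of a radiating half-sphere of radius `r`:
#' `Z = rho0 c [ (kr)^2 / (1 + (kr)^2) + j kr / (1 + (kr)^2) ]` with
#' `k = 2 pi f / c`. Tends to 0 at f = 0 and to the plane-wave impedance
#' `rho0 c` as `kr -> Inf`.
#'
#' @param f Frequencies in Hz (vectorized).
#' @param r Radiator radius in m.
#' @param medium A [medium_props()].
#' @return Complex specific impedance in N s/m3.
#' @export
z_sphere <- function(f, r, medium = medium_props()) {
  medium <- as_medium(medium)
  stopifnot(all(f >= 0), r > 0)
  kr <- 2 * pi * f / medium$c * r
  medium$rho0 * medium$c * (kr^2 + 1i * kr) / (1 + kr^2)
}

#' Baffled rigid-piston radiation impedance
#'
#' Specific impedance of a rigid circular piston of radius `a` in an
#' infinite baffle:
#' `Z = rho0 c [ 1 - 2 J1(2ka)/(2ka) + j 2 H1(2ka)/(2ka) ]`,
#' with `J1` the Bessel function of the first kind and `H1` the Struve
#' function of order one (see [struve_h1()]).
#'
#' @inheritParams z_sphere
#' @param a Piston radius in m.
#' @return Complex specific impedance in N s/m3 (0 at f = 0).
#' @export
z_piston <- function(f, a, medium = medium_props()) {
  medium <- as_medium(medium)
  stopifnot(all(f >= 0), a > 0)
  x <- 2 * (2 * pi * f / medium$c) * a          # 2 k a
  z <- complex(length.out = length(x))
  pos <- x > 0
  xp <- x[pos]
  z[pos] <- (1 - 2 * besselJ(xp, 1) / xp) + 1i * (2 * struve_h1(xp) / xp)
  medium$rho0 * medium$c * z
}

#' Low-frequency piston radiation impedance
#'
#' Two-term small-argument expansion of [z_piston()]:
#' `Z = rho0 c [ (ka)^2 / 2 + j (8 / (3 pi)) ka ]`.
#'
#' @inheritParams z_piston
#' @return Complex specific impedance in N s/m3.
#' @export
z_lf_piston <- function(f, a, medium = medium_props()) {
  medium <- as_medium(medium)
  stopifnot(all(f >= 0), a > 0)
  ka <- 2 * pi * f / medium$c * a
  medium$rho0 * medium$c * (ka^2 / 2 + 1i * (8 / (3 * pi)) * ka)
}

#' Struve function H1
#'
#' The Struve function of order one, needed for the reactive part of the
#' baffled-piston impedance. Evaluated by its ascending power series for
#' `x <= 25` and by the asymptotic expansion `H1(x) = Y1(x) + (2/pi)(1 +
#' 1/x^2 - 3/x^4 + 45/x^6 - ...)` beyond, keeping the relative error below
#' about 1e-8 across the switchover.
#'
#' @param x Nonnegative argument (vectorized).
#' @return `H1(x)`.
#' @export
struve_h1 <- function(x) {
  stopifnot(all(x >= 0))
  out <- numeric(length(x))
  small <- x <= 25
  if (any(small)) {
    xs <- x[small]
    # H1(x) = sum_{k>=0} (-1)^k (x/2)^(2k+2) / (Gamma(k+3/2) Gamma(k+5/2))
    term <- (xs / 2)^2 / (gamma(1.5) * gamma(2.5))
    acc <- term
    for (k in seq_len(60L)) {
      term <- -term * (xs / 2)^2 / ((k + 0.5) * (k + 1.5))
      acc <- acc + term
      if (all(abs(term) < 1e-17 * (abs(acc) + 1))) break
    }
    out[small] <- acc
  }
  if (any(!small)) {
    xl <- x[!small]
    # asymptotic: H1 - Y1 ~ (1/pi) sum_k Gamma(k+1/2)/Gamma(3/2-k) (x/2)^(-2k)
    s <- 2 + 2 / xl^2 - 6 / xl^4 + 90 / xl^6 - 3150 / xl^8 + 198450 / xl^10
    out[!small] <- besselY(xl, 1) + s / pi
  }
  out
}

#' Mass-damper wall impedance specification
#'
#' The yielding tract wall is modelled as an array of independent local
#' mass-damper elements normalised by the wall area:
#' `Z_wall(f) = b/A + j 2 pi f m/A`, with areal damping `b/A` in N s/m3 and
#' areal mass `m/A` in kg/m2. Either parameter may be a tabulated function
#' of frequency (interpolated with a shape-preserving monotone cubic and
#' held constant outside the table). `wall_spec("hard")` requests
#' acoustically hard walls (the boundary term is omitted: a homogeneous
#' Neumann condition, the exact `|Z| -> Inf` limit).
#'
#' @param b_over_A Areal damping in N s/m3 (scalar or vector along `freq`),
#'   or the string `"hard"`.
#' @param m_over_A Areal mass in kg/m2 (scalar or vector along `freq`).
#' @param freq Optional ascending frequency table in Hz for tabulated
#'   parameters.
#' @return An object of class `wall_spec`.
#' @export
#' @examples
#' wall_spec(100, 1)                 # constant parameters
#' wall_spec("hard")                 # rigid wall
#' wall_spec(c(60, 80), c(2, 1), freq = c(500, 2000))
wall_spec <- function(b_over_A, m_over_A = NULL, freq = NULL) {
  if (identical(b_over_A, "hard")) {
    return(structure(list(hard = TRUE), class = "wall_spec"))
  }
  stopifnot(is.numeric(b_over_A), is.numeric(m_over_A))
  if (any(b_over_A < 0) || any(m_over_A < 0))
    stop("wall parameters must be nonnegative")
  if (is.null(freq)) {
    stopifnot(length(b_over_A) == 1L, length(m_over_A) == 1L)
  } else {
    stopifnot(is.numeric(freq), all(diff(freq) > 0),
              length(freq) >= 2L)
    if (length(b_over_A) == 1L) b_over_A <- rep(b_over_A, length(freq))
    if (length(m_over_A) == 1L) m_over_A <- rep(m_over_A, length(freq))
    stopifnot(length(b_over_A) == length(freq),
              length(m_over_A) == length(freq))
  }
  structure(list(hard = FALSE, b_over_A = b_over_A, m_over_A = m_over_A,
                 freq = freq),
            class = "wall_spec")
}

is_hard_wall <- function(wall) isTRUE(wall$hard)

#' @export
print.wall_spec <- function(x, ...) {
  if (is_hard_wall(x)) {
    cat("<wall_spec> acoustically hard (Neumann)\n")
  } else if (is.null(x$freq)) {
    cat(sprintf("<wall_spec> b/A = %g N s/m3, m/A = %g kg/m2\n",
                x$b_over_A, x$m_over_A))
  } else {
    cat(sprintf("<wall_spec> tabulated over %g-%g Hz (%d points)\n",
                min(x$freq), max(x$freq), length(x$freq)))
  }
  invisible(x)
}

# Evaluate tabulated or constant wall parameters at frequencies f.
wall_params_at <- function(wall, f) {
  if (is_hard_wall(wall)) stop("hard wall has no finite parameters")
  if (is.null(wall$freq)) {
    list(b_over_A = rep(wall$b_over_A, length(f)),
         m_over_A = rep(wall$m_over_A, length(f)))
  } else {
    fc <- pmin(max(wall$freq), pmax(min(wall$freq), f))
    bfun <- stats::splinefun(wall$freq, wall$b_over_A, method = "monoH.FC")
    mfun <- stats::splinefun(wall$freq, wall$m_over_A, method = "monoH.FC")
    list(b_over_A = pmax(0, bfun(fc)), m_over_A = pmax(0, mfun(fc)))
  }
}

#' Wall impedance spectrum
#'
#' @param f Frequencies in Hz (vectorized).
#' @param wall A [wall_spec()] (not `"hard"`).
#' @return Complex specific impedance `b/A + j 2 pi f m/A` in N s/m3.
#' @export
z_wall <- function(f, wall) {
  stopifnot(inherits(wall, "wall_spec"), all(f >= 0))
  if (is_hard_wall(wall))
    stop("hard wall: impedance is infinite (boundary term is omitted)")
  p <- wall_params_at(wall, f)
  complex(real = p$b_over_A, imaginary = 2 * pi * f * p$m_over_A)
}

#' Mouth radiation impedance spectrum
#'
#' Dispatches on the model of a [radiation_spec()].
#'
#' @param f Frequencies in Hz.
#' @param spec A [radiation_spec()] (not `"hard"`).
#' @param medium A [medium_props()].
#' @return Complex specific impedance in N s/m3.
#' @export
z_radiation <- function(f, spec, medium = medium_props()) {
  stopifnot(inherits(spec, "radiation_spec"))
  if (spec$model == "hard")
    stop("hard mouth: impedance is infinite (boundary term is omitted)")
  r <- radiation_radius(spec$mouth_area, spec$model)
  switch(spec$model,
         sphere = z_sphere(f, r, medium),
         piston = z_piston(f, r, medium),
         lf_piston = z_lf_piston(f, r, medium))
}
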