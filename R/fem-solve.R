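#' Frequency sweep configuration
#'
#' @param f_min,f_max Sweep bounds in Hz, `0 < f_min < f_max`.
#' @param df Frequency resolution in Hz (default 5).
#' @param f0 Glottal source amplitude (normal pressure gradient at the
#'   glottis), default 1.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(f_min, f_max, df = 5, f0 = 1) {
  stopifnot(is.numeric(f_min), is.numeric(f_max), is.numeric(df),
            f_min > 0, f_max > f_min, df > 0, f0 != 0)
  structure(list(f_min = f_min, f_max = f_max, df = df, f0 = f0),
            class = "sweep_config")
}

sweep_freqs <- function(sweep) seq(sweep$f_min, sweep$f_max, by = sweep$df)

# Eq-style impedance-to-matrix coefficients: a surface with specific
# impedance Z contributes j*w*cD*S + cK*S with cD = rho0 Re(Z)/|Z|^2 and
# cK = w rho0 Im(Z)/|Z|^2; |Z| -> Inf gives zero (hard wall).
impedance_coeffs <- function(Z, omega, rho0) {
  den <- Re(Z)^2 + Im(Z)^2
  if (any(den == 0))
    stop("zero impedance encountered; a pressure-release surface is not ",
         "representable by the impedance boundary term")
  list(cD = rho0 * Re(Z) / den, cK = omega * rho0 * Im(Z) / den)
}

#' Solve the damped Helmholtz system over a frequency sweep
#'
#' For each frequency, builds the frequency-dependent damping and stiffness
#' contributions of the mouth-radiation and wall impedances from the
#' assembled surface matrices and solves the complex linear system
#' `(-w^2 M + j w D(w) + K(w)) P = f0 * g` by direct factorization.
#' A `hard` radiation model or wall spec omits the corresponding boundary
#' term entirely (homogeneous Neumann), which is the exact infinite
#' impedance limit.
#'
#' Small systems are solved with a dense complex factorization; larger ones
#' through an equivalent real block system using sparse LU. A singular
#' system at an isolated undamped resonance is reported with its frequency
#' and the sweep continues (`NA` pressures at that bin).
#'
#' @param ops Assembled and mouth-coupled operators (uncoupled operators
#'   are coupled on the fly).
#' @param radiation A [radiation_spec()].
#' @param wall A [wall_spec()].
#' @param sweep A [sweep_config()].
#' @param medium A [medium_props()]; defaults to the medium used at
#'   assembly.
#' @param dense_threshold Reduced systems up to this size use the dense
#'   path.
#' @param store_full Keep the full nodal solution (needed for
#'   [write_vtk()]); otherwise only the mouth pressure is retained.
#' @return An object of class `pressure_solution` with `freqs`, `p_mouth`,
#'   and (if `store_full`) the nodal pressure matrix `P`.
#' @export
solve_sweep <- function(ops, radiation, wall, sweep,
                        medium = NULL, dense_threshold = 700L,
                        store_full = FALSE) {
  stopifnot(inherits(ops, "assembled_operators"),
            inherits(radiation, "radiation_spec"),
            inherits(wall, "wall_spec"),
            inherits(sweep, "sweep_config"))
  if (!ops$coupled) ops <- apply_mouth_coupling(ops)
  medium <- if (is.null(medium)) ops$medium else as_medium(medium)
  freqs <- sweep_freqs(sweep)
  nf <- length(freqs)
  nr <- ops$n_reduced

  lambda_min <- medium$c / max(freqs)
  if (lambda_min / ops$h_max < 8)
    warning(sprintf(paste0("mesh resolves only %.1f elements per wavelength",
                           " at %g Hz (rule of thumb: >= 8); refine the mesh"),
                    lambda_min / ops$h_max, max(freqs)))

  omega <- 2 * pi * freqs
  mouth_hard <- radiation$model == "hard"
  wall_hard <- is_hard_wall(wall)
  if (!mouth_hard) {
    Zm <- z_radiation(freqs, radiation, medium)
    cm <- impedance_coeffs(Zm, omega, medium$rho0)
  } else cm <- list(cD = numeric(nf), cK = numeric(nf))
  if (!wall_hard) {
    Zw <- z_wall(freqs, wall)
    cw <- impedance_coeffs(Zw, omega, medium$rho0)
  } else cw <- list(cD = numeric(nf), cK = numeric(nf))

  g <- ops$g * sweep$f0
  use_dense <- nr <= dense_threshold
  if (use_dense) {
    K0d <- as.matrix(ops$K0); Md <- as.matrix(ops$M)
    Smd <- as.matrix(ops$S_mouth); Swd <- as.matrix(ops$S_wall)
  }

  p_mouth <- complex(length.out = nf)
  P <- if (store_full) matrix(NA_complex_, ops$n, nf) else NULL
  for (k in seq_len(nf)) {
    sol <- tryCatch({
      if (use_dense) {
        A <- K0d + cm$cK[k] * Smd + cw$cK[k] * Swd - omega[k]^2 * Md +
          (1i * omega[k]) * (cm$cD[k] * Smd + cw$cD[k] * Swd)
        solve(A, g)
      } else {
        Ar <- ops$K0 + cm$cK[k] * ops$S_mouth + cw$cK[k] * ops$S_wall -
          omega[k]^2 * ops$M
        if (cm$cD[k] == 0 && cw$cD[k] == 0) {
          as.vector(Matrix::solve(Ar, g))
        } else {
          Ai <- omega[k] * (cm$cD[k] * ops$S_mouth + cw$cD[k] * ops$S_wall)
          B <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
          x <- as.vector(Matrix::solve(B, c(g, numeric(nr))))
          complex(real = x[seq_len(nr)], imaginary = x[nr + seq_len(nr)])
        }
      }
    }, error = function(e) {
      warning(sprintf("solve failed at %g Hz (%s); bin skipped",
                      freqs[k], conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(sol)) {
      p_mouth[k] <- NA_complex_
    } else {
      p_mouth[k] <- sol[ops$master_mouth]
      if (store_full) P[, k] <- sol[ops$map]
    }
  }
  structure(list(freqs = freqs, p_mouth = p_mouth, P = P, f0 = sweep$f0),
            class = "pressure_solution")
}

#' @export
print.pressure_solution <- function(x, ...) {
  cat(sprintf("<pressure_solution> %d frequencies (%g-%g Hz)%s\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              if (is.null(x$P)) "" else sprintf(", %d nodes", nrow(x$P))))
  invisible(x)
}

#' Transfer function of a pressure solution
#'
#' The magnitude ratio of the (simplified) mouth flow to the glottal
#' source, `TF(w) = | p_mouth(w) / (j w f0) |`, plus its dB form
#' `20 log10(TF / max TF)`.
#'
#' @param sol A [solve_sweep()] result.
#' @param f0_amplitude Source amplitude; defaults to the amplitude used in
#'   the sweep. Must be nonzero.
#' @return An object of class `transfer_function`: list with `freqs`,
#'   `magnitude`, `db`.
#' @export
transfer_function <- function(sol, f0_amplitude = NULL) {
  stopifnot(inherits(sol, "pressure_solution"))
  f0 <- if (is.null(f0_amplitude)) sol$f0 else f0_amplitude
  if (f0 == 0) stop("source amplitude must be nonzero")
  keep <- sol$freqs > 0
  if (any(!keep))
    warning("zero frequency excluded from the transfer function")
  freqs <- sol$freqs[keep]
  # the solution scales linearly with its own f0; renormalize to the
  # requested amplitude (the TF is invariant, by linearity)
  mag <- Mod(sol$p_mouth[keep] * (f0 / sol$f0)) / (2 * pi * freqs * abs(f0))
  db <- 20 * log10(mag / max(mag, na.rm = TRUE))
  structure(list(freqs = freqs, magnitude = mag, db = db),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> %d bins, %g-%g Hz, peak at %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[which.max(x$magnitude)]))
  invisible(x)
}

#' Write a transfer function as CSV
#'
#' Columns `freq_hz, tf, tf_db`.
#'
#' @param tf A [transfer_function()].
#' @param path Output path.
#' @export
write_transfer_function <- function(tf, path) {
  utils::write.csv(data.frame(freq_hz = tf$freqs, tf = tf$magnitude,
                              tf_db = tf$db),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a transfer function CSV written by [write_transfer_function()]
#' @param path CSV path.
#' @return A `transfer_function`.
#' @export
read_transfer_function <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("freq_hz", "tf") %in% names(d)))
  structure(list(freqs = d$freq_hz, magnitude = d$tf,
                 db = 20 * log10(d$tf / max(d$tf))),
            class = "transfer_function")
}
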