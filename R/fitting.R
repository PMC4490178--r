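#' Wall-parameter sampling grid
#'
#' Grid of areal mass and areal damping values at which the transfer
#' function is simulated. The default grid is logarithmic with 5 points
#' per decade over the physically meaningful limits established for tract
#' walls: `m/A` in [0.25, 250] kg/m2 (2.5e2 to 2.5e5 g/m2) and `b/A` in
#' [1, 1e5] N s/m3; at the upper corner the wall behaves acoustically hard.
#'
#' @param m_values Ascending areal masses in kg/m2 (>= 2 values).
#' @param b_values Ascending areal dampings in N s/m3 (>= 2 values).
#' @return An object of class `param_grid`.
#' @export
param_grid <- function(m_values, b_values) {
  stopifnot(is.numeric(m_values), is.numeric(b_values),
            length(m_values) >= 2L, length(b_values) >= 2L,
            all(diff(m_values) > 0), all(diff(b_values) > 0),
            all(m_values > 0), all(b_values > 0))
  if (min(m_values) < 0.25 - 1e-9 || max(m_values) > 250 + 1e-6 ||
      min(b_values) < 1 - 1e-9 || max(b_values) > 1e5 + 1e-3)
    warning("grid extends beyond the default wall-parameter limits ",
            "(m/A in [0.25, 250] kg/m2, b/A in [1, 1e5] N s/m3)")
  structure(list(m_values = m_values, b_values = b_values),
            class = "param_grid")
}

#' @rdname param_grid
#' @param points_per_decade Grid density of the default logarithmic grid.
#' @export
default_param_grid <- function(points_per_decade = 5) {
  logseq <- function(lo, hi)
    10^seq(log10(lo), log10(hi),
           by = 1 / points_per_decade)
  param_grid(logseq(0.25, 250), logseq(1, 1e5))
}

#' Sample formant/bandwidth objective surfaces over a wall-parameter grid
#'
#' Runs one FEM sweep per grid point, extracts formants, and tracks them
#' against a reference table (normally the hard-wall run) with
#' [match_to_reference()]. Grid points where a formant cannot be tracked
#' (the "white islands" at high damping and low inertia, where the peak
#' structure of the transfer function changes) are masked rather than
#' aborting the sweep, as is any failed solve.
#'
#' @param mesh A [vt_mesh()] (assembled once and reused).
#' @param grid A [param_grid()].
#' @param sweep A [sweep_config()].
#' @param radiation A [radiation_spec()] for the mouth.
#' @param reference A `formant_table` used for peak tracking.
#' @param medium A [medium_props()].
#' @param window Matching window (fraction of reference frequency).
#' @param progress Print one line per grid row.
#' @param ... Passed to [solve_sweep()] (e.g. `dense_threshold`).
#' @return An object of class `objective_surfaces`: arrays `F`, `BW`,
#'   `valid` of dimension (formants x m values x b values), plus the grid
#'   and reference.
#' @export
sweep_parameter_grid <- function(mesh, grid, sweep, radiation, reference,
                                 medium = medium_props(), window = 0.2,
                                 progress = FALSE, ...) {
  stopifnot(inherits(mesh, "vt_mesh"), inherits(grid, "param_grid"),
            inherits(reference, "formant_table"), nrow(reference) > 0L)
  ops <- apply_mouth_coupling(assemble(mesh, medium))
  nk <- nrow(reference)
  nm <- length(grid$m_values)
  nb <- length(grid$b_values)
  Fs <- array(NA_real_, c(nk, nm, nb))
  BWs <- array(NA_real_, c(nk, nm, nb))
  valid <- array(FALSE, c(nk, nm, nb))
  for (i in seq_len(nm)) {
    for (j in seq_len(nb)) {
      res <- tryCatch({
        wall <- wall_spec(grid$b_values[j], grid$m_values[i])
        sol <- suppressWarnings(
          solve_sweep(ops, radiation, wall, sweep, medium, ...))
        tf <- transfer_function(sol)
        found <- find_formants(tf, n_max = nk + 3L)
        if (nrow(found) == 0L) NULL
        else match_to_reference(found, reference, window = window)
      }, error = function(e) NULL)
      if (!is.null(res)) {
        Fs[, i, j] <- res$F_found
        BWs[, i, j] <- res$BW_found
        valid[, i, j] <- res$valid & is.finite(res$F_found) &
          is.finite(res$BW_found)
      }
    }
    if (progress)
      message(sprintf("m/A = %.3g kg/m2 done (%d/%d)",
                      grid$m_values[i], i, nm))
  }
  structure(list(F = Fs, BW = BWs, valid = valid, grid = grid,
                 reference = reference),
            class = "objective_surfaces")
}

#' @export
print.objective_surfaces <- function(x, ...) {
  cat(sprintf("<objective_surfaces> %d formants on %d x %d grid (%.0f%% valid)\n",
              dim(x$F)[1L], dim(x$F)[2L], dim(x$F)[3L],
              100 * mean(x$valid)))
  invisible(x)
}

#' Fit a bilinear patch to one grid cell
#'
#' Solves the 4x4 linear systems that make the local approximations
#' `F(m/A, b/A) = [m/A, b/A, m b/A^2, 1] psi` and
#' `BW(m/A, b/A) = [m/A, b/A, m b/A^2, 1] xi`
#' interpolate the four cell corners exactly.
#'
#' @param cell List or vector with `m_lo`, `m_hi`, `b_lo`, `b_hi`.
#' @param F_corners,BW_corners Corner values in the order (m_lo, b_lo),
#'   (m_hi, b_lo), (m_lo, b_hi), (m_hi, b_hi).
#' @return An object of class `patch_coeffs` with `psi`, `xi`, `cell`, and
#'   the corner values.
#' @export
fit_patch <- function(cell, F_corners, BW_corners) {
  cell <- as.list(cell)
  stopifnot(all(c("m_lo", "m_hi", "b_lo", "b_hi") %in% names(cell)),
            length(F_corners) == 4L, length(BW_corners) == 4L,
            all(is.finite(F_corners)), all(is.finite(BW_corners)))
  m <- c(cell$m_lo, cell$m_hi, cell$m_lo, cell$m_hi)
  b <- c(cell$b_lo, cell$b_lo, cell$b_hi, cell$b_hi)
  V <- cbind(m, b, m * b, 1)
  if (abs(det(V)) < .Machine$double.eps * max(abs(V))^4)
    stop("degenerate cell: bilinear system is singular")
  psi <- unname(solve(V, F_corners))
  xi <- unname(solve(V, BW_corners))
  structure(list(psi = psi, xi = xi, cell = cell,
                 F_corners = F_corners, BW_corners = BW_corners),
            class = "patch_coeffs")
}

#' Evaluate a bilinear patch
#'
#' @param patch A [fit_patch()] result.
#' @param m,b Evaluation points (recycled).
#' @param what `"F"` or `"BW"`.
#' @return Interpolated values.
#' @export
eval_patch <- function(patch, m, b, what = c("F", "BW")) {
  what <- match.arg(what)
  cf <- if (what == "F") patch$psi else patch$xi
  cf[1L] * m + cf[2L] * b + cf[3L] * m * b + cf[4L]
}

#' Intersect the level curves of a bilinear patch analytically
#'
#' Solves `F(m, b) = F_target` and `BW(m, b) = BW_target` simultaneously
#' inside one cell. Substituting the F-constraint into the BW-constraint
#' yields a quadratic whose real roots are computed in closed form (in
#' normalized cell coordinates for conditioning). Roots outside the cell
#' are discarded; if two interior roots remain, the one with smaller `b/A`
#' (the less dissipative solution) is returned.
#'
#' @param patch A [fit_patch()] result.
#' @param F_target,BW_target Target values.
#' @return List `(m_over_A, b_over_A)` or `NULL` if the curves do not
#'   intersect inside the cell (a valid outcome).
#' @export
level_curve_intersection <- function(patch, F_target, BW_target) {
  cl <- patch$cell
  # normalized bilinear coefficients: F = p1 u + p2 v + p3 u v + p4
  nrm <- function(cv) c(cv[2L] - cv[1L], cv[3L] - cv[1L],
                        cv[4L] - cv[2L] - cv[3L] + cv[1L], cv[1L])
  p <- nrm(patch$F_corners)
  x <- nrm(patch$BW_corners)
  dF <- F_target - p[4L]
  dB <- BW_target - x[4L]
  # (x1 u - dB)(p2 + p3 u) + (dF - p1 u)(x2 + x3 u) = 0
  a <- x[1L] * p[3L] - p[1L] * x[3L]
  bq <- x[1L] * p[2L] - dB * p[3L] + dF * x[3L] - p[1L] * x[2L]
  cq <- dF * x[2L] - dB * p[2L]
  roots <- if (abs(a) < 1e-14 * max(abs(bq), abs(cq), 1)) {
    if (bq == 0) numeric(0) else -cq / bq
  } else {
    disc <- bq^2 - 4 * a * cq
    if (disc < 0) numeric(0)
    else {
      q <- -(bq + sign(bq + (bq == 0)) * sqrt(disc)) / 2
      unique(c(q / a, if (q != 0) cq / q else -bq / a))
    }
  }
  tol <- 1e-9
  cand <- NULL
  for (u in roots) {
    if (!is.finite(u) || u < -tol || u > 1 + tol) next
    den <- p[2L] + p[3L] * u
    v <- if (abs(den) > 1e-12 * (abs(p[2L]) + abs(p[3L]) + 1)) {
      (dF - p[1L] * u) / den
    } else {
      den2 <- x[2L] + x[3L] * u
      if (abs(den2) <= 1e-12 * (abs(x[2L]) + abs(x[3L]) + 1)) next
      (dB - x[1L] * u) / den2
    }
    if (!is.finite(v) || v < -tol || v > 1 + tol) next
    cand <- rbind(cand, c(u, v))
  }
  if (is.null(cand)) return(NULL)
  # tie-break: smaller b/A
  pick <- cand[which.min(cand[, 2L]), ]
  list(m_over_A = cl$m_lo + pick[1L] * (cl$m_hi - cl$m_lo),
       b_over_A = cl$b_lo + pick[2L] * (cl$b_hi - cl$b_lo))
}

# dense sampling of the level curves of one formant's surfaces over all
# valid cells, in log10 parameter space; returns matrices of (log m, log b)
# points on each curve plus the dense field samples
sample_level_curves <- function(surfaces, k, F_target, BW_target,
                                nsub = 12L) {
  mv <- surfaces$grid$m_values
  bv <- surfaces$grid$b_values
  curveF <- NULL; curveB <- NULL; field <- NULL
  for (i in seq_len(length(mv) - 1L)) {
    for (j in seq_len(length(bv) - 1L)) {
      ok <- surfaces$valid[k, i:(i + 1L), j:(j + 1L)]
      if (!all(ok)) next
      Fc <- c(surfaces$F[k, i, j], surfaces$F[k, i + 1L, j],
              surfaces$F[k, i, j + 1L], surfaces$F[k, i + 1L, j + 1L])
      Bc <- c(surfaces$BW[k, i, j], surfaces$BW[k, i + 1L, j],
              surfaces$BW[k, i, j + 1L], surfaces$BW[k, i + 1L, j + 1L])
      u <- seq(0, 1, length.out = nsub)
      lm <- log10(mv[i]) + u * log10(mv[i + 1L] / mv[i])
      lb <- log10(bv[j]) + u * log10(bv[j + 1L] / bv[j])
      mm <- 10^lm
      bb <- 10^lb
      Ff <- outer(mm, bb, function(M, B)
        Fc[1L] + (Fc[2L] - Fc[1L]) * (M - mv[i]) / (mv[i + 1L] - mv[i]) +
          (Fc[3L] - Fc[1L]) * (B - bv[j]) / (bv[j + 1L] - bv[j]) +
          (Fc[4L] - Fc[2L] - Fc[3L] + Fc[1L]) *
          (M - mv[i]) / (mv[i + 1L] - mv[i]) *
          (B - bv[j]) / (bv[j + 1L] - bv[j]))
      Bf <- outer(mm, bb, function(M, B)
        Bc[1L] + (Bc[2L] - Bc[1L]) * (M - mv[i]) / (mv[i + 1L] - mv[i]) +
          (Bc[3L] - Bc[1L]) * (B - bv[j]) / (bv[j + 1L] - bv[j]) +
          (Bc[4L] - Bc[2L] - Bc[3L] + Bc[1L]) *
          (M - mv[i]) / (mv[i + 1L] - mv[i]) *
          (B - bv[j]) / (bv[j + 1L] - bv[j]))
      cf <- grDevices::contourLines(lm, lb, Ff, levels = F_target)
      cb <- grDevices::contourLines(lm, lb, Bf, levels = BW_target)
      for (cc in cf) curveF <- rbind(curveF, cbind(cc$x, cc$y))
      for (cc in cb) curveB <- rbind(curveB, cbind(cc$x, cc$y))
      field <- rbind(field, cbind(as.vector(outer(lm, lb * 0, "+")),
                                  as.vector(outer(lm * 0, lb, "+")),
                                  as.vector(Ff), as.vector(Bf)))
    }
  }
  list(curveF = curveF, curveB = curveB, field = field)
}

min_dist <- function(pts, curve) {
  if (is.null(curve)) return(rep(Inf, nrow(pts)))
  vapply(seq_len(nrow(pts)), function(i)
    sqrt(min((curve[, 1L] - pts[i, 1L])^2 + (curve[, 2L] - pts[i, 2L])^2)),
    numeric(1L))
}

#' Select the optimal wall parameters per formant
#'
#' Scans all valid grid cells of each formant's objective surfaces for
#' analytic level-curve intersections matching the target formant
#' frequency and bandwidth. Fallback rules when no intersection exists:
#' \itemize{
#'   \item both level curves exist but never cross: the densely sampled
#'     point minimizing the summed log-space distance to the two curves
#'     (`status = "nearest_neighbour"`);
#'   \item a level curve is missing entirely (the target is unreachable on
#'     the grid): the grid's maximum `m/A`, with `b/A` chosen on that edge
#'     to best match the remaining constraint
#'     (`status = "saturated_mass"`);
#'   \item no valid cells at all: `status = "none"`.
#' }
#'
#' @param surfaces An [sweep_parameter_grid()] result.
#' @param targets Data frame with columns `k`, `F_hz`, `BW_hz` (one row
#'   per formant to fit).
#' @return A data frame of class `fit_result`: `k`, `F_target`,
#'   `BW_target`, `m_over_A`, `b_over_A`, `status`.
#' @export
select_optimum <- function(surfaces, targets) {
  stopifnot(inherits(surfaces, "objective_surfaces"),
            all(c("k", "F_hz", "BW_hz") %in% names(targets)))
  mv <- surfaces$grid$m_values
  bv <- surfaces$grid$b_values
  out <- lapply(seq_len(nrow(targets)), function(r) {
    k <- targets$k[r]
    Ft <- targets$F_hz[r]; Bt <- targets$BW_hz[r]
    base <- data.frame(k = k, F_target = Ft, BW_target = Bt,
                       m_over_A = NA_real_, b_over_A = NA_real_,
                       status = "none", stringsAsFactors = FALSE)
    if (k > dim(surfaces$F)[1L] || !any(surfaces$valid[k, , ]))
      return(base)
    hits <- NULL
    for (i in seq_len(length(mv) - 1L)) {
      for (j in seq_len(length(bv) - 1L)) {
        if (!all(surfaces$valid[k, i:(i + 1L), j:(j + 1L)])) next
        Fc <- c(surfaces$F[k, i, j], surfaces$F[k, i + 1L, j],
                surfaces$F[k, i, j + 1L], surfaces$F[k, i + 1L, j + 1L])
        Bc <- c(surfaces$BW[k, i, j], surfaces$BW[k, i + 1L, j],
                surfaces$BW[k, i, j + 1L], surfaces$BW[k, i + 1L, j + 1L])
        patch <- fit_patch(list(m_lo = mv[i], m_hi = mv[i + 1L],
                                b_lo = bv[j], b_hi = bv[j + 1L]), Fc, Bc)
        hit <- level_curve_intersection(patch, Ft, Bt)
        if (!is.null(hit))
          hits <- rbind(hits, c(hit$m_over_A, hit$b_over_A))
      }
    }
    if (!is.null(hits)) {
      pick <- hits[which.min(hits[, 2L]), ]
      base$m_over_A <- pick[1L]; base$b_over_A <- pick[2L]
      base$status <- "intersection"
      return(base)
    }
    sc <- sample_level_curves(surfaces, k, Ft, Bt)
    if (is.null(sc$field)) return(base)
    if (is.null(sc$curveF) || is.null(sc$curveB)) {
      # a level curve is missing: saturate the mass at the grid maximum
      base$m_over_A <- max(mv)
      edge <- sc$field[abs(sc$field[, 1L] - log10(max(mv))) < 1e-9, ,
                       drop = FALSE]
      if (nrow(edge) == 0L) edge <- sc$field
      resid <- if (is.null(sc$curveB)) abs(edge[, 4L] - Bt)
               else abs(edge[, 3L] - Ft)
      base$b_over_A <- 10^edge[which.min(resid), 2L]
      base$status <- "saturated_mass"
      return(base)
    }
    d <- min_dist(sc$field[, 1:2, drop = FALSE], sc$curveF) +
      min_dist(sc$field[, 1:2, drop = FALSE], sc$curveB)
    best <- sc$field[which.min(d), ]
    base$m_over_A <- 10^best[1L]
    base$b_over_A <- 10^best[2L]
    base$status <- "nearest_neighbour"
    base
  })
  res <- do.call(rbind, out)
  class(res) <- c("fit_result", "data.frame")
  res
}

#' Build a frequency-dependent wall impedance from per-formant optima
#'
#' Connects the per-formant optimal `(m/A, b/A)` pairs into tabulated
#' frequency functions: within each formant's bandwidth the functions are
#' held constant (avoiding instabilities from steep slopes at the optima),
#' and between formants they follow a shape-preserving monotone cubic, so
#' no non-plausible overshoot peaks appear. Extrapolation beyond the first
#' and last formant is constant.
#'
#' @param results A [select_optimum()] result (or a data frame with `k`,
#'   `m_over_A`, `b_over_A`, `status`); at least two successful fits
#'   (status not `"none"`) are required.
#' @param formants Data frame with `k`, `F_hz`, `BW_hz`: the anchor
#'   frequencies (the target formants, not the shifted model peaks).
#' @return A tabulated [wall_spec()].
#' @export
build_impedance_function <- function(results, formants) {
  ok <- results$status != "none" & is.finite(results$m_over_A) &
    is.finite(results$b_over_A)
  res <- results[ok, , drop = FALSE]
  if (nrow(res) < 2L)
    stop("need at least 2 successful per-formant fits to build a ",
         "frequency-dependent wall impedance")
  idx <- match(res$k, formants$k)
  if (anyNA(idx)) stop("results refer to formants missing from `formants`")
  Fk <- formants$F_hz[idx]
  BWk <- formants$BW_hz[idx]
  o <- order(Fk)
  Fk <- Fk[o]; BWk <- BWk[o]
  mA <- res$m_over_A[o]; bA <- res$b_over_A[o]
  lo <- Fk - BWk / 2
  hi <- Fk + BWk / 2
  # clip overlapping constant bands at the midpoint between formants
  for (q in seq_len(length(Fk) - 1L)) {
    if (hi[q] >= lo[q + 1L]) {
      mid <- (Fk[q] + Fk[q + 1L]) / 2
      hi[q] <- mid - 1e-6
      lo[q + 1L] <- mid + 1e-6
    }
  }
  freq <- as.vector(rbind(lo, hi))
  wall_spec(b_over_A = rep(bA, each = 2L),
            m_over_A = rep(mA, each = 2L),
            freq = freq)
}

#' Continuum-layer equivalents of the areal wall parameters
#'
#' The lumped mass-damper wall maps onto an isotropic viscous tissue layer
#' of thickness `l`, density `rho` and dynamic viscosity `eta` through
#' `m/A = rho * l` and `b/A = eta / l`. Given the areal parameters and a
#' density (water, 1000 kg/m3, is the standard surrogate for mucosa), this
#' returns the effective layer thickness and viscosity; a known thickness
#' can be supplied instead to obtain the viscosity for that layer.
#'
#' @param m_over_A Areal mass in kg/m2.
#' @param b_over_A Areal damping in N s/m3.
#' @param rho Tissue density in kg/m3 (default 1000).
#' @param l Optional layer thickness in m; defaults to `(m/A)/rho`.
#' @return List with `l` (m) and `eta` (Pa s).
#' @export
#' @examples
#' continuum_equivalents(0.252, 65)        # ~0.25 mm layer
#' continuum_equivalents(0.252, 65, l = 3e-3)
continuum_equivalents <- function(m_over_A, b_over_A, rho = 1000, l = NULL) {
  stopifnot(is.numeric(m_over_A), is.numeric(b_over_A), is.numeric(rho))
  if (any(m_over_A <= 0) || any(b_over_A <= 0) || any(rho <= 0))
    stop("areal parameters and density must be positive")
  if (is.null(l)) l <- m_over_A / rho
  if (any(l <= 0)) stop("layer thickness must be positive")
  list(l = l, eta = b_over_A * l)
}

#' Write fit results as CSV
#' @param results A [select_optimum()] result.
#' @param path Output path.
#' @export
write_fit_results <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' Read/write tabulated wall specs as CSV
#'
#' File schema: `freq_hz, b_over_A, m_over_A` with `b/A` in N s/m3 and
#' `m/A` in g/m2 in the file (converted to kg/m2 in memory).
#'
#' @param wall A tabulated [wall_spec()].
#' @param path CSV path.
#' @export
write_wall_spec <- function(wall, path) {
  stopifnot(inherits(wall, "wall_spec"), !is_hard_wall(wall))
  if (is.null(wall$freq))
    stop("only tabulated wall specs have a CSV representation")
  utils::write.csv(data.frame(freq_hz = wall$freq, b_over_A = wall$b_over_A,
                              m_over_A = wall$m_over_A * 1000),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wall_spec
#' @export
read_wall_spec <- function(path) {
  d <- utils::read.csv(path)
  need <- c("freq_hz", "b_over_A", "m_over_A")
  if (!all(need %in% names(d)))
    stop("wall spec CSV must have columns: ", paste(need, collapse = ", "))
  wall_spec(b_over_A = d$b_over_A, m_over_A = d$m_over_A / 1000,
            freq = d$freq_hz)
}
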