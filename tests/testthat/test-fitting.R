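test_that("bilinear patches reproduce their corners exactly", {
  set.seed(11)
  cell <- list(m_lo = 0.79, m_hi = 2.5, b_lo = 100, b_hi = 1000)
  V <- function(m, b) c(m, b, m * b, 1)
  corners <- list(c(cell$m_lo, cell$b_lo), c(cell$m_hi, cell$b_lo),
                  c(cell$m_lo, cell$b_hi), c(cell$m_hi, cell$b_hi))
  for (rep in 1:20) {
    Fc <- stats::runif(4, 400, 900)
    Bc <- stats::runif(4, 20, 200)
    p <- fit_patch(cell, Fc, Bc)
    for (q in 1:4) {
      expect_equal(sum(V(corners[[q]][1], corners[[q]][2]) * p$psi), Fc[q])
      expect_equal(sum(V(corners[[q]][1], corners[[q]][2]) * p$xi), Bc[q])
    }
  }
  # constant surface: psi = (0, 0, 0, F)
  pc <- fit_patch(cell, rep(7, 4), rep(3, 4))
  expect_equal(pc$psi, c(0, 0, 0, 7), tolerance = 1e-12)
  # F = m/A: the identity in m
  pid <- fit_patch(cell, c(cell$m_lo, cell$m_hi, cell$m_lo, cell$m_hi),
                   rep(1, 4))
  expect_equal(pid$psi, c(1, 0, 0, 0), tolerance = 1e-12)
})

test_that("patch interpolation matches dense bilinear evaluation", {
  set.seed(12)
  cell <- list(m_lo = 1, m_hi = 3, b_lo = 10, b_hi = 40)
  Fc <- stats::runif(4); Bc <- stats::runif(4)
  p <- fit_patch(cell, Fc, Bc)
  # cell centre equals the corner mean for a bilinear surface
  expect_equal(eval_patch(p, 2, 25, "F"), mean(Fc))
  # dense cross-check against the normalized form
  u <- stats::runif(50); v <- stats::runif(50)
  m <- cell$m_lo + u * 2; b <- cell$b_lo + v * 30
  direct <- Fc[1] * (1 - u) * (1 - v) + Fc[2] * u * (1 - v) +
    Fc[3] * (1 - u) * v + Fc[4] * u * v
  expect_equal(eval_patch(p, m, b, "F"), direct, tolerance = 1e-10)
})

test_that("identity surfaces intersect at the target point", {
  cell <- list(m_lo = 1, m_hi = 2, b_lo = 10, b_hi = 20)
  p <- fit_patch(cell, c(1, 2, 1, 2), c(10, 10, 20, 20))
  hit <- level_curve_intersection(p, 1.5, 13)
  expect_equal(hit$m_over_A, 1.5)
  expect_equal(hit$b_over_A, 13)
  expect_null(level_curve_intersection(p, 5, 13))
  expect_null(level_curve_intersection(p, 1.5, 130))
})

test_that("level-curve roots agree with a dense brute-force oracle", {
  set.seed(13)
  cell <- list(m_lo = 1, m_hi = 2, b_lo = 10, b_hi = 20)
  ms <- seq(1, 2, length.out = 201)
  bs <- seq(10, 20, length.out = 201)
  n_checked <- 0L
  for (rep in 1:300) {
    p <- fit_patch(cell, stats::runif(4), stats::runif(4))
    Ft <- stats::runif(1); Bt <- stats::runif(1)
    hit <- level_curve_intersection(p, Ft, Bt)
    G <- abs(outer(ms, bs, function(M, B) eval_patch(p, M, B, "F")) - Ft) +
      abs(outer(ms, bs, function(M, B) eval_patch(p, M, B, "BW")) - Bt)
    gmin <- min(G)
    if (is.null(hit)) {
      # no analytic root: the dense residual must stay clearly nonzero
      expect_gt(gmin, 1e-4)
    } else {
      # the analytic root is an exact zero ...
      expect_equal(eval_patch(p, hit$m_over_A, hit$b_over_A, "F"), Ft,
                   tolerance = 1e-8)
      expect_equal(eval_patch(p, hit$m_over_A, hit$b_over_A, "BW"), Bt,
                   tolerance = 1e-8)
      # ... within one fine-grid cell of a brute-force near-zero
      near <- which(G <= gmin + 1e-3, arr.ind = TRUE)
      d <- sqrt((ms[near[, 1]] - hit$m_over_A)^2 / diff(range(ms))^2 +
                  (bs[near[, 2]] - hit$b_over_A)^2 / diff(range(bs))^2)
      expect_lt(min(d), 1.5 / 200)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 25L)   # intersections actually occurred
})

test_that("select_optimum applies the stated fallback rules", {
  # synthetic surfaces: F = 100 * m, BW = b on a 3 x 3 grid
  mv <- c(1, 2, 4); bv <- c(10, 100, 1000)
  Fs <- array(NA_real_, c(1, 3, 3)); BWs <- array(NA_real_, c(1, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    Fs[1, i, j] <- 100 * mv[i]
    BWs[1, i, j] <- bv[j]
  }
  surf <- structure(list(F = Fs, BW = BWs,
                         valid = array(TRUE, c(1, 3, 3)),
                         grid = param_grid(mv, bv), reference = NULL),
                    class = "objective_surfaces")
  # reachable targets: exact intersection
  fit <- select_optimum(surf, data.frame(k = 1, F_hz = 150, BW_hz = 50))
  expect_equal(fit$status, "intersection")
  expect_equal(fit$m_over_A, 1.5)
  expect_equal(fit$b_over_A, 50)
  # F below everything on the grid: saturated mass at the maximum m/A
  fit2 <- select_optimum(surf, data.frame(k = 1, F_hz = 50, BW_hz = 50))
  expect_equal(fit2$status, "saturated_mass")
  expect_equal(fit2$m_over_A, 4)
  # formant with no valid cells: none
  surf$valid[] <- FALSE
  fit3 <- select_optimum(surf, data.frame(k = 1, F_hz = 150, BW_hz = 50))
  expect_equal(fit3$status, "none")
})

test_that("impedance functions interpolate the optima and stay constant", {
  results <- data.frame(k = 1:3, m_over_A = c(2, 2, 2),
                        b_over_A = c(300, 300, 300),
                        status = "intersection")
  formants <- data.frame(k = 1:3, F_hz = c(500, 1500, 2500),
                         BW_hz = c(50, 60, 80))
  w <- build_impedance_function(results, formants)
  # equal optima give a constant function everywhere
  p <- vtfem:::wall_params_at(w, c(100, 500, 1000, 2500, 4000))
  expect_true(all(abs(p$m_over_A - 2) < 1e-12))
  expect_true(all(abs(p$b_over_A - 300) < 1e-12))
  # distinct optima: evaluation at each anchor returns exactly the optimum
  res2 <- data.frame(k = 1:3, m_over_A = c(5, 1, 2.5),
                     b_over_A = c(100, 4000, 800), status = "intersection")
  w2 <- build_impedance_function(res2, formants)
  p2 <- vtfem:::wall_params_at(w2, formants$F_hz)
  expect_equal(p2$m_over_A, res2$m_over_A)
  expect_equal(p2$b_over_A, res2$b_over_A)
  # constant within each bandwidth interval
  p3 <- vtfem:::wall_params_at(w2, c(1500 - 25, 1500, 1500 + 25))
  expect_true(all(abs(p3$m_over_A - 1) < 1e-12))
  # order of the input rows does not matter
  w3 <- build_impedance_function(res2[c(3, 1, 2), ], formants)
  expect_equal(vtfem:::wall_params_at(w3, seq(300, 3000, 50)),
               vtfem:::wall_params_at(w2, seq(300, 3000, 50)))
  expect_error(build_impedance_function(res2[1, , drop = FALSE], formants),
               "at least 2")
})

test_that("continuum equivalents follow m/A = rho l and b/A = eta / l", {
  # 252 g/m2 over water density: a quarter-millimetre layer
  eq <- continuum_equivalents(0.252, 65)
  expect_equal(eq$l * 1000, 0.252, tolerance = 1e-12)
  expect_equal(round(eq$l * 1000, 2), 0.25)
  # 251,189 g/m2: a quarter-metre layer
  eq2 <- continuum_equivalents(251.189, 65)
  expect_equal(round(eq2$l, 2), 0.25)
  # a 3 mm mucosa layer with b/A = 65 N s/m3 gives eta = 0.195 Pa s
  eq3 <- continuum_equivalents(0.252, 65, l = 3e-3)
  expect_equal(eq3$eta, 0.195)
  expect_error(continuum_equivalents(-1, 65), "positive")
})
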