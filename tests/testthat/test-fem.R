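test_that("quadrature rules integrate simplex monomials exactly", {
  gm <- vtfem:::grundmann_moeller(2L, 3L)
  mono <- function(a, b, c) sum(gm$weights * gm$points[, 2]^a *
                                  gm$points[, 3]^b * gm$points[, 4]^c)
  exact <- function(a, b, c)
    factorial(a) * factorial(b) * factorial(c) / factorial(a + b + c + 3)
  for (pw in list(c(0, 0, 0), c(1, 0, 0), c(2, 2, 0), c(1, 1, 2),
                  c(5, 0, 0), c(2, 2, 1)))
    expect_equal(mono(pw[1], pw[2], pw[3]), exact(pw[1], pw[2], pw[3]))
  gm2 <- vtfem:::grundmann_moeller(2L, 2L)
  expect_equal(sum(gm2$weights), 0.5)
})

test_that("stiffness has the constant-pressure nullspace", {
  for (order in 1:2) {
    m <- if (order == 1) tube_mesh_coarse() else tube_mesh_quad()
    ops <- assemble(m)
    expect_lt(max(abs(Matrix::rowSums(ops$K0))), 1e-10)
    # symmetry of all operators
    for (A in list(ops$K0, ops$M, ops$S_mouth, ops$S_wall))
      expect_lt(max(abs(A - Matrix::t(A))), 1e-12 * max(abs(A)))
  }
})

test_that("surface mass of a unit square patch integrates by hand", {
  # two linear triangles covering the unit square: total int N N^T = area 1
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                 c(0.5, 0.5, 1))
  tets <- rbind(c(1L, 2L, 3L, 5L), c(1L, 3L, 4L, 5L))
  bnd <- vtfem:::boundary_faces(tets)
  zmax <- apply(matrix(nodes[bnd, 3L], ncol = 3L), 1, max)
  tag <- ifelse(zmax == 0, "mouth", "wall")
  tag[which(tag == "wall")[1]] <- "glottis"   # need all three tags
  mesh <- vt_mesh(nodes, tets, bnd, tag)
  ops <- assemble(mesh)
  expect_equal(sum(ops$S_mouth), 1, tolerance = 1e-12)
  # hand integration of linear shape functions, triangle area 1/2:
  # int Ni Nj = 1/24 per triangle; edge (1,2) lies in one triangle, the
  # diagonal (1,3) in both
  S <- as.matrix(ops$S_mouth)
  expect_equal(S[1, 2], 1 / 24, tolerance = 1e-12)
  expect_equal(S[1, 3], 2 / 24, tolerance = 1e-12)
})

test_that("glottal load sums to the glottis area (partition of unity)", {
  for (m in list(tube_mesh_coarse(), tube_mesh_quad())) {
    ops <- assemble(m)
    expect_equal(sum(ops$g), ops$glottis_area, tolerance = 1e-12)
    expect_equal(ops$glottis_area, summarize_geometry(m)$glottis_area)
  }
})

test_that("mouth coupling reduces the system and keeps symmetry", {
  ops <- assemble(tube_mesh_coarse())
  red <- apply_mouth_coupling(ops)
  expect_equal(red$n_reduced, ops$n - (length(ops$mouth_dofs) - 1L))
  for (A in list(red$K0, red$M, red$S_wall))
    expect_lt(max(abs(A - Matrix::t(A))), 1e-12 * max(abs(A)))
  # coupled mouth surface matrix collapses to the mouth area at the master
  expect_equal(sum(red$S_mouth), ops$mouth_area, tolerance = 1e-12)
  # idempotent
  expect_identical(apply_mouth_coupling(red)$n_reduced, red$n_reduced)
})

test_that("solved mouth pressure is shared by construction across the patch", {
  ops <- tube_ops_coarse()
  sw <- sweep_config(500, 520, 10)
  sol <- solve_sweep(ops, tube_sphere_rad(), wall_spec(2000, 2), sw,
                     store_full = TRUE)
  m <- tube_mesh_coarse()
  mouth_nodes <- unique(as.vector(
    m$boundary_tris[m$boundary_tag == "mouth", ]))
  for (k in seq_along(sol$freqs))
    expect_equal(max(Mod(sol$P[mouth_nodes, k] - sol$p_mouth[k])), 0)
})

test_that("transfer function is linear in the source and nonnegative", {
  ops <- tube_ops_coarse()
  sw1 <- sweep_config(300, 800, 5, f0 = 1)
  sw2 <- sweep_config(300, 800, 5, f0 = 2)
  tf1 <- transfer_function(solve_sweep(ops, tube_sphere_rad(),
                                       wall_spec(2000, 2), sw1))
  tf2 <- transfer_function(solve_sweep(ops, tube_sphere_rad(),
                                       wall_spec(2000, 2), sw2))
  expect_equal(tf1$magnitude, tf2$magnitude, tolerance = 1e-10)
  expect_true(all(tf1$magnitude >= 0))
})

test_that("density scaling leaves radiation-loaded peaks unchanged", {
  # the radiation impedance is itself proportional to rho0 c, so its
  # boundary coefficient rho0 Re(Z)/|Z|^2 is density-invariant; with hard
  # walls the peak frequencies therefore do not move while the driven
  # pressures scale with the load
  m <- tube_mesh_coarse()
  sw <- sweep_config(150, 2000, 5)
  sol_at <- function(rho) {
    med <- medium_props(350, rho)
    ops <- apply_mouth_coupling(assemble(m, med))
    suppressWarnings(solve_sweep(ops, tube_sphere_rad(),
                                 wall_spec("hard"), sw, med))
  }
  s1 <- sol_at(1.15); s2 <- sol_at(2.30)
  f1 <- find_formants(transfer_function(s1))$F_hz
  f2 <- find_formants(transfer_function(s2))$F_hz
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("wall damping never raises a peak above its hard-wall level", {
  ops <- tube_ops_coarse()
  sw <- tube_sweep()
  tf_hard <- transfer_function(suppressWarnings(
    solve_sweep(ops, tube_sphere_rad(), wall_spec("hard"), sw)))
  # peak magnitudes stay at or below the hard-wall levels once the wall
  # dissipates (passivity)
  ref_peaks <- find_formants(tf_hard)
  for (b in c(1e3, 1e4, 1e5)) {
    tf <- transfer_function(suppressWarnings(
      solve_sweep(ops, tube_sphere_rad(), wall_spec(b, 2.5), sw)))
    found <- find_formants(tf)
    mt <- match_to_reference(found, ref_peaks, window = TUBE_WINDOW)
    lev_ref <- ref_peaks$level_db + 20 * log10(max(tf_hard$magnitude))
    lev_fnd <- found$level_db[mt$k_found] + 20 * log10(max(tf$magnitude))
    expect_true(all(lev_fnd[mt$valid] <= lev_ref[mt$valid] + 0.01))
  }
})

test_that("a coarse mesh for the requested band triggers the sampling warning", {
  ops <- tube_ops_coarse()   # h ~ 3 cm
  expect_warning(
    solve_sweep(ops, tube_sphere_rad(), wall_spec(2000, 2),
                sweep_config(3000, 3010, 5)),
    "elements per wavelength")
})

test_that("VTK snapshot export writes a well-formed legacy file", {
  m <- tube_mesh_coarse()
  ops <- tube_ops_coarse()
  sol <- solve_sweep(ops, tube_sphere_rad(), wall_spec(2000, 2),
                     sweep_config(500, 510, 10), store_full = TRUE)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(m, Mod(sol$P[, 1]), path)
  txt <- readLines(path)
  expect_true(any(grepl("^POINTS", txt)))
  expect_true(any(grepl("^CELLS", txt)))
  expect_equal(sum(txt == "10"), nrow(m$tets))
})

test_that("tube peak frequencies are stable under mesh refinement", {
  # linear h ~ 3 cm vs quadratic h ~ 2 cm: F1 of the radiation-loaded
  # hard-wall tube moves by well under 1%
  sw <- sweep_config(300, 800, 5)
  f1_of <- function(mesh) {
    ops <- apply_mouth_coupling(assemble(mesh))
    tf <- transfer_function(suppressWarnings(
      solve_sweep(ops, tube_sphere_rad(), wall_spec("hard"), sw)))
    find_formants(tf)$F_hz[1]
  }
  expect_equal(f1_of(tube_mesh_coarse()), f1_of(tube_mesh_quad()),
               tolerance = 0.01)
})
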