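#' Assemble the acoustic FEM operators on a tract mesh
#'
#' Builds the frequency-independent operators of the damped Helmholtz
#' system: the mass matrix `M = (1/c^2) int N N^T dV` (the `1/c^2` factor is
#' folded into `M` so that the assembled system is
#' `(-w^2 M + j w D(w) + K(w)) P = g`, reproducing the free-field dispersion
#' `k = w/c`), the undamped stiffness `K0 = int grad N . grad N^T dV`, the
#' boundary surface matrices `S_mouth`, `S_wall`, `S_glottis`
#' (`int N N^T dG` per tag), and the glottal load `g = int N f0 dG` for a
#' unit normal-gradient source `f0 = 1` (rescaled at solve time).
#'
#' @param mesh A [vt_mesh()] (order 1 or 2).
#' @param medium A [medium_props()].
#' @return An object of class `assembled_operators` with sparse symmetric
#'   matrices `M`, `K0`, `S_mouth`, `S_wall`, load vector `g`, the
#'   `mouth_dofs` index set, and mesh metadata (`h_max`, areas).
#' @export
assemble <- function(mesh, medium = medium_props()) {
  stopifnot(inherits(mesh, "vt_mesh"))
  medium <- as_medium(medium)
  n <- nrow(mesh$nodes)
  tets <- mesh$tets
  nd <- ncol(tets)
  order <- mesh$order
  ref <- tet_reference(order)

  v1 <- mesh$nodes[tets[, 1L], , drop = FALSE]
  e1 <- mesh$nodes[tets[, 2L], , drop = FALSE] - v1
  e2 <- mesh$nodes[tets[, 3L], , drop = FALSE] - v1
  e3 <- mesh$nodes[tets[, 4L], , drop = FALSE] - v1
  cross3 <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
  c23 <- cross3(e2, e3)
  detJ <- rowSums(e1 * c23)
  if (any(detJ <= 0))
    stop(sprintf("inverted element (nonpositive Jacobian): tet %d",
                 which(detJ <= 0)[1]))
  # rows of J^-1 (scaled by 1/detJ)
  r1 <- c23 / detJ
  r2 <- cross3(e3, e1) / detJ
  r3 <- cross3(e1, e2) / detJ
  rows <- list(r1, r2, r3)

  # element matrices, flattened column-major over (i, j) dof pairs
  nel <- nrow(tets)
  Kflat <- matrix(0, nel, nd * nd)
  for (a in 1:3) for (b in 1:3) {
    Aab <- rowSums(rows[[a]] * rows[[b]]) * detJ
    Kflat <- Kflat + Aab %o% as.vector(ref$Cab[a, b, , ])
  }
  Mflat <- (detJ / medium$c^2) %o% as.vector(ref$Mref)

  ii <- tets[, rep(seq_len(nd), times = nd)]
  jj <- tets[, rep(seq_len(nd), each = nd)]
  K0 <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                             x = as.vector(Kflat), dims = c(n, n))
  M <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(Mflat), dims = c(n, n))

  tref <- tri_reference(order)
  ndt <- ncol(mesh$boundary_tris)
  areas <- tri_areas(mesh$nodes, mesh$boundary_tris)
  surf <- function(tag) {
    sel <- mesh$boundary_tag == tag
    tris <- mesh$boundary_tris[sel, , drop = FALSE]
    Sflat <- (2 * areas[sel]) %o% as.vector(tref$Mref)
    si <- tris[, rep(seq_len(ndt), times = ndt)]
    sj <- tris[, rep(seq_len(ndt), each = ndt)]
    Matrix::sparseMatrix(i = as.vector(si), j = as.vector(sj),
                         x = as.vector(Sflat), dims = c(n, n))
  }
  S_mouth <- surf("mouth")
  S_wall <- surf("wall")
  gsel <- mesh$boundary_tag == "glottis"
  gtris <- mesh$boundary_tris[gsel, , drop = FALSE]
  gflat <- (2 * areas[gsel]) %o% tref$gref
  g <- numeric(n)
  gi <- as.vector(gtris)
  gx <- as.vector(gflat)
  g[sort(unique(gi))] <- vapply(split(gx, gi), sum, numeric(1L))

  # longest vertex edge, for the elements-per-wavelength rule
  h_max <- sqrt(max(rowSums(e1^2), rowSums(e2^2), rowSums(e3^2),
                    rowSums((e2 - e1)^2), rowSums((e3 - e1)^2),
                    rowSums((e3 - e2)^2)))

  structure(list(M = M, K0 = K0, S_mouth = S_mouth, S_wall = S_wall, g = g,
                 mouth_dofs = sort(unique(as.vector(
                   mesh$boundary_tris[mesh$boundary_tag == "mouth", ]))),
                 n = n, order = order, h_max = h_max,
                 mouth_area = sum(areas[mesh$boundary_tag == "mouth"]),
                 glottis_area = sum(areas[gsel]),
                 wall_area = sum(areas[mesh$boundary_tag == "wall"]),
                 medium = medium, coupled = FALSE, map = seq_len(n)),
            class = "assembled_operators")
}

#' Couple the mouth pressure degrees of freedom
#'
#' Constrains the pressure of every node on the mouth patch to a single
#' master degree of freedom by constraint elimination (`A -> T' A T`), so
#' that the solved pressure is identical over the whole mouth opening. The
#' reduced system is smaller by the number of slaved nodes and stays
#' symmetric.
#'
#' @param ops An [assemble()]d operator set.
#' @return The operator set with reduced matrices and `coupled = TRUE`.
#' @export
apply_mouth_coupling <- function(ops) {
  stopifnot(inherits(ops, "assembled_operators"))
  if (ops$coupled) return(ops)
  n <- ops$n
  md <- ops$mouth_dofs
  if (length(md) == 0L) stop("mouth patch is empty")
  master <- md[1L]
  map <- integer(n)
  keep <- setdiff(seq_len(n), md[-1L])
  map[keep] <- seq_along(keep)
  map[md] <- map[master]
  Tm <- Matrix::sparseMatrix(i = seq_len(n), j = map, x = 1,
                             dims = c(n, length(keep)))
  red <- function(A) Matrix::t(Tm) %*% A %*% Tm
  ops$M <- red(ops$M); ops$K0 <- red(ops$K0)
  ops$S_mouth <- red(ops$S_mouth); ops$S_wall <- red(ops$S_wall)
  ops$g <- as.vector(Matrix::t(Tm) %*% ops$g)
  ops$map <- map
  ops$master_mouth <- map[master]
  ops$n_reduced <- length(keep)
  ops$coupled <- TRUE
  ops
}

#' @export
print.assembled_operators <- function(x, ...) {
  cat(sprintf("<assembled_operators> order %d, %d dofs%s, h_max = %.3g m\n",
              x$order, x$n,
              if (x$coupled) sprintf(" (%d after mouth coupling)",
                                     x$n_reduced) else "",
              x$h_max))
  invisible(x)
}
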