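# Reference-element machinery for the acoustic FEM.
#
# All elements are affine (straight edges, flat faces), so every element
# integral reduces to constant reference matrices scaled by the element
# Jacobian: the mass matrix is |det J| * Mref, and the stiffness matrix is
# |det J| * sum_{a,b} (J^-1 J^-T)[a,b] * Cab with Cab the reference
# gradient-product matrices. Reference matrices are computed once per
# element order with a Grundmann-Moeller simplex quadrature rule of degree
# 5 (exact for the degree-4 integrands of quadratic elements).

# nonnegative integer compositions of k into `parts` parts (rows)
compositions <- function(k, parts) {
  if (parts == 1L) return(matrix(k, 1L, 1L))
  do.call(rbind, lapply(0:k, function(j)
    cbind(j, compositions(k - j, parts - 1L))))
}

# Grundmann-Moeller rule of degree 2s+1 on the unit n-simplex.
# Returns barycentric points (rows, n+1 columns) and weights summing to the
# simplex volume 1/n!.
grundmann_moeller <- function(s, n) {
  d <- 2L * s + 1L
  pts <- NULL
  w <- NULL
  for (i in 0:s) {
    denom <- d + n - 2L * i
    beta <- compositions(s - i, n + 1L)
    p <- (2 * beta + 1) / denom
    wi <- (-1)^i * 2^(-2 * s) * denom^d /
      (factorial(i) * factorial(d + n - i))
    pts <- rbind(pts, p)
    w <- c(w, rep(wi, nrow(beta)))
  }
  list(points = pts, weights = w)
}

# Shape functions and reference-coordinate gradients at barycentric points.
# lambda: q x (n+1); returns N (q x ndof) and dN (q x ndof x n).
shape_tet <- function(lambda, order) {
  q <- nrow(lambda)
  # d lambda / d (xi, eta, zeta)
  dl <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  if (order == 1L) {
    N <- lambda
    dN <- array(0, c(q, 4L, 3L))
    for (a in 1:3) dN[, , a] <- matrix(dl[, a], q, 4L, byrow = TRUE)
    return(list(N = N, dN = dN))
  }
  ndof <- 10L
  N <- matrix(0, q, ndof)
  dN <- array(0, c(q, ndof, 3L))
  for (i in 1:4) {
    N[, i] <- lambda[, i] * (2 * lambda[, i] - 1)
    for (a in 1:3)
      dN[, i, a] <- (4 * lambda[, i] - 1) * dl[i, a]
  }
  for (e in seq_len(nrow(EDGE_ORDER_TET))) {
    i <- EDGE_ORDER_TET[e, 1L]; j <- EDGE_ORDER_TET[e, 2L]
    N[, 4L + e] <- 4 * lambda[, i] * lambda[, j]
    for (a in 1:3)
      dN[, 4L + e, a] <- 4 * (lambda[, j] * dl[i, a] + lambda[, i] * dl[j, a])
  }
  list(N = N, dN = dN)
}

shape_tri <- function(lambda, order) {
  q <- nrow(lambda)
  if (order == 1L) return(list(N = lambda))
  N <- matrix(0, q, 6L)
  for (i in 1:3) N[, i] <- lambda[, i] * (2 * lambda[, i] - 1)
  for (e in 1:3) {
    i <- EDGE_ORDER_TRI[e, 1L]; j <- EDGE_ORDER_TRI[e, 2L]
    N[, 3L + e] <- 4 * lambda[, i] * lambda[, j]
  }
  list(N = N)
}

# cached reference matrices per order
ref_cache <- new.env(parent = emptyenv())

tet_reference <- function(order) {
  key <- paste0("tet", order)
  if (!is.null(ref_cache[[key]])) return(ref_cache[[key]])
  gm <- grundmann_moeller(2L, 3L)          # degree 5
  sh <- shape_tet(gm$points, order)
  ndof <- ncol(sh$N)
  Mref <- matrix(0, ndof, ndof)
  Cab <- array(0, c(3L, 3L, ndof, ndof))
  for (q in seq_along(gm$weights)) {
    wq <- gm$weights[q]
    Nq <- sh$N[q, ]
    Mref <- Mref + wq * tcrossprod(Nq)
    for (a in 1:3) for (b in 1:3)
      Cab[a, b, , ] <- Cab[a, b, , ] +
        wq * tcrossprod(sh$dN[q, , a], sh$dN[q, , b])
  }
  out <- list(Mref = Mref, Cab = Cab, ndof = ndof)
  ref_cache[[key]] <- out
  out
}

tri_reference <- function(order) {
  key <- paste0("tri", order)
  if (!is.null(ref_cache[[key]])) return(ref_cache[[key]])
  gm <- grundmann_moeller(2L, 2L)          # degree 5
  sh <- shape_tri(gm$points, order)
  ndof <- ncol(sh$N)
  Mref <- matrix(0, ndof, ndof)
  gref <- numeric(ndof)
  for (q in seq_along(gm$weights)) {
    Mref <- Mref + gm$weights[q] * tcrossprod(sh$N[q, ])
    gref <- gref + gm$weights[q] * sh$N[q, ]
  }
  out <- list(Mref = Mref, gref = gref, ndof = ndof)
  ref_cache[[key]] <- out
  out
}
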