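# Gmsh-conventional local orderings for quadratic elements: mid-side nodes
# follow these edges of the linear parent element.
EDGE_ORDER_TET <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L),
                        c(1L, 4L), c(3L, 4L), c(2L, 4L))
EDGE_ORDER_TRI <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))

SURFACE_TAGS <- c("glottis", "mouth", "wall")

#' Construct a tagged tetrahedral tract mesh
#'
#' Low-level constructor validating the mesh invariants: positive tet
#' volumes, a boundary partitioned into exactly the three surface tags
#' `glottis`, `mouth` and `wall`, and non-empty, disjoint glottis and mouth
#' patches. Most users will call [build_tube_mesh()] or [read_mesh()]
#' instead.
#'
#' @param nodes Numeric matrix (n x 3) of coordinates in m.
#' @param tets Integer matrix of connectivity: 4 columns (linear) or 10
#'   columns (quadratic, mid-side nodes in Gmsh edge order).
#' @param boundary_tris Integer matrix of boundary triangles: 3 or 6 columns
#'   matching the tet order.
#' @param boundary_tag Character/factor of tags, one per boundary triangle.
#' @param layer_x Optional axial station positions of extruded node layers
#'   (used by [summarize_geometry()] for the centerline).
#' @return An object of class `vt_mesh`.
#' @export
vt_mesh <- function(nodes, tets, boundary_tris, boundary_tag, layer_x = NULL) {
  nodes <- unname(as.matrix(nodes))
  storage.mode(nodes) <- "double"
  tets <- unname(as.matrix(tets))
  storage.mode(tets) <- "integer"
  boundary_tris <- unname(as.matrix(boundary_tris))
  storage.mode(boundary_tris) <- "integer"
  if (ncol(nodes) != 3L) stop("`nodes` must be an n x 3 matrix")
  if (!ncol(tets) %in% c(4L, 10L))
    stop("`tets` must have 4 (linear) or 10 (quadratic) columns")
  if (!ncol(boundary_tris) %in% c(3L, 6L))
    stop("`boundary_tris` must have 3 or 6 columns")
  order <- if (ncol(tets) == 4L) 1L else 2L
  if ((order == 1L) != (ncol(boundary_tris) == 3L))
    stop("element order of boundary triangles must match tet order")
  boundary_tag <- factor(as.character(boundary_tag), levels = SURFACE_TAGS)
  if (anyNA(boundary_tag))
    stop("boundary tags must be one of: ", paste(SURFACE_TAGS, collapse = ", "))
  if (length(boundary_tag) != nrow(boundary_tris))
    stop("one tag per boundary triangle required")
  for (tag in c("glottis", "mouth"))
    if (!any(boundary_tag == tag))
      stop(sprintf("missing surface tag: %s (patch is empty)", tag))
  v <- tet_volumes(nodes, tets)
  if (any(v <= 0))
    stop(sprintf("inverted element: tet %d has nonpositive volume",
                 which(v <= 0)[1]))
  structure(list(nodes = nodes, tets = tets, boundary_tris = boundary_tris,
                 boundary_tag = boundary_tag, order = order,
                 layer_x = layer_x),
            class = "vt_mesh")
}

#' @export
print.vt_mesh <- function(x, ...) {
  cat(sprintf("<vt_mesh> order %d: %d nodes, %d tets, %d boundary tris (%s)\n",
              x$order, nrow(x$nodes), nrow(x$tets), nrow(x$boundary_tris),
              paste(sprintf("%s: %d", levels(x$boundary_tag),
                            tabulate(x$boundary_tag, 3L)), collapse = ", ")))
  invisible(x)
}

# Signed volumes of the linear (vertex) tets, vectorized.
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 2L], , drop = FALSE] - a
  c <- nodes[tets[, 3L], , drop = FALSE] - a
  d <- nodes[tets[, 4L], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

# Areas of boundary triangles (vertex nodes only; quadratic tris are straight).
tri_areas <- function(nodes, tris) {
  a <- nodes[tris[, 1L], , drop = FALSE]
  u <- nodes[tris[, 2L], , drop = FALSE] - a
  v <- nodes[tris[, 3L], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# Structured triangulation of the unit disk: a centre node, `n_r` concentric
# rings of `n_theta` nodes. Returns 2D nodes and a triangle list. The
# triangulated area equals the area of the outer n_theta-gon.
disk_template <- function(n_r, n_theta) {
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  xy <- rbind(c(0, 0),
              do.call(rbind, lapply(seq_len(n_r), function(k)
                cbind(cos(th), sin(th)) * (k / n_r))))
  ring <- function(k) 1L + (k - 1L) * n_theta + seq_len(n_theta)  # node ids
  nxt <- c(seq_len(n_theta)[-1L], 1L)
  tris <- cbind(1L, ring(1L), ring(1L)[nxt])            # central fan
  if (n_r > 1L) {
    for (k in seq_len(n_r - 1L)) {
      a <- ring(k); b <- ring(k + 1L)
      tris <- rbind(tris,
                    cbind(a, b, b[nxt]),
                    cbind(a, b[nxt], a[nxt]))
    }
  }
  list(xy = xy, tris = tris, area = n_theta * sin(2 * pi / n_theta) / 2)
}

#' Build a tube-like tract mesh from an area function
#'
#' Lofts a straight tube with circular (polygonal) cross-sections through an
#' area function: a stack of extruded disk layers tetrahedralized into a
#' conforming, watertight mesh. The end disk at the first station is tagged
#' `glottis`, the end disk at the last station `mouth`, and the lateral
#' surface `wall`. Cross-section polygons are radially scaled so that each
#' section's triangulated area equals the requested cross-sectional area
#' exactly, which keeps geometric summaries faithful to the area function
#' even at moderate angular resolution.
#'
#' @param area_fn An [area_function()].
#' @param target_edge Target element edge length in m. Must resolve the
#'   narrowest cross-section with at least 3 elements across the diameter.
#' @param order Element order: 1 (4-node tets) or 2 (10-node tets, generated
#'   by inserting mid-edge nodes on straight edges).
#' @return A [vt_mesh()].
#' @export
#' @examples
#' af <- area_function(c(0, 0.175), rep(pi * 0.015^2, 2))
#' m <- build_tube_mesh(af, target_edge = 0.01, order = 1)
#' summarize_geometry(m)
build_tube_mesh <- function(area_fn, target_edge, order = 2L) {
  stopifnot(inherits(area_fn, "area_function"),
            is.numeric(target_edge), length(target_edge) == 1L,
            is.finite(target_edge), target_edge > 0)
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("`order` must be 1 or 2")

  r_max <- sqrt(max(area_fn$area) / pi)
  r_min <- sqrt(min(area_fn$area) / pi)
  n_r <- max(2L, as.integer(ceiling(r_max / target_edge)))
  n_theta <- max(12L, as.integer(ceiling(2 * pi * r_max / target_edge)))
  # elements across the narrowest diameter (sections share the template)
  if (2L * n_r * (r_min / r_max) < 3)
    stop("target_edge does not resolve the narrowest cross-section with ",
         ">= 3 elements across the diameter; refine target_edge")

  # refine axial stations so that layer spacing <= target_edge
  st <- area_fn$station
  x <- unlist(lapply(seq_len(length(st) - 1L), function(i) {
    n <- max(1L, ceiling((st[i + 1L] - st[i]) / target_edge))
    st[i] + (st[i + 1L] - st[i]) * (seq_len(n) - 1L) / n
  }))
  x <- c(x, st[length(st)])
  a_x <- interp_area(area_fn, x)

  tpl <- disk_template(n_r, n_theta)
  nn2d <- nrow(tpl$xy)
  n_layers <- length(x)
  scale <- sqrt(a_x / tpl$area)
  nodes <- do.call(rbind, lapply(seq_len(n_layers), function(i)
    cbind(x[i], tpl$xy[, 1L] * scale[i], tpl$xy[, 2L] * scale[i])))

  # ascending-index template triangles give a conforming prism split: each
  # lateral quad is cut by the diagonal from the bottom copy of its smaller
  # column to the top copy of its larger column.
  tpl_tris <- t(apply(tpl$tris, 1L, sort))
  tets <- vector("list", n_layers - 1L)
  for (i in seq_len(n_layers - 1L)) {
    lo <- tpl_tris + (i - 1L) * nn2d
    hi <- lo + nn2d
    p1 <- lo[, 1L]; p2 <- lo[, 2L]; p3 <- lo[, 3L]
    p4 <- hi[, 1L]; p5 <- hi[, 2L]; p6 <- hi[, 3L]
    tets[[i]] <- rbind(cbind(p1, p2, p3, p6),
                       cbind(p1, p2, p6, p5),
                       cbind(p1, p5, p6, p4))
  }
  tets <- do.call(rbind, tets)
  storage.mode(tets) <- "integer"
  v <- tet_volumes(nodes, tets)
  flip <- v < 0
  if (any(flip)) tets[flip, c(3L, 4L)] <- tets[flip, c(4L, 3L)]

  bnd <- boundary_faces(tets)
  fx <- matrix(nodes[bnd, 1L], ncol = 3L)
  tol <- 1e-9 * max(1, diff(range(x)))
  at_lo <- rowSums(abs(fx - x[1L]) < tol) == 3L
  at_hi <- rowSums(abs(fx - x[n_layers]) < tol) == 3L
  tag <- rep("wall", nrow(bnd))
  tag[at_lo] <- "glottis"
  tag[at_hi] <- "mouth"

  if (order == 2L) {
    q <- to_quadratic(nodes, tets, bnd)
    nodes <- q$nodes; tets <- q$tets; bnd <- q$tris
  }
  vt_mesh(nodes, tets, bnd, tag, layer_x = x)
}

# Faces of the tet mesh that occur exactly once (the closed boundary).
boundary_faces <- function(tets) {
  f <- rbind(tets[, c(1L, 2L, 3L)], tets[, c(1L, 2L, 4L)],
             tets[, c(1L, 3L, 4L)], tets[, c(2L, 3L, 4L)])
  fs <- t(apply(f, 1L, sort))
  key <- paste(fs[, 1L], fs[, 2L], fs[, 3L])
  cnt <- table(key)
  keep <- cnt[key] == 1L
  f[keep, , drop = FALSE]
}

# Insert mid-edge nodes: linear tets/tris -> 10-node tets and 6-node tris.
to_quadratic <- function(nodes, tets, tris) {
  ed <- do.call(rbind, lapply(seq_len(nrow(EDGE_ORDER_TET)), function(k)
    cbind(tets[, EDGE_ORDER_TET[k, 1L]], tets[, EDGE_ORDER_TET[k, 2L]])))
  key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  uk <- !duplicated(key)
  mid_id <- nrow(nodes) + match(key, key[uk])
  uniq <- ed[uk, , drop = FALSE]
  mids <- (nodes[uniq[, 1L], , drop = FALSE] +
           nodes[uniq[, 2L], , drop = FALSE]) / 2
  lookup <- seq_len(sum(uk))
  names(lookup) <- key[uk]
  tet10 <- cbind(tets, matrix(mid_id, ncol = nrow(EDGE_ORDER_TET)))
  tri_mid <- sapply(seq_len(nrow(EDGE_ORDER_TRI)), function(k) {
    a <- tris[, EDGE_ORDER_TRI[k, 1L]]; b <- tris[, EDGE_ORDER_TRI[k, 2L]]
    nrow(nodes) + unname(lookup[paste(pmin(a, b), pmax(a, b))])
  })
  if (is.null(dim(tri_mid))) tri_mid <- matrix(tri_mid, nrow = nrow(tris))
  list(nodes = rbind(nodes, mids),
       tets = tet10,
       tris = cbind(tris, tri_mid))
}

#' Summarize the geometry of a tract mesh
#'
#' Per-tag boundary areas and the centerline length, mirroring the
#' geometric measures reported for segmented vocal tracts (mouth-opening
#' area, tissue-contact area, tract length along the mean path).
#'
#' The centerline is the polyline through the centroids of axial
#' cross-section node layers (for generated tube meshes) or of axial slices
#' between the glottis- and mouth-patch centroids (generic meshes), with the
#' patch centroids as end points.
#'
#' @param mesh A [vt_mesh()].
#' @return An object of class `geometry_measures`: list with `mouth_area`,
#'   `wall_area`, `glottis_area` (m2) and `centerline_length` (m).
#' @export
summarize_geometry <- function(mesh) {
  stopifnot(inherits(mesh, "vt_mesh"))
  areas <- tri_areas(mesh$nodes, mesh$boundary_tris)
  by_tag <- vapply(SURFACE_TAGS, function(t) {
    sel <- mesh$boundary_tag == t
    if (!any(sel)) stop(sprintf("missing surface tag: %s", t))
    sum(areas[sel])
  }, numeric(1L))

  centroid_of <- function(tag) {
    tris <- mesh$boundary_tris[mesh$boundary_tag == tag, 1:3, drop = FALSE]
    ids <- unique(as.vector(tris))
    colMeans(mesh$nodes[ids, , drop = FALSE])
  }
  g0 <- centroid_of("glottis"); m0 <- centroid_of("mouth")
  if (!is.null(mesh$layer_x)) {
    # extruded mesh: layers are at known axial stations
    xs <- mesh$nodes[, 1L]
    pts <- t(vapply(mesh$layer_x, function(x0)
      colMeans(mesh$nodes[abs(xs - x0) < 1e-9 * max(1, abs(x0)) + 1e-12, ,
                          drop = FALSE]),
      numeric(3L)))
  } else {
    axis <- m0 - g0
    len <- sqrt(sum(axis^2))
    if (len == 0) stop("glottis and mouth centroids coincide")
    t_par <- as.vector((sweep(mesh$nodes, 2L, g0) %*% axis) / len^2)
    nbin <- 30L
    bin <- pmin(nbin, pmax(1L, ceiling(t_par * nbin)))
    pts <- do.call(rbind, lapply(seq_len(nbin), function(b) {
      sel <- bin == b
      if (!any(sel)) return(NULL)
      colMeans(mesh$nodes[sel, , drop = FALSE])
    }))
    pts <- rbind(g0, pts, m0)
  }
  seglen <- sqrt(rowSums(diff(pts)^2))
  structure(list(mouth_area = by_tag[["mouth"]],
                 wall_area = by_tag[["wall"]],
                 glottis_area = by_tag[["glottis"]],
                 centerline_length = sum(seglen)),
            class = "geometry_measures")
}

#' @export
print.geometry_measures <- function(x, ...) {
  cat(sprintf(paste0("<geometry_measures> mouth %.4g mm2, wall %.4g mm2, ",
                     "glottis %.4g mm2, length %.4g cm\n"),
              x$mouth_area * 1e6, x$wall_area * 1e6, x$glottis_area * 1e6,
              x$centerline_length * 100))
  invisible(x)
}

#' Ratio of tissue-contact area to mouth-opening area
#'
#' For human tracts this ratio spans roughly 24 to 180 depending on vowel
#' and voice mode; it controls how strongly the wall impedance can shape
#' the transfer function relative to the radiation load.
#'
#' @param measures A `geometry_measures` object, or anything with
#'   `wall_area` and `mouth_area` fields.
#' @return `wall_area / mouth_area` (dimensionless).
#' @export
wall_to_mouth_ratio <- function(measures) {
  if (!is.list(measures) || is.null(measures$wall_area) ||
      is.null(measures$mouth_area))
    stop("`measures` must provide wall_area and mouth_area")
  if (measures$mouth_area <= 0) stop("mouth area must be positive")
  measures$wall_area / measures$mouth_area
}

#' Relative elongation of one tract length versus another
#'
#' @param length_a,length_b Lengths in consistent units; `length_b` is the
#'   baseline (must be > 0).
#' @return Percent elongation `100 * (length_a - length_b) / length_b`.
#' @export
relative_elongation <- function(length_a, length_b) {
  stopifnot(is.numeric(length_a), is.numeric(length_b))
  if (any(length_b <= 0)) stop("baseline length must be positive")
  100 * (length_a - length_b) / length_b
}
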