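# Gmsh ASCII v2.2 element type codes
MSH_TRI3 <- 2L; MSH_TET4 <- 4L; MSH_TRI6 <- 9L; MSH_TET10 <- 11L

#' Write a tract mesh to disk
#'
#' Supported formats:
#' \describe{
#'   \item{`msh`}{Gmsh ASCII v2.2 with physical surface groups named
#'     exactly `glottis`, `mouth`, `wall` and a physical volume `cavity`.
#'     Round-trips losslessly through [read_mesh()].}
#'   \item{`stl`}{ASCII STL of the boundary only, one file per tag: for
#'     `path = "m.stl"` the files `m_glottis.stl`, `m_mouth.stl`,
#'     `m_wall.stl` are written (vertex triangles; quadratic boundary
#'     triangles are written as their straight parent triangle).}
#' }
#'
#' @param mesh A [vt_mesh()].
#' @param path Output file path.
#' @param format `"msh"` or `"stl"`.
#' @return `path`, invisibly (for STL, the vector of files written).
#' @export
write_mesh <- function(mesh, path, format = c("msh", "stl")) {
  stopifnot(inherits(mesh, "vt_mesh"))
  format <- match.arg(format)
  if (format == "msh") write_msh(mesh, path) else write_stl(mesh, path)
}

#' Read a tract mesh from disk
#'
#' Reads Gmsh ASCII v2.2 meshes with the physical surface groups `glottis`,
#' `mouth` and `wall`. Missing or unknown group names are an error listing
#' the expected names.
#'
#' @param path Path to a `.msh` file.
#' @param format Only `"msh"` carries the volume mesh and tags needed to
#'   rebuild a [vt_mesh()].
#' @return A [vt_mesh()].
#' @export
read_mesh <- function(path, format = c("msh")) {
  format <- match.arg(format)
  read_msh(path)
}

write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tri_type <- if (mesh$order == 1L) MSH_TRI3 else MSH_TRI6
  tet_type <- if (mesh$order == 1L) MSH_TET4 else MSH_TET10
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  wl("$PhysicalNames", "4",
     sprintf('2 %d "%s"', seq_along(SURFACE_TAGS), SURFACE_TAGS),
     '3 4 "cavity"', "$EndPhysicalNames")
  n <- nrow(mesh$nodes)
  wl("$Nodes", as.character(n),
     sprintf("%d %.17g %.17g %.17g", seq_len(n),
             mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]))
  wl("$EndNodes")
  nb <- nrow(mesh$boundary_tris)
  nt <- nrow(mesh$tets)
  tag_id <- as.integer(mesh$boundary_tag)
  tri_rows <- sprintf("%d %d 2 %d %d %s", seq_len(nb), tri_type, tag_id,
                      tag_id,
                      apply(mesh$boundary_tris, 1L, paste, collapse = " "))
  tet_rows <- sprintf("%d %d 2 4 4 %s", nb + seq_len(nt), tet_type,
                      apply(mesh$tets, 1L, paste, collapse = " "))
  wl("$Elements", as.character(nb + nt), tri_rows, tet_rows, "$EndElements")
  invisible(path)
}

read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop("MSH file lacks section $", name)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(sec("MeshFormat")[1L], "\\s+")[[1L]]
  if (!startsWith(fmt[1L], "2"))
    stop("only Gmsh ASCII v2.x is supported (file is v", fmt[1L], ")")

  pn <- sec("PhysicalNames")
  pn <- pn[-1L]
  toks <- strsplit(pn, "\\s+")
  phys_id <- vapply(toks, function(t) as.integer(t[2L]), integer(1L))
  phys_dim <- vapply(toks, function(t) as.integer(t[1L]), integer(1L))
  phys_name <- vapply(toks, function(t)
    gsub('"', "", paste(t[-(1:2)], collapse = " ")), character(1L))
  surf <- phys_dim == 2L
  unknown <- setdiff(phys_name[surf], SURFACE_TAGS)
  if (length(unknown))
    stop("unknown physical surface group(s): ",
         paste(unknown, collapse = ", "),
         "; expected: ", paste(SURFACE_TAGS, collapse = ", "))
  missing <- setdiff(c("glottis", "mouth"), phys_name[surf])
  if (length(missing))
    stop("MSH file is missing physical surface group(s): ",
         paste(missing, collapse = ", "),
         "; expected groups: ", paste(SURFACE_TAGS, collapse = ", "))
  tag_of <- phys_name
  names(tag_of) <- as.character(phys_id)

  nd <- sec("Nodes")
  n <- as.integer(nd[1L])
  nm <- matrix(as.numeric(unlist(strsplit(nd[1L + seq_len(n)], "\\s+"))),
               ncol = 4L, byrow = TRUE)
  nodes <- nm[order(nm[, 1L]), 2:4, drop = FALSE]

  el <- sec("Elements")
  m <- as.integer(el[1L])
  rows <- strsplit(el[1L + seq_len(m)], "\\s+")
  etype <- vapply(rows, function(r) as.integer(r[2L]), integer(1L))
  ntags <- vapply(rows, function(r) as.integer(r[3L]), integer(1L))
  phys <- vapply(rows, function(r) as.integer(r[4L]), integer(1L))
  conn <- lapply(seq_len(m), function(i)
    as.integer(rows[[i]][-(seq_len(3L + ntags[i]))]))

  is_tri <- etype %in% c(MSH_TRI3, MSH_TRI6)
  is_tet <- etype %in% c(MSH_TET4, MSH_TET10)
  if (!any(is_tet)) stop("MSH file contains no tetrahedra")
  tets <- do.call(rbind, conn[is_tet])
  tris <- do.call(rbind, conn[is_tri])
  tags <- tag_of[as.character(phys[is_tri])]
  if (anyNA(tags))
    stop("boundary element refers to a physical group without a name entry")
  vt_mesh(nodes, tets, tris, tags)
}

write_stl <- function(mesh, path) {
  base <- sub("\\.stl$", "", path, ignore.case = TRUE)
  files <- character(0)
  for (tag in SURFACE_TAGS) {
    sel <- mesh$boundary_tag == tag
    if (!any(sel)) next
    tris <- mesh$boundary_tris[sel, 1:3, drop = FALSE]
    a <- mesh$nodes[tris[, 1L], , drop = FALSE]
    b <- mesh$nodes[tris[, 2L], , drop = FALSE]
    c_ <- mesh$nodes[tris[, 3L], , drop = FALSE]
    u <- b - a; v <- c_ - a
    nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), .Machine$double.xmin)
    f <- sprintf("%s_%s.stl", base, tag)
    vtx <- function(p) sprintf("      vertex %.9e %.9e %.9e",
                               p[, 1], p[, 2], p[, 3])
    blocks <- vapply(seq_len(nrow(tris)), function(i) paste(
      sprintf("  facet normal %.9e %.9e %.9e",
              nx[i] / nn[i], ny[i] / nn[i], nz[i] / nn[i]),
      "    outer loop",
      vtx(a[i, , drop = FALSE]), vtx(b[i, , drop = FALSE]),
      vtx(c_[i, , drop = FALSE]),
      "    endloop", "  endfacet", sep = "\n"), character(1L))
    writeLines(c(sprintf("solid %s", tag), blocks,
                 sprintf("endsolid %s", tag)), f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Export nodal values on a tract mesh as legacy VTK
#'
#' Writes an ASCII legacy-VTK unstructured grid of the (vertex) tets with
#' one point-data scalar field, e.g. the pressure magnitude at one
#' frequency, for visual inspection in ParaView.
#'
#' @param mesh A [vt_mesh()].
#' @param values Numeric vector, one value per mesh node (quadratic
#'   mid-side nodes are dropped together with their tets' corner-only
#'   connectivity).
#' @param path Output `.vtk` path.
#' @param name Field name.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, values, path, name = "pressure") {
  stopifnot(inherits(mesh, "vt_mesh"), length(values) == nrow(mesh$nodes))
  nverts <- max(mesh$tets[, 1:4])
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "vtfem solution snapshot", "ASCII",
     "DATASET UNSTRUCTURED_GRID",
     sprintf("POINTS %d double", nverts),
     sprintf("%.9e %.9e %.9e", mesh$nodes[1:nverts, 1L],
             mesh$nodes[1:nverts, 2L], mesh$nodes[1:nverts, 3L]))
  nt <- nrow(mesh$tets)
  wl(sprintf("CELLS %d %d", nt, 5L * nt),
     sprintf("4 %d %d %d %d", mesh$tets[, 1L] - 1L, mesh$tets[, 2L] - 1L,
             mesh$tets[, 3L] - 1L, mesh$tets[, 4L] - 1L),
     sprintf("CELL_TYPES %d", nt), rep("10", nt),
     sprintf("POINT_DATA %d", nverts),
     sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default",
     sprintf("%.9e", values[1:nverts]))
  invisible(path)
}
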