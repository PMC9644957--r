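# Plain-text mesh interchange: ASCII STL for surfaces and legacy ASCII VTK
# unstructured grids for volumes with node sets, region labels and result
# fields. Only the small subset of each format that the package itself
# writes is supported on read.

#' Write the mesh surface as ASCII STL
#'
#' @param mesh a `skull_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  f <- mesh_boundary_faces(mesh)
  nd <- mesh$nodes
  p1 <- nd[f[, 1], , drop = FALSE]
  p2 <- nd[f[, 2], , drop = FALSE]
  p3 <- nd[f[, 3], , drop = FALSE]
  u <- p2 - p1
  v <- p3 - p1
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$params$label %||% "mesh"), con)
  block <- sprintf(
    paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
           "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
           "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
    nrm[, 1], nrm[, 2], nrm[, 3],
    p1[, 1], p1[, 2], p1[, 3], p2[, 1], p2[, 2], p2[, 3],
    p3[, 1], p3[, 2], p3[, 3])
  writeLines(block, con)
  writeLines("endsolid", con)
  invisible(path)
}

#' Read an ASCII STL surface
#'
#' Returns the triangle soup as written by [write_stl()] (vertices are not
#' merged).
#' @param path STL file path.
#' @return list with `vertices` (3t x 3) and `faces` (t x 3).
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vx <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  t <- nrow(nums) / 3
  list(vertices = nums, faces = matrix(seq_len(3 * t), ncol = 3, byrow = TRUE))
}

#' Write a mesh (and optional result field) as legacy ASCII VTK
#'
#' Writes a VTK 2.0 unstructured grid with the tetrahedra, region labels
#' as cell data, node-set membership as point data, and, when a
#' `stress_field` is supplied, displacements, the stress tensor components
#' and the von Mises scalar. For contour viewing the recommended colour
#' scale is 0-3 MPa; the clamp bounds are written into the header comment.
#'
#' @param mesh a `skull_mesh`.
#' @param path output `.vtk` path.
#' @param field optional `stress_field` from [fe_solve()].
#' @param scale_clamp numeric length-2 recommended contour range, MPa.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, field = NULL, scale_clamp = c(0, 3)) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 2.0",
               sprintf("craniofea mesh '%s' (von Mises contour clamp %g-%g MPa)",
                       mesh$params$label %||% "mesh",
                       scale_clamp[1], scale_clamp[2]),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elements[, 1] - 1,
                     mesh$elements[, 2] - 1, mesh$elements[, 3] - 1,
                     mesh$elements[, 4] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)

  writeLines(sprintf("CELL_DATA %d", m), con)
  regions <- sort(unique(mesh$regions))
  writeLines(c(sprintf("SCALARS region int 1 # %s",
                       paste(seq_along(regions), regions, sep = "=",
                             collapse = " ")),
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$regions, regions)), con)
  if (!is.null(field)) {
    writeLines(c("SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", field$von_mises), con)
    writeLines("TENSORS stress double", con)
    s <- field$element_stress
    writeLines(sprintf("%.9g %.9g %.9g %.9g %.9g %.9g %.9g %.9g %.9g",
                       s[, "xx"], s[, "xy"], s[, "zx"],
                       s[, "xy"], s[, "yy"], s[, "yz"],
                       s[, "zx"], s[, "yz"], s[, "zz"]), con)
  }

  writeLines(sprintf("POINT_DATA %d", n), con)
  if (length(mesh$node_sets)) {
    member <- integer(n)
    for (i in seq_along(mesh$node_sets)) {
      member[mesh$node_sets[[i]]] <- i
    }
    writeLines(c(sprintf("SCALARS node_set int 1 # %s",
                         paste(seq_along(mesh$node_sets),
                               names(mesh$node_sets), sep = "=",
                               collapse = " ")),
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(member), con)
  }
  if (!is.null(field)) {
    writeLines("VECTORS displacement double", con)
    u <- field$displacements
    writeLines(sprintf("%.9g %.9g %.9g", u[, 1], u[, 2], u[, 3]), con)
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid
#'
#' Reads back the subset written by [write_vtk()]: points, tetrahedral
#' cells and the region-label cell data.
#' @param path `.vtk` file path.
#' @return list with `nodes`, `elements` (1-based) and `regions`
#'   (character, when present).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cl <- scan(text = lines[(ic + 1):(ic + m)], quiet = TRUE)
  cl <- matrix(cl, ncol = 5, byrow = TRUE)
  if (any(cl[, 1] != 4)) stop("only tetrahedral cells supported")
  elements <- cl[, 2:5] + 1L
  regions <- NULL
  ir <- grep("^SCALARS region", lines)
  if (length(ir)) {
    lab <- sub("^.*# ", "", lines[ir[1]])
    map <- strsplit(strsplit(lab, " ")[[1]], "=")
    nm <- vapply(map, `[`, "", 2)
    vals <- scan(text = lines[(ir[1] + 2):(ir[1] + 1 + m)], quiet = TRUE)
    regions <- nm[vals]
  }
  list(nodes = nodes, elements = elements, regions = regions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
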