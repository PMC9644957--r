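#' Structured tetrahedral box mesh
#'
#' Rectangular block `[0, lx] x [-ly/2, ly/2] x [0, lz]` meshed with a
#' structured hexahedral grid, each cell split into six conforming linear
#' tetrahedra. Used for solver verification (patch test, prismatic bar,
#' cantilever bending) and available for custom checks.
#'
#' @param lx,ly,lz box dimensions, mm.
#' @param nx,ny,nz cell counts along each axis.
#' @param regions optional function `f(centroids)` returning a character
#'   region label per element.
#' @return a list with `nodes`, `elements` and (optionally) `regions`,
#'   usable by [assemble_stiffness()], [fe_solve()] and
#'   [region_summary()].
#' @export
#' @examples
#' b <- tet_box_mesh(10, 2, 2, 5, 2, 2)
#' nrow(b$elements) # 5*2*2*6 tetrahedra
tet_box_mesh <- function(lx, ly, lz, nx, ny, nz, regions = NULL) {
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(-ly / 2, ly / 2, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  grid <- expand.grid(i = seq_len(nx + 1), j = seq_len(ny + 1),
                      k = seq_len(nz + 1))
  nodes <- cbind(xs[grid$i], ys[grid$j], zs[grid$k])
  idx <- function(i, j, k) i + (nx + 1) * ((j - 1) + (ny + 1) * (k - 1))
  cells <- expand.grid(ci = seq_len(nx), cj = seq_len(ny), ck = seq_len(nz))
  corner <- function(di, dj, dk) idx(cells$ci + di, cells$cj + dj,
                                     cells$ck + dk)
  cn <- cbind(corner(0, 0, 0), corner(1, 0, 0), corner(1, 1, 0),
              corner(0, 1, 0), corner(0, 0, 1), corner(1, 0, 1),
              corner(1, 1, 1), corner(0, 1, 1))
  tm <- hex_tet_templates()$right
  elements <- do.call(rbind, lapply(seq_len(6), function(t) {
    cbind(cn[, tm[t, 1]], cn[, tm[t, 2]], cn[, tm[t, 3]], cn[, tm[t, 4]])
  }))
  out <- list(nodes = nodes, elements = elements,
              params = list(label = "box"))
  if (!is.null(regions)) {
    cent <- (nodes[elements[, 1], ] + nodes[elements[, 2], ] +
               nodes[elements[, 3], ] + nodes[elements[, 4], ]) / 4
    out$regions <- regions(cent)
  }
  out
}
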