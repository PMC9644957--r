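# Shared fixtures built in code: coarse morphotype presets for quick mesh
# tests and a toy two-node "muscle" mesh for force-vector arithmetic.

coarse_gracile <- function(edge = 7) {
  morphotype_preset("gracile", target_edge_length = edge)
}

coarse_robust <- function(edge = 9) {
  morphotype_preset("robust", target_edge_length = edge)
}

# Memoized coarse meshes (building is deterministic, so cache per session).
.mesh_cache <- new.env(parent = emptyenv())
cached_mesh <- function(key, builder) {
  if (is.null(.mesh_cache[[key]])) .mesh_cache[[key]] <- builder()
  .mesh_cache[[key]]
}

gracile_mesh_coarse <- function() {
  cached_mesh("gracile7", function() {
    suppressWarnings(build_skull_mesh(coarse_gracile()))
  })
}

robust_mesh_coarse <- function() {
  cached_mesh("robust9", function() {
    suppressWarnings(build_skull_mesh(coarse_robust()))
  })
}

# A single-tetrahedron-pair toy mesh whose "origin" node sits directly
# above the "insertion" node: unit-vector arithmetic is then trivial.
toy_muscle_mesh <- function() {
  nodes <- rbind(c(0, 0, 10),  # origin node
                 c(0, 0, 0),   # insertion node
                 c(5, 0, 0), c(0, 5, 0), c(5, 5, 5), c(-5, 0, 5))
  elements <- rbind(c(2, 3, 4, 1), c(2, 4, 3, 5), c(1, 2, 4, 6))
  # orient all tets positively
  vol <- element_volumes(list(nodes = nodes, elements = elements))
  elements[vol < 0, c(3, 4)] <- elements[vol < 0, c(4, 3)]
  list(nodes = nodes, elements = elements,
       node_sets = list(origin_mAMP_right = 1L,
                        insertion_mandible_external_right = 2L),
       params = list(label = "toy"))
}

# Independent quadrature oracle for the parametric solid volume: section
# area by shoelace over a finely sampled mapped boundary, trapezoid rule
# along x. Never touches the mesh.
analytic_skull_volume <- function(params, nb = 360, nx = 600) {
  prof <- craniofea:::skull_profiles(params)
  t <- seq(0, 4, length.out = nb + 1)[-(nb + 1)]
  eta <- ifelse(t < 1, -1 + 2 * t,
                ifelse(t < 2, 1, ifelse(t < 3, 1 - 2 * (t - 2), -1)))
  zeta <- ifelse(t < 1, -1,
                 ifelse(t < 2, -1 + 2 * (t - 1), ifelse(t < 3, 1,
                                                        1 - 2 * (t - 3))))
  area <- function(x) {
    pts <- craniofea:::map_section(rep(x, nb), eta, zeta, prof)
    y <- pts[, 2]
    z <- pts[, 3]
    abs(sum(y * c(z[-1], z[1]) - c(y[-1], y[1]) * z)) / 2
  }
  xs <- seq(0, params$total_skull_length, length.out = nx + 1)
  as <- vapply(xs, area, numeric(1))
  sum((as[-1] + as[-length(as)]) / 2 * diff(xs))
}

element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elements[, 1], ] + mesh$nodes[mesh$elements[, 2], ] +
     mesh$nodes[mesh$elements[, 3], ] + mesh$nodes[mesh$elements[, 4], ]) / 4
}
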