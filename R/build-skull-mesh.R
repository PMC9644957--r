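# Parametric skull solid generator.
#
# The solid is a structured hexahedral grid, each hexahedron split into six
# conforming linear tetrahedra. Cross-sections are square-to-ellipse blends:
# near-rectangular in the posterior cranium, near-elliptical along the rostrum.
# The ventral margin is held at z ~ 0 along the whole skull (flat tooth-row
# line); the dorsal profile drops anteriorly with the taper.

# Cross-section profile functions for a morphotype: width W(x), height H(x)
# and square-to-ellipse blend factor s(x). The cranium-to-rostrum transition
# is a smoothstep over the anterior quarter of the cranium.
skull_profiles <- function(params) {
  L <- params$total_skull_length
  lc <- L * (1 - params$rostrum_fraction)
  tr <- 0.25 * lc
  sstep <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    u * u * (3 - 2 * u)
  }
  taper <- function(x, base, tipf) {
    u <- (L - x) / (L - lc) # 1 at rostrum base, 0 at tip
    base * (tipf + (1 - tipf) * u^params$taper_exponent)
  }
  width <- function(x) {
    ifelse(x <= lc,
           params$cranium_width +
             (params$rostrum_base_width - params$cranium_width) *
             sstep((x - (lc - tr)) / tr),
           taper(x, params$rostrum_base_width, params$tip_fraction))
  }
  height <- function(x) {
    ifelse(x <= lc,
           params$cranium_height +
             (params$rostrum_base_height - params$cranium_height) *
             sstep((x - (lc - tr)) / tr),
           taper(x, params$rostrum_base_height, params$tip_fraction))
  }
  blend <- function(x) {
    0.25 + 0.6 * pmin(pmax((x - (lc - tr)) / (L - (lc - tr)), 0), 1)
  }
  list(width = width, height = height, blend = blend,
       cranium_end = lc, length = L)
}

# Map grid coordinates (x, eta, zeta) in [x] x [-1,1]^2 to physical
# coordinates with the blended square-to-ellipse section.
map_section <- function(x, eta, zeta, prof) {
  s <- prof$blend(x)
  w <- prof$width(x)
  h <- prof$height(x)
  y <- (w / 2) * eta * sqrt(1 - s * zeta^2 / 2)
  z <- (h / 2) * (1 + zeta * sqrt(1 - s * eta^2 / 2))
  cbind(x, y, z)
}

# Six-tetrahedron decomposition of the unit hexahedron, all sharing the
# 0-6 main diagonal. Conforms across neighbouring cells when every cell on
# one side of the symmetry plane uses the template and the other side its
# y-mirror (then face diagonals match across the midplane as well, and the
# element centroids are exactly bilaterally paired).
hex_tet_templates <- function() {
  ta <- rbind(c(0, 1, 2, 6), c(0, 2, 3, 6), c(0, 3, 7, 6),
              c(0, 7, 4, 6), c(0, 4, 5, 6), c(0, 5, 1, 6))
  mirror <- c(3, 2, 1, 0, 7, 6, 5, 4) # y-mirror of local corner ids
  tb <- matrix(mirror[ta + 1], ncol = 4)
  tb <- tb[, c(1, 2, 4, 3)] # restore positive orientation
  list(right = ta + 1, left = tb + 1) # to 1-based corner ids
}

# Nearest-k surface nodes to an anchor, optionally restricted to one side.
pick_patch <- function(nodes, candidates, anchor, k, set_name) {
  if (length(candidates) < k) {
    stop("cannot build node set '", set_name, "': only ",
         length(candidates), " candidate nodes for ", k, " requested ",
         "(target_edge_length too coarse)", call. = FALSE)
  }
  d <- sqrt(colSums((t(nodes[candidates, , drop = FALSE]) - anchor)^2))
  candidates[order(d)[seq_len(k)]]
}

# Anchor table for the seven muscle origins and four insertion areas, on
# the right side (y > 0); x and z are fractions of cranium length/height,
# y is a fraction of the local half-width. Placement follows standard
# diapsid jaw-muscle topology: external adductors on the temporal rim,
# internal pseudotemporalis antero-dorsally, pterygoideus on the palatal
# flange, posterior adductor at the quadrate, depressor behind the joint;
# insertion proxies sit ventro-laterally where the mandible would lie.
attachment_anchor_table <- function() {
  rbind(
    data.frame(set = "origin_mAMEpr",  xf = 0.38, yf = 0.35, zf = 0.92, k = 40),
    data.frame(set = "origin_mAMEsu",  xf = 0.46, yf = 0.85, zf = 0.80, k = 46),
    data.frame(set = "origin_mAMEme",  xf = 0.50, yf = 0.85, zf = 0.70, k = 46),
    data.frame(set = "origin_mAMIps",  xf = 0.58, yf = 0.35, zf = 0.90, k = 62),
    data.frame(set = "origin_mAMIpt",  xf = 0.55, yf = 0.45, zf = 0.08, k = 64),
    data.frame(set = "origin_mAMP",    xf = 0.17, yf = 0.85, zf = 0.35, k = 38),
    data.frame(set = "origin_mDM",     xf = 0.06, yf = 0.45, zf = 0.90, k = 52),
    data.frame(set = "insertion_coronoid",          xf = 0.50, yf = 0.95, zf = 0.12, k = 130),
    data.frame(set = "insertion_angular",           xf = 0.13, yf = 0.80, zf = 0.06, k = 64),
    data.frame(set = "insertion_mandible_external", xf = 0.22, yf = 0.95, zf = 0.15, k = 40),
    data.frame(set = "insertion_surangular",        xf = 0.02, yf = 0.75, zf = 0.30, k = 54)
  )
}

# Map every node to its bilateral mirror (y -> -y); NA when no partner
# exists within tolerance. Node sets are derived on the right side and
# mirrored, so left/right sets are exact bilateral pairs regardless of
# tie-breaking in the selection.
node_mirror_map <- function(nodes, tol = 1e-6) {
  key <- function(m) paste(round(m[, 1] / tol), round(m[, 2] / tol),
                           round(m[, 3] / tol))
  mirrored <- nodes
  mirrored[, 2] <- -mirrored[, 2]
  match(key(mirrored), key(nodes))
}

# Select one 20-node bite set (5 nodes x 2 teeth x 2 sides) centred at
# tooth-row position x_b on the ventral margin: right side selected,
# left side mirrored.
pick_bite_set <- function(nodes, surf, prof, x_b, tooth_gap, mirror,
                          nodes_per_tooth = 5) {
  right <- integer(0)
  for (x_t in c(x_b - tooth_gap / 2, x_b + tooth_gap / 2)) {
    w <- prof$width(x_t)
    cand <- surf[nodes[surf, 2] > 0 &
                   nodes[surf, 3] < 0.45 * prof$height(nodes[surf, 1])]
    cand <- setdiff(cand, right)
    anchor <- c(x_t, 0.45 * w / 2, 0)
    right <- c(right, pick_patch(nodes, cand, anchor, nodes_per_tooth,
                                 sprintf("bite tooth at x=%.1f", x_t)))
  }
  sort(c(right, mirror[right]))
}

# Derive region labels from element centroids. `x_ant` is the anterior
# extent of the (possibly truncated) mesh: nasal = dorsal posterior half of
# the remaining rostrum, the geometric proxy for the nasal-bone area.
derive_regions <- function(cent, prof, params, x_ant) {
  lc <- prof$cranium_end
  ro <- params$orbit_diameter / 2
  xo <- 0.72 * lc
  zo <- 0.55 * params$cranium_height
  reg <- rep("posterior_cranium", nrow(cent))
  rost <- cent[, 1] > lc
  reg[rost] <- "rostrum"
  nasal_end <- lc + 0.5 * (x_ant - lc)
  reg[rost & cent[, 1] <= nasal_end &
        cent[, 3] > prof$height(cent[, 1]) / 2] <- "nasal"
  orb <- !rost & (cent[, 1] - xo)^2 + (cent[, 3] - zo)^2 <
    (ro + params$target_edge_length)^2
  reg[orb] <- "orbital"
  pal <- !rost & !orb & cent[, 3] < 0.18 * params$cranium_height
  reg[pal] <- "palate"
  reg
}

# Re-derive all node sets on a (possibly truncated) mesh body.
derive_node_sets <- function(nodes, elements, prof, params,
                             nodes_per_tooth = 5) {
  tmp <- list(nodes = nodes, elements = elements)
  surf <- surface_nodes(tmp)
  lc <- prof$cranium_end
  ch <- params$cranium_height
  x_ant <- max(nodes[, 1])
  sets <- list()

  mirror <- node_mirror_map(nodes)
  if (anyNA(mirror[surf])) {
    stop("surface nodes are not bilaterally paired", call. = FALSE)
  }

  anch <- attachment_anchor_table()
  for (r in seq_len(nrow(anch))) {
    x <- anch$xf[r] * lc
    anchor <- c(x, anch$yf[r] * prof$width(x) / 2, anch$zf[r] * ch)
    cand <- surf[nodes[surf, 2] > 0 & nodes[surf, 1] <= lc * 1.05]
    rset <- sort(pick_patch(nodes, cand, anchor, anch$k[r],
                            paste0(anch$set[r], "_right")))
    sets[[paste0(anch$set[r], "_right")]] <- rset
    sets[[paste0(anch$set[r], "_left")]] <- sort(mirror[rset])
  }

  # Basicranium constraint patches emulate the small occipital-condyle
  # contact area: anchored at the posterior ventral margin and kept
  # compact anteroposteriorly (x-distance triple-weighted in the metric),
  # so the patch does not grow into a long strip on coarse meshes and
  # spuriously absorb the pitching moment that the bite points react.
  cand <- surf[nodes[surf, 2] > 0 & nodes[surf, 1] <= 0.3 * lc &
                 nodes[surf, 3] < 0.25 * ch]
  if (length(cand) < 10) {
    stop("cannot build basicranium patch: mesh too coarse", call. = FALSE)
  }
  anchor <- c(0, 0.2 * prof$width(0) / 2, 0)
  d <- sqrt(9 * (nodes[cand, 1] - anchor[1])^2 +
              (nodes[cand, 2] - anchor[2])^2 +
              (nodes[cand, 3] - anchor[3])^2)
  rset <- sort(cand[order(d)[1:10]])
  sets$basicranium_right <- rset
  sets$basicranium_left <- sort(mirror[rset])

  row_start <- params$tooth_row_start_fraction * prof$length
  dx <- prof$length / max(8, ceiling(prof$length / params$target_edge_length))
  tooth_gap <- 1.5 * dx
  x_tip <- x_ant - tooth_gap
  x_mid <- (row_start + x_ant) / 2
  sets$bite_posterior <- pick_bite_set(nodes, surf, prof, row_start,
                                       tooth_gap, mirror, nodes_per_tooth)
  sets$bite_mid <- pick_bite_set(nodes, surf, prof, x_mid, tooth_gap,
                                 mirror, nodes_per_tooth)
  sets$bite_anterior <- pick_bite_set(nodes, surf, prof, x_tip, tooth_gap,
                                      mirror, nodes_per_tooth)
  sets
}

#' Build a parametric tetrahedral skull mesh
#'
#' Generates a watertight linear-tetrahedral solid for one morphotype: an
#' elongated tapered rostrum (blended square-to-elliptical cross-section,
#' shrinking anteriorly according to the taper exponent) fused to a
#' box-like posterior cranium with lateral orbital voids. All node sets
#' required by the load-case stages (seven paired muscle origins, four
#' paired insertion areas, paired basicranium constraint patches, and
#' three 20-node bite sets) are derived deterministically from the
#' geometry, so identical parameters always give identical meshes.
#'
#' @param params a [morphotype_params()] object (see [morphotype_preset()]
#'   for the two shipped morphotypes).
#' @param include_orbit carve the lateral orbital voids (default `TRUE`);
#'   `FALSE` yields the plain parametric solid, used by the analytic
#'   volume checks.
#' @param aspect_bound maximum tolerated element edge aspect ratio;
#'   elements above the bound are reported via a warning and recorded in
#'   the returned object, never silently accepted.
#' @return a `skull_mesh` object (see [validate_skull_mesh()] for its
#'   invariants).
#' @export
#' @examples
#' p <- morphotype_preset("gracile", target_edge_length = 7)
#' m <- build_skull_mesh(p)
#' m
build_skull_mesh <- function(params, include_orbit = TRUE,
                             aspect_bound = 8) {
  validate_morphotype_params(params)
  prof <- skull_profiles(params)
  L <- prof$length
  edge <- params$target_edge_length

  nx <- max(8, ceiling(L / edge))
  ny <- 2 * max(1, ceiling(params$rostrum_base_width / (2 * edge)))
  nz <- max(3, ceiling(params$rostrum_base_height / edge))

  xs <- seq(0, L, length.out = nx + 1)
  etas <- seq(-1, 1, length.out = ny + 1)
  # exact bitwise antisymmetry of the lateral grid, so mirrored nodes are
  # exact negations and left/right tie-breaking cannot diverge
  etas <- (etas - rev(etas)) / 2
  zetas <- seq(-1, 1, length.out = nz + 1)

  grid <- expand.grid(i = seq_len(nx + 1), j = seq_len(ny + 1),
                      k = seq_len(nz + 1))
  nodes <- map_section(xs[grid$i], etas[grid$j], zetas[grid$k], prof)
  idx <- function(i, j, k) i + (nx + 1) * ((j - 1) + (ny + 1) * (k - 1))

  cells <- expand.grid(ci = seq_len(nx), cj = seq_len(ny), ck = seq_len(nz))
  corner <- function(di, dj, dk) idx(cells$ci + di, cells$cj + dj,
                                     cells$ck + dk)
  # local corners 0..7 of each hexahedron
  cn <- cbind(corner(0, 0, 0), corner(1, 0, 0), corner(1, 1, 0),
              corner(0, 1, 0), corner(0, 0, 1), corner(1, 0, 1),
              corner(1, 1, 1), corner(0, 1, 1))

  if (include_orbit) {
    cx <- (xs[cells$ci] + xs[cells$ci + 1]) / 2
    ceta <- (etas[cells$cj] + etas[cells$cj + 1]) / 2
    czeta <- (zetas[cells$ck] + zetas[cells$ck + 1]) / 2
    cc <- map_section(cx, ceta, czeta, prof)
    xo <- 0.72 * prof$cranium_end
    zo <- 0.55 * params$cranium_height
    ro <- params$orbit_diameter / 2
    inside <- (cc[, 1] - xo)^2 + (cc[, 3] - zo)^2 < ro^2 &
      abs(cc[, 2]) > 0.35 * prof$width(cc[, 1]) / 2
    if (any(inside)) {
      keep <- !inside
      cells <- cells[keep, , drop = FALSE]
      cn <- cn[keep, , drop = FALSE]
    }
  }

  tmpl <- hex_tet_templates()
  right <- cells$cj > ny / 2
  build_side <- function(rows, tm) {
    do.call(rbind, lapply(seq_len(6), function(t) {
      cbind(cn[rows, tm[t, 1]], cn[rows, tm[t, 2]],
            cn[rows, tm[t, 3]], cn[rows, tm[t, 4]])
    }))
  }
  elements <- rbind(build_side(right, tmpl$right),
                    build_side(!right, tmpl$left))

  # drop unreferenced nodes and renumber
  used <- sort(unique(as.vector(elements)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  elements <- matrix(remap[elements], ncol = 4)

  vol <- element_volumes(list(nodes = nodes, elements = elements))
  if (any(vol <= 0)) {
    stop("degenerate geometry: element ", which(vol <= 0)[1],
         " has non-positive volume (check taper_exponent and ",
         "tip_fraction)", call. = FALSE)
  }

  cent <- (nodes[elements[, 1], ] + nodes[elements[, 2], ] +
             nodes[elements[, 3], ] + nodes[elements[, 4], ]) / 4
  regions <- derive_regions(cent, prof, params, max(nodes[, 1]))
  sets <- derive_node_sets(nodes, elements, prof, params)

  mesh <- skull_mesh(nodes, elements, sets, regions, params,
                     extra = list(cranium_end = prof$cranium_end,
                                  anterior_x = max(nodes[, 1]),
                                  nx = nx, ny = ny, nz = nz))
  ar <- element_aspect_ratios(mesh)
  bad <- which(ar > aspect_bound)
  mesh$aspect_violations <- bad
  if (length(bad)) {
    warning(length(bad), " element(s) exceed the aspect-ratio bound of ",
            aspect_bound, " (max ", round(max(ar), 1), ")", call. = FALSE)
  }
  mesh
}

#' Truncate the rostrum of a skull mesh
#'
#' Removes all elements whose centroid lies anterior to
#' `keep_fraction * total_skull_length`, emulating a specimen whose
#' anterior rostrum is missing. All node sets are re-derived on the
#' truncated body: posterior sets (muscle attachments, basicranium) are
#' preserved, `bite_anterior` relocates to the new anterior-most tooth
#' position, `bite_mid` to the middle of the remaining tooth row, and the
#' nasal region becomes the dorsal posterior half of the remaining rostrum.
#'
#' @param mesh a `skull_mesh` built by [build_skull_mesh()].
#' @param keep_fraction fraction of the total skull length to keep, in
#'   (0, 1]. `1` returns the mesh unchanged. The cut plane must fall in
#'   the rostrum region: a cut at or behind the rostrum base would remove
#'   muscle attachment or constraint sets and is an error.
#' @return a truncated `skull_mesh`.
#' @export
truncate_rostrum <- function(mesh, keep_fraction) {
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    stop("'keep_fraction' must lie in (0, 1]", call. = FALSE)
  }
  if (keep_fraction == 1) {
    return(mesh)
  }
  params <- mesh$params
  prof <- skull_profiles(params)
  x_cut <- keep_fraction * params$total_skull_length
  if (x_cut <= prof$cranium_end + params$target_edge_length) {
    stop("cut plane at x = ", round(x_cut, 1),
         " mm would remove muscle attachment or constraint sets ",
         "(rostrum starts at x = ", round(prof$cranium_end, 1), " mm)",
         call. = FALSE)
  }
  row_start <- params$tooth_row_start_fraction * params$total_skull_length
  if (x_cut <= row_start + 2 * params$target_edge_length) {
    stop("cut plane at x = ", round(x_cut, 1),
         " mm leaves no usable tooth row (row starts at x = ",
         round(row_start, 1), " mm)", call. = FALSE)
  }

  nodes <- mesh$nodes
  el <- mesh$elements
  cent_x <- (nodes[el[, 1], 1] + nodes[el[, 2], 1] +
               nodes[el[, 3], 1] + nodes[el[, 4], 1]) / 4
  keep <- cent_x < x_cut
  el <- el[keep, , drop = FALSE]
  used <- sort(unique(as.vector(el)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  new_nodes <- nodes[used, , drop = FALSE]
  el <- matrix(remap[el], ncol = 4)

  cent <- (new_nodes[el[, 1], ] + new_nodes[el[, 2], ] +
             new_nodes[el[, 3], ] + new_nodes[el[, 4], ]) / 4
  regions <- derive_regions(cent, prof, params, max(new_nodes[, 1]))
  sets <- derive_node_sets(new_nodes, el, prof, params)

  out <- skull_mesh(new_nodes, el, sets, regions, params,
                    extra = utils::modifyList(mesh$extra,
                      list(anterior_x = max(new_nodes[, 1]),
                           truncated_at = x_cut)))
  out$aspect_violations <- which(element_aspect_ratios(out) > 8)
  out
}
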