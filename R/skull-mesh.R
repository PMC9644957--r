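#' Tetrahedral skull mesh
#'
#' Container for a watertight linear-tetrahedral solid with the named node
#' sets and anatomical regions the downstream stages need. Constructed by
#' [build_skull_mesh()]; users normally never call this directly.
#'
#' @param nodes numeric matrix (n x 3) of node coordinates, mm.
#' @param elements integer matrix (m x 4) of 1-based node indices; every
#'   tetrahedron must have positive signed volume.
#' @param node_sets named list of integer node-index vectors (muscle
#'   origins and insertions, basicranium constraints, bite points).
#' @param regions character vector of length m assigning each element to
#'   one of `rostrum`, `nasal`, `orbital`, `posterior_cranium`, `palate`.
#' @param params the [morphotype_params()] the mesh was built from.
#' @param extra named list of derived geometry (cranium extent, tooth-row
#'   span, anterior extent) kept for truncation and load-case building.
#' @return an object of class `skull_mesh`.
#' @keywords internal
skull_mesh <- function(nodes, elements, node_sets, regions, params, extra) {
  m <- structure(
    list(nodes = nodes, elements = elements, node_sets = node_sets,
         regions = regions, params = params,
         symmetry_plane = list(normal = c(0, 1, 0), offset = 0),
         extra = extra),
    class = "skull_mesh")
  m
}

#' Signed volumes of all tetrahedra
#'
#' @param mesh a `skull_mesh` (or any list with `nodes` and `elements`).
#' @return numeric vector of signed volumes, mm^3.
#' @export
element_volumes <- function(mesh) {
  nd <- mesh$nodes
  el <- mesh$elements
  a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  c3 <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  det / 6
}

#' Total mesh volume
#' @param mesh a `skull_mesh`.
#' @return total volume, mm^3.
#' @export
mesh_volume <- function(mesh) sum(element_volumes(mesh))

#' Element edge aspect ratios
#'
#' Longest-to-shortest edge ratio of every tetrahedron. The generator
#' reports (with a warning) any element above the configured bound rather
#' than silently accepting it.
#'
#' @param mesh a `skull_mesh`.
#' @return numeric vector of aspect ratios, one per element.
#' @export
element_aspect_ratios <- function(mesh) {
  nd <- mesh$nodes
  el <- mesh$elements
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  lens <- matrix(0, nrow(el), 6)
  for (p in seq_len(6)) {
    d <- nd[el[, pairs[p, 1]], , drop = FALSE] -
      nd[el[, pairs[p, 2]], , drop = FALSE]
    lens[, p] <- sqrt(rowSums(d^2))
  }
  apply(lens, 1, max) / apply(lens, 1, min)
}

#' Boundary faces of a tetrahedral mesh
#'
#' Faces belonging to exactly one tetrahedron. A watertight solid has a
#' closed boundary: every face appears either once (surface) or twice
#' (interior); any face appearing more than twice indicates a broken mesh.
#'
#' @param mesh a `skull_mesh`.
#' @return integer matrix (f x 3) of node indices of the boundary faces.
#' @export
mesh_boundary_faces <- function(mesh) {
  el <- mesh$elements
  f <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)],
             el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  n <- max(hi) + 1
  key <- lo + n * (mid + n * hi) # unique per unordered face
  cnt <- table(key)
  if (any(cnt > 2)) stop("non-manifold mesh: a face is shared by > 2 elements")
  once <- as.numeric(names(cnt)[cnt == 1])
  f[key %in% once, , drop = FALSE]
}

#' Surface node indices
#' @param mesh a `skull_mesh`.
#' @return sorted integer vector of nodes lying on the mesh boundary.
#' @export
surface_nodes <- function(mesh) sort(unique(as.vector(mesh_boundary_faces(mesh))))

#' Is the mesh a single connected component?
#'
#' Breadth-first search over node-sharing element adjacency (via nodes:
#' two elements are connected if they share at least one node).
#' @param mesh a `skull_mesh`.
#' @return `TRUE` if all elements are reachable from the first.
#' @export
mesh_is_connected <- function(mesh) {
  n <- nrow(mesh$nodes)
  el <- mesh$elements
  # union-find over nodes
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (c in 2:4) {
    a <- el[, 1]
    b <- el[, c]
    for (r in seq_along(a)) {
      ra <- find(a[r]); rb <- find(b[r])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(unique(as.vector(el)), find, integer(1))
  length(unique(roots)) == 1
}

#' Check bilateral node symmetry
#'
#' Verifies that mirroring every node across the symmetry plane (y = 0)
#' lands on another mesh node within `tol`.
#'
#' @param mesh a `skull_mesh`.
#' @param tol matching tolerance, mm.
#' @return `TRUE`/`FALSE`.
#' @export
mesh_is_bilateral <- function(mesh, tol = 1e-6) {
  key <- function(m) paste(round(m[, 1] / tol), round(m[, 2] / tol),
                           round(m[, 3] / tol))
  mirrored <- mesh$nodes
  mirrored[, 2] <- -mirrored[, 2]
  all(key(mirrored) %in% key(mesh$nodes))
}

#' Validate a skull mesh
#'
#' Checks the structural invariants: positive element volumes, node-set
#' indices in range, required node sets present with the configured bite
#' count, single connected component, and bilateral node symmetry.
#'
#' @param mesh a `skull_mesh`.
#' @param bite_count required size of each bite node set (default 20 = 5
#'   nodes per tooth x 2 teeth x 2 sides).
#' @return `mesh`, invisibly, if valid; otherwise an error.
#' @export
validate_skull_mesh <- function(mesh, bite_count = 20) {
  vol <- element_volumes(mesh)
  if (any(vol <= 0)) {
    stop("inverted element(s): ", paste(utils::head(which(vol <= 0)),
                                        collapse = ", "), call. = FALSE)
  }
  n <- nrow(mesh$nodes)
  for (s in names(mesh$node_sets)) {
    idx <- mesh$node_sets[[s]]
    if (any(idx < 1 | idx > n)) {
      stop("node set '", s, "' references nodes outside the mesh",
           call. = FALSE)
    }
  }
  need <- c(paste0("origin_", c("mAMEpr", "mAMEsu", "mAMEme", "mAMIps",
                                "mAMIpt", "mAMP", "mDM"), "_left"),
            paste0("origin_", c("mAMEpr", "mAMEsu", "mAMEme", "mAMIps",
                                "mAMIpt", "mAMP", "mDM"), "_right"),
            paste0("insertion_", c("coronoid", "angular",
                                   "mandible_external", "surangular"),
                   "_left"),
            paste0("insertion_", c("coronoid", "angular",
                                   "mandible_external", "surangular"),
                   "_right"),
            "basicranium_left", "basicranium_right",
            "bite_anterior", "bite_mid", "bite_posterior")
  missing <- setdiff(need, names(mesh$node_sets))
  if (length(missing)) {
    stop("missing node sets: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (b in c("bite_anterior", "bite_mid", "bite_posterior")) {
    if (length(mesh$node_sets[[b]]) != bite_count) {
      stop("bite set '", b, "' has ", length(mesh$node_sets[[b]]),
           " nodes, expected ", bite_count, call. = FALSE)
    }
  }
  if (!mesh_is_connected(mesh)) {
    stop("mesh is not a single connected component", call. = FALSE)
  }
  if (!mesh_is_bilateral(mesh)) {
    stop("mesh nodes are not bilaterally symmetric about y = 0",
         call. = FALSE)
  }
  invisible(mesh)
}

#' @export
print.skull_mesh <- function(x, ...) {
  cat("Skull mesh '", x$params$label, "': ", nrow(x$nodes), " nodes, ",
      nrow(x$elements), " tetrahedra\n", sep = "")
  cat("  extent x: [", round(min(x$nodes[, 1]), 1), ", ",
      round(max(x$nodes[, 1]), 1), "] mm; volume ",
      round(mesh_volume(x)), " mm^3\n", sep = "")
  rg <- table(x$regions)
  cat("  regions:", paste(names(rg), rg, sep = "=", collapse = ", "), "\n")
  cat("  node sets:", length(x$node_sets), "\n")
  invisible(x)
}
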