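# Linear-elastic small-deformation FEM on 4-node (constant-strain)
# tetrahedra, mm-N-MPa unit system. Sparse assembly and direct sparse
# Cholesky factorization via the Matrix package; constraints by freedom
# elimination so reaction forces are recovered exactly.

#' Isotropic linear-elastic material
#'
#' Homogeneous isotropic bone everywhere — no sutures, no cartilage,
#' matching an akinetic-skull idealization. The defaults are cranial-bone
#' values used for extant crocodilians.
#'
#' @param youngs_E Young's modulus, MPa (default 15000).
#' @param poisson_nu Poisson's ratio, dimensionless in (-1, 0.5)
#'   (default 0.29).
#' @return an object of class `fe_material`.
#' @export
fe_material <- function(youngs_E = 15000, poisson_nu = 0.29) {
  if (!is.numeric(youngs_E) || youngs_E <= 0) {
    stop("Young's modulus must be > 0", call. = FALSE)
  }
  if (poisson_nu <= -1 || poisson_nu >= 0.5) {
    stop("Poisson's ratio must lie in (-1, 0.5)", call. = FALSE)
  }
  structure(list(youngs_E = youngs_E, poisson_nu = poisson_nu),
            class = "fe_material")
}

# Per-element shape-function gradients and volumes.
# Returns grads: list of three (m x 4) matrices (d(lambda_a)/dx_i) and
# volumes; stops naming the first inverted element.
tet_gradients <- function(nodes, elements) {
  m <- nrow(elements)
  p1 <- nodes[elements[, 1], , drop = FALSE]
  e1 <- nodes[elements[, 2], , drop = FALSE] - p1
  e2 <- nodes[elements[, 3], , drop = FALSE] - p1
  e3 <- nodes[elements[, 4], , drop = FALSE] - p1
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
    e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
    e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  if (any(det <= 0)) {
    stop("inverted element (non-positive Jacobian): element ",
         which(det <= 0)[1], call. = FALSE)
  }
  # rows of inverse of J = [e1; e2; e3] (J maps local to global): the
  # gradient of barycentric coordinate a+1 is column a of inv(J^T).
  inv <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1]) / det
  }
  g2 <- inv(e2, e3) # grad lambda_2
  g3 <- inv(e3, e1) # grad lambda_3
  g4 <- inv(e1, e2) # grad lambda_4
  g1 <- -(g2 + g3 + g4)
  gx <- cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1])
  gy <- cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2])
  gz <- cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3])
  list(gx = gx, gy = gy, gz = gz, volume = det / 6)
}

#' Assemble the global stiffness matrix
#'
#' Sparse symmetric stiffness of the whole mesh for an isotropic material,
#' before any constraints: exactly six rigid-body zero-energy modes.
#' Freedom numbering is `3 * (node - 1) + component`.
#'
#' @param mesh a `skull_mesh` (or any list with `nodes` and `elements`).
#' @param material an [fe_material()].
#' @return a `dsCMatrix` sparse symmetric matrix of size `3n x 3n`.
#' @export
assemble_stiffness <- function(mesh, material) {
  nodes <- mesh$nodes
  elements <- mesh$elements
  g <- tet_gradients(nodes, elements)
  e <- material$youngs_E
  nu <- material$poisson_nu
  lam <- e * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- e / (2 * (1 + nu))
  m <- nrow(elements)
  grads <- list(g$gx, g$gy, g$gz)
  v <- g$volume

  nent <- 144 * m
  ii <- integer(nent)
  jj <- integer(nent)
  xx <- numeric(nent)
  pos <- 0L
  for (a in 1:4) {
    for (b in 1:4) {
      # dot product of the two shape gradients, per element
      gdot <- g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b] +
        g$gz[, a] * g$gz[, b]
      for (i in 1:3) {
        for (j in 1:3) {
          k <- v * (lam * grads[[i]][, a] * grads[[j]][, b] +
                      mu * grads[[j]][, a] * grads[[i]][, b] +
                      (if (i == j) mu * gdot else 0))
          ii[pos + seq_len(m)] <- 3L * (elements[, a] - 1L) + i
          jj[pos + seq_len(m)] <- 3L * (elements[, b] - 1L) + j
          xx[pos + seq_len(m)] <- k
          pos <- pos + m
        }
      }
    }
  }
  ndof <- 3L * nrow(nodes)
  k <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  Matrix::forceSymmetric((k + Matrix::t(k)) / 2)
}

#' Finite-element load case
#'
#' Nodal force vectors plus fully fixed node sets for one bite position.
#' Constrained nodes have all three translational freedoms fixed (zero
#' displacement unless `prescribed` is given).
#'
#' @param nodal_forces numeric matrix with columns `node`, `fx`, `fy`,
#'   `fz` (N), or a data.frame with those columns; forces on repeated
#'   nodes are summed.
#' @param fixed_nodes integer vector of constrained node indices
#'   (typically the bite node set plus both basicranium patches).
#' @param label case label, e.g. `"gracile:bite_mid"`.
#' @param prescribed optional numeric matrix (length(fixed_nodes) x 3) of
#'   prescribed displacements, mm; default all zero.
#' @return an object of class `fe_load_case`.
#' @export
fe_load_case <- function(nodal_forces, fixed_nodes, label = "case",
                         prescribed = NULL) {
  nodal_forces <- as.matrix(as.data.frame(nodal_forces)[,
    c("node", "fx", "fy", "fz")])
  fixed_nodes <- sort(unique(as.integer(fixed_nodes)))
  if (length(fixed_nodes) == 0) {
    stop("load case needs a nonempty fixed node set", call. = FALSE)
  }
  overlap <- intersect(nodal_forces[, "node"], fixed_nodes)
  if (length(overlap)) {
    stop("node(s) both loaded and fixed: ",
         paste(utils::head(overlap), collapse = ", "), call. = FALSE)
  }
  if (!is.null(prescribed)) {
    prescribed <- as.matrix(prescribed)
    stopifnot(nrow(prescribed) == length(fixed_nodes), ncol(prescribed) == 3)
  }
  structure(list(nodal_forces = nodal_forces, fixed_nodes = fixed_nodes,
                 label = label, prescribed = prescribed),
            class = "fe_load_case")
}

#' Solve a load case
#'
#' Solves `K u = f` with the fixed freedoms eliminated (direct sparse
#' Cholesky), recovers per-element stress via the constitutive law from
#' element strain, the per-element von Mises scalar from the deviatoric
#' second invariant, and exact reaction forces at the fixed nodes.
#'
#' @param mesh a `skull_mesh` (or box mesh from the test helpers).
#' @param material an [fe_material()].
#' @param load_case an [fe_load_case()].
#' @param stiffness optional pre-assembled stiffness from
#'   [assemble_stiffness()] (reused across load cases on the same mesh).
#' @return an object of class `stress_field`: `displacements` (n x 3, mm),
#'   `element_stress` (m x 6, MPa, Voigt order xx,yy,zz,xy,yz,zx),
#'   `von_mises` (MPa per element), `reactions` (per fixed node, N),
#'   `applied` (total applied force per axis) and the case label.
#' @export
fe_solve <- function(mesh, material, load_case, stiffness = NULL) {
  if (length(load_case$fixed_nodes) < 3) {
    stop("constrained system likely singular: need >= 3 non-collinear ",
         "fixed nodes", call. = FALSE)
  }
  k <- if (is.null(stiffness)) assemble_stiffness(mesh, material) else stiffness
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  fixed_dofs <- as.vector(t(outer(3L * (load_case$fixed_nodes - 1L), 1:3, "+")))
  free <- setdiff(seq_len(ndof), fixed_dofs)

  f <- numeric(ndof)
  nf <- load_case$nodal_forces
  for (c in 1:3) {
    f_c <- tapply(nf[, c + 1], nf[, "node"], sum)
    dof <- 3L * (as.integer(names(f_c)) - 1L) + c
    f[dof] <- f[dof] + as.numeric(f_c)
  }

  u <- numeric(ndof)
  if (!is.null(load_case$prescribed)) {
    u[fixed_dofs] <- as.vector(t(load_case$prescribed))
  }
  kff <- k[free, free, drop = FALSE]
  rhs <- f[free] - as.numeric(k[free, fixed_dofs, drop = FALSE] %*%
                                u[fixed_dofs])
  sol <- tryCatch(
    Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(kff)),
                  rhs, system = "A"),
    error = function(e) {
      stop("constrained system is singular or indefinite (missing ",
           "constraints?): ", conditionMessage(e), call. = FALSE)
    })
  u[free] <- as.numeric(sol)

  # reactions: residual at the fixed freedoms
  r_fixed <- as.numeric(k[fixed_dofs, , drop = FALSE] %*% u) - f[fixed_dofs]
  reactions <- matrix(r_fixed, ncol = 3, byrow = TRUE)
  rownames(reactions) <- load_case$fixed_nodes

  st <- element_stresses(mesh, material, matrix(u, ncol = 3, byrow = TRUE))

  structure(list(displacements = matrix(u, ncol = 3, byrow = TRUE),
                 element_stress = st$stress,
                 von_mises = st$von_mises,
                 reactions = reactions,
                 fixed_nodes = load_case$fixed_nodes,
                 loaded_nodes = sort(unique(as.integer(nf[, "node"]))),
                 applied = colSums(matrix(f, ncol = 3, byrow = TRUE)),
                 label = load_case$label),
            class = "stress_field")
}

# Constant per-element stress from a nodal displacement field (n x 3).
element_stresses <- function(mesh, material, u) {
  g <- tet_gradients(mesh$nodes, mesh$elements)
  el <- mesh$elements
  e <- material$youngs_E
  nu <- material$poisson_nu
  lam <- e * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- e / (2 * (1 + nu))
  comp <- function(gr, c) {
    gr[, 1] * u[el[, 1], c] + gr[, 2] * u[el[, 2], c] +
      gr[, 3] * u[el[, 3], c] + gr[, 4] * u[el[, 4], c]
  }
  exx <- comp(g$gx, 1)
  eyy <- comp(g$gy, 2)
  ezz <- comp(g$gz, 3)
  exy <- (comp(g$gy, 1) + comp(g$gx, 2)) / 2
  eyz <- (comp(g$gz, 2) + comp(g$gy, 3)) / 2
  ezx <- (comp(g$gx, 3) + comp(g$gz, 1)) / 2
  tr <- exx + eyy + ezz
  sxx <- lam * tr + 2 * mu * exx
  syy <- lam * tr + 2 * mu * eyy
  szz <- lam * tr + 2 * mu * ezz
  sxy <- 2 * mu * exy
  syz <- 2 * mu * eyz
  szx <- 2 * mu * ezx
  vm <- sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) +
               3 * (sxy^2 + syz^2 + szx^2))
  list(stress = cbind(xx = sxx, yy = syy, zz = szz,
                      xy = sxy, yz = syz, zx = szx),
       von_mises = vm)
}

#' @export
print.stress_field <- function(x, ...) {
  cat("Stress field '", x$label, "': ", nrow(x$element_stress),
      " elements\n", sep = "")
  cat("  von Mises (MPa): median ", signif(stats::median(x$von_mises), 3),
      ", p95 ", signif(stats::quantile(x$von_mises, 0.95), 3),
      ", max ", signif(max(x$von_mises), 3), "\n", sep = "")
  res <- x$applied + colSums(x$reactions)
  cat("  equilibrium residual (N): ", paste(signif(res, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Regional von Mises summaries
#'
#' Volume-weighted mean, median, 95th percentile and maximum of the
#' per-element von Mises stress for every labelled anatomical region.
#' Elements touching loaded or fixed nodes are excluded from the
#' summaries (they carry constraint-singularity artefacts) and counted
#' separately in the `excluded` column; a region whose elements are all
#' excluded, or which is absent from the mesh, reports `NA`, never zero.
#'
#' @param field a `stress_field` from [fe_solve()].
#' @param mesh the mesh the field was computed on.
#' @return a data.frame with one row per region: `region`, `n`,
#'   `excluded`, `volume`, `mean`, `median`, `p95`, `max`.
#' @export
region_summary <- function(field, mesh) {
  if (is.null(mesh$regions)) stop("mesh carries no region labels",
                                  call. = FALSE)
  vol <- element_volumes(mesh)
  touched <- c(field$fixed_nodes, field$loaded_nodes)
  excl <- matrix(mesh$elements %in% touched, ncol = 4)
  excl <- rowSums(excl) > 0
  regions <- sort(unique(mesh$regions))
  out <- lapply(regions, function(r) {
    in_r <- mesh$regions == r
    ok <- in_r & !excl
    if (!any(ok)) {
      return(data.frame(region = r, n = sum(in_r), excluded = sum(in_r & excl),
                        volume = sum(vol[in_r]), mean = NA_real_,
                        median = NA_real_, p95 = NA_real_, max = NA_real_))
    }
    v <- vol[ok]
    s <- field$von_mises[ok]
    q <- weighted_quantile(s, v, c(0.5, 0.95))
    data.frame(region = r, n = sum(in_r), excluded = sum(in_r & excl),
               volume = sum(vol[in_r]),
               mean = sum(s * v) / sum(v),
               median = q[1], p95 = q[2], max = max(s))
  })
  do.call(rbind, out)
}
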