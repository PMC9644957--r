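mat <- fe_material(15000, 0.29)

test_that("material invariants are enforced", {
  expect_error(fe_material(-1), "Young")
  expect_error(fe_material(1000, 0.5), "Poisson")
  expect_equal(fe_material()$youngs_E, 15000)
  expect_equal(fe_material()$poisson_nu, 0.29)
})

test_that("stiffness has rigid-body modes and scales linearly in E", {
  tet <- list(nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                            c(0, 0, 1)),
              elements = matrix(1:4, 1))
  k <- as.matrix(assemble_stiffness(tet, mat))
  # translation invariance: uniform translation produces no force
  for (c in 1:3) {
    u <- rep(0, 12)
    u[seq(c, 12, by = 3)] <- 1
    expect_lt(max(abs(k %*% u)), 1e-9)
  }
  expect_equal(max(abs(k - t(k))), 0) # symmetric
  # exactly 6 zero-energy modes before constraints
  ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < max(ev) * 1e-10), 6)
  # K(2E) = 2 K(E)
  k2 <- as.matrix(assemble_stiffness(tet, fe_material(30000, 0.29)))
  expect_equal(k2, 2 * k, tolerance = 1e-12)
  # inverted element is an error naming the element
  bad <- tet
  bad$elements <- matrix(c(1, 3, 2, 4), 1)
  expect_error(assemble_stiffness(bad, mat), "element 1")
})

test_that("patch test: linear displacement fields are reproduced exactly", {
  b <- tet_box_mesh(1, 1, 1, 2, 2, 2)
  a <- matrix(c(0.01, 0.002, 0.003,
                0.004, 0.02, 0.001,
                0.002, 0.005, 0.015), 3, 3, byrow = TRUE)
  surf <- surface_nodes(b)
  lc <- fe_load_case(data.frame(node = integer(0), fx = numeric(0),
                                fy = numeric(0), fz = numeric(0)),
                     surf, prescribed = b$nodes[surf, ] %*% t(a))
  f <- fe_solve(b, mat, lc)
  expect_equal(f$displacements, b$nodes %*% t(a), tolerance = 1e-12)
  # constant strain state: stress identical in every element
  spread <- apply(f$element_stress, 2, function(cc) diff(range(cc)))
  expect_lt(max(spread), 1e-10)
})

test_that("prismatic bar under axial load recovers sigma = F/A", {
  bar <- tet_box_mesh(20, 2, 2, 20, 2, 2)
  wall <- which(bar$nodes[, 1] == 0)
  tip <- which(bar$nodes[, 1] == 20)
  f_tot <- 10
  lc <- fe_load_case(data.frame(node = tip, fx = f_tot / length(tip),
                                fy = 0, fz = 0), wall)
  f <- fe_solve(bar, mat, lc)
  cent <- element_centroids(bar)
  mid <- abs(cent[, 1] - 10) < 2
  expect_equal(mean(f$von_mises[mid]), f_tot / 4, tolerance = 1e-3)
})

test_that("pure shear gives von Mises = sqrt(3) tau", {
  b <- tet_box_mesh(1, 1, 1, 2, 2, 2)
  gam <- 1e-3
  surf <- surface_nodes(b)
  u <- cbind(gam * b$nodes[surf, 3], 0, 0) # u_x = gamma z
  lc <- fe_load_case(data.frame(node = integer(0), fx = numeric(0),
                                fy = numeric(0), fz = numeric(0)),
                     surf, prescribed = u)
  f <- fe_solve(b, mat, lc)
  mu <- 15000 / (2 * (1 + 0.29))
  tau <- mu * gam
  expect_equal(unname(f$von_mises), rep(sqrt(3) * tau, nrow(b$elements)),
               tolerance = 1e-9)
})

test_that("cantilever bending stress approaches M c / I under refinement", {
  bend <- function(nx, ny, nz) {
    l <- 40; w <- 4; h <- 4; f_tip <- -20
    b <- tet_box_mesh(l, w, h, nx, ny, nz)
    wall <- which(b$nodes[, 1] == 0)
    tip <- which(b$nodes[, 1] == l)
    lc <- fe_load_case(data.frame(node = tip, fx = 0, fy = 0,
                                  fz = f_tip / length(tip)), wall)
    f <- fe_solve(b, mat, lc)
    cent <- element_centroids(b)
    xs <- 10
    top <- abs(cent[, 1] - xs) < l / nx & cent[, 3] > h - h / nz
    i_sec <- w * h^3 / 12
    exact <- abs(f_tip) * (l - xs) * (h / 2 - h / (2 * nz)) / i_sec
    abs(mean(f$von_mises[top]) - exact) / exact
  }
  err_coarse <- bend(20, 4, 4)
  err_fine <- bend(40, 8, 8)
  expect_lt(err_fine, 0.10)       # within 10% at moderate refinement
  expect_lt(err_fine, err_coarse) # error decreases under refinement
})

test_that("sparse solution matches a dense direct solve", {
  b <- tet_box_mesh(4, 2, 2, 4, 2, 2) # 135 freedoms
  wall <- which(b$nodes[, 1] == 0)
  tip <- which(b$nodes[, 1] == 4)
  lc <- fe_load_case(data.frame(node = tip, fx = 0.3, fy = -0.1, fz = 1),
                     wall)
  k <- assemble_stiffness(b, mat)
  f <- fe_solve(b, mat, lc, stiffness = k)
  ndof <- 3 * nrow(b$nodes)
  fixd <- as.vector(t(outer(3 * (wall - 1), 1:3, "+")))
  free <- setdiff(seq_len(ndof), fixd)
  fvec <- numeric(ndof)
  fvec[3 * (tip - 1) + 1] <- 0.3
  fvec[3 * (tip - 1) + 2] <- -0.1
  fvec[3 * (tip - 1) + 3] <- 1
  u_dense <- solve(as.matrix(k[free, free]), fvec[free])
  u_sparse <- as.vector(t(f$displacements))[free]
  expect_lt(max(abs(u_dense - u_sparse)) / max(abs(u_dense)), 1e-8)
})

test_that("global equilibrium holds on a skull load case", {
  m <- gracile_mesh_coarse()
  mus <- specimen_muscles("M1399")
  f <- fe_solve(m, mat, bite_load_case(m, mus, "bite_mid"))
  res <- f$applied + colSums(f$reactions)
  expect_lt(max(abs(res)), 1e-6 * sum(abs(f$applied)))
})

test_that("bilateral loading of a bilateral mesh gives a mirror-symmetric field", {
  m <- gracile_mesh_coarse()
  mus <- specimen_muscles("M1399")
  f <- fe_solve(m, mat, bite_load_case(m, mus, "bite_posterior"))
  cent <- element_centroids(m)
  key <- paste(round(cent[, 1], 6), round(abs(cent[, 2]), 6),
               round(cent[, 3], 6))
  left <- which(cent[, 2] < 0)
  right <- which(cent[, 2] > 0)
  mr <- match(key[left], key[right])
  expect_false(anyNA(mr))
  rel <- abs(f$von_mises[left] - f$von_mises[right[mr]]) /
    pmax(f$von_mises[right[mr]], 1e-9)
  expect_lt(max(rel), 0.01)
})

test_that("missing constraints raise a singularity error", {
  b <- tet_box_mesh(4, 2, 2, 2, 1, 1)
  expect_error(fe_solve(b, mat,
                        fe_load_case(data.frame(node = 1, fx = 1, fy = 0,
                                                fz = 0), c(2, 3))),
               "singular|fixed nodes")
  expect_error(fe_load_case(data.frame(node = 1, fx = 1, fy = 0, fz = 0),
                            integer(0)), "nonempty")
  expect_error(fe_load_case(data.frame(node = 2, fx = 1, fy = 0, fz = 0),
                            c(2, 3, 4)), "both loaded and fixed")
})

test_that("regional summaries are volume-weighted, linear, and flag exclusions", {
  thirds <- function(cent) {
    c("a", "b", "c")[pmin(3, 1 + floor(cent[, 1] / (20 / 3 + 1e-9)))]
  }
  bar <- tet_box_mesh(20, 4, 4, 12, 3, 3, regions = thirds)
  surf <- surface_nodes(bar)
  # uniform uniaxial-strain state imposed through boundary displacements:
  # exactly constant stress, so every region must report the same mean
  eps <- 1e-3
  u <- cbind(eps * bar$nodes[surf, 1], 0, 0)
  lc <- fe_load_case(data.frame(node = integer(0), fx = numeric(0),
                                fy = numeric(0), fz = numeric(0)),
                     surf, prescribed = u)
  f <- fe_solve(bar, mat, lc)
  rs <- region_summary(f, bar)
  expect_true(all(abs(rs$mean - rs$mean[1]) / rs$mean[1] < 1e-9))
  expect_equal(rs$mean[rs$region == "b"], f$von_mises[1],
               tolerance = 1e-9)
  # elements touching fixed nodes are excluded and counted, per region
  expect_true(all(rs$excluded > 0))
  expect_true(all(rs$n > rs$excluded)) # interior elements remain
  # doubling the imposed deformation doubles every statistic
  lc2 <- fe_load_case(data.frame(node = integer(0), fx = numeric(0),
                                 fy = numeric(0), fz = numeric(0)),
                      surf, prescribed = 2 * u)
  rs2 <- region_summary(fe_solve(bar, mat, lc2), bar)
  for (col in c("mean", "median", "p95", "max")) {
    expect_equal(rs2[[col]], 2 * rs[[col]], tolerance = 1e-9)
  }
  # a region whose elements are all excluded reports NA, never zero
  bar$regions[1] <- "d" # element 1 touches the boundary
  rs3 <- region_summary(fe_solve(bar, mat, lc), bar)
  expect_true(is.na(rs3$mean[rs3$region == "d"]))
  expect_equal(rs3$n[rs3$region == "d"], 1)
  # missing region labels are an error
  expect_error(region_summary(f, tet_box_mesh(1, 1, 1, 1, 1, 1)),
               "region labels")
})
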