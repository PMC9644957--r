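test_that("morphotype parameter invariants are enforced with named errors", {
  base <- coarse_gracile()
  expect_s3_class(base, "morphotype_params")

  bad <- base; bad$rostrum_base_height <- -1
  expect_error(validate_morphotype_params(bad), "rostrum_base_height")
  bad <- base; bad$rostrum_fraction <- 1.2
  expect_error(validate_morphotype_params(bad), "rostrum_fraction")
  bad <- base; bad$orbit_diameter <- base$cranium_height + 1
  expect_error(validate_morphotype_params(bad), "orbit_diameter")
  bad <- base; bad$rostrum_base_width <- base$cranium_width + 1
  expect_error(validate_morphotype_params(bad), "rostrum_base_width")
  # too-coarse mesh cites the three-elements-thick invariant
  expect_error(morphotype_preset("gracile", target_edge_length = 12),
               "three elements thick")
})

test_that("mesh generation is deterministic for fixed parameters", {
  m1 <- suppressWarnings(build_skull_mesh(coarse_gracile()))
  m2 <- suppressWarnings(build_skull_mesh(coarse_gracile()))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)
  expect_identical(m1$node_sets, m2$node_sets)
})

test_that("generated meshes satisfy the structural invariants", {
  for (m in list(gracile_mesh_coarse(), robust_mesh_coarse())) {
    expect_silent(validate_skull_mesh(m))
    expect_true(all(element_volumes(m) > 0))
    # watertight: closed boundary, each boundary edge shared by 2 faces
    bf <- mesh_boundary_faces(m)
    ed <- rbind(bf[, c(1, 2)], bf[, c(2, 3)], bf[, c(1, 3)])
    ekey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    expect_true(all(table(ekey) == 2))
  }
})

test_that("node sets are bilaterally paired with equal cardinality", {
  m <- gracile_mesh_coarse()
  lefts <- grep("_left$", names(m$node_sets), value = TRUE)
  expect_length(lefts, 12) # 7 origins + 4 insertions + basicranium
  mir <- craniofea:::node_mirror_map(m$nodes)
  for (l in lefts) {
    r <- sub("_left$", "_right", l)
    expect_true(r %in% names(m$node_sets))
    expect_equal(length(m$node_sets[[l]]), length(m$node_sets[[r]]))
    expect_setequal(mir[m$node_sets[[r]]], m$node_sets[[l]])
  }
  for (b in c("bite_anterior", "bite_mid", "bite_posterior")) {
    expect_length(m$node_sets[[b]], 20)
  }
})

test_that("morphotype presets encode the robust/gracile contrast", {
  mr <- robust_mesh_coarse()
  mg <- gracile_mesh_coarse()
  # robust rostrum region anteroposteriorly longer than posterior cranium
  cr <- element_centroids(mr)
  rost <- mr$regions %in% c("rostrum", "nasal")
  span <- function(sel) diff(range(cr[sel, 1]))
  expect_gt(span(rost), span(!rost))
  # gracile rostrum-base-height / cranium-height ratio smaller than robust
  ratio <- function(m) {
    nd <- m$nodes
    lc <- m$extra$cranium_end
    base <- abs(nd[, 1] - lc) < m$params$target_edge_length
    crn <- nd[, 1] < 0.3 * lc
    diff(range(nd[base, 3])) / diff(range(nd[crn, 3]))
  }
  expect_lt(ratio(mg), ratio(mr))
})

test_that("mesh volume matches the analytic solid volume and converges", {
  errs <- vapply(c(7, 5, 3.5), function(e) {
    p <- morphotype_preset("gracile", target_edge_length = e)
    m <- suppressWarnings(build_skull_mesh(p, include_orbit = FALSE))
    abs(mesh_volume(m) - analytic_skull_volume(p)) / analytic_skull_volume(p)
  }, numeric(1))
  expect_lt(errs[1], 0.02)           # within 2% even at coarse granularity
  expect_true(all(diff(errs) < 0))   # monotone convergence under refinement
})

test_that("element aspect ratios are reported, not silently accepted", {
  ar <- element_aspect_ratios(gracile_mesh_coarse())
  expect_true(all(ar >= 1))
  # an artificially tight bound must trigger the report
  expect_warning(build_skull_mesh(coarse_gracile(), aspect_bound = 2),
                 "aspect-ratio bound")
})

test_that("rostrum truncation removes the anterior elements only", {
  m <- gracile_mesh_coarse()
  expect_identical(truncate_rostrum(m, 1), m) # identity

  # (at this coarse granularity the robust preserved-length ratio would
  # leave too short a tooth row; the default-granularity case is covered
  # by the truncation-sensitivity check)
  keep <- 0.6
  mt <- truncate_rostrum(m, keep)
  x_cut <- keep * m$params$total_skull_length
  cent_full <- element_centroids(m)
  expect_equal(nrow(mt$elements), sum(cent_full[, 1] < x_cut))
  expect_lt(nrow(mt$elements), nrow(m$elements))
  expect_silent(validate_skull_mesh(mt))

  # posterior node sets unchanged (same physical nodes)
  for (s in c("origin_mAMIps_right", "basicranium_left",
              "insertion_coronoid_right")) {
    expect_equal(mt$nodes[mt$node_sets[[s]], ], m$nodes[m$node_sets[[s]], ])
  }
  # anterior bite relocated to the new anterior-most tooth position
  expect_gt(max(mt$nodes[mt$node_sets$bite_anterior, 1]),
            max(mt$nodes[, 1]) - 4 * m$params$target_edge_length)

  # a cut through the cranium would destroy attachment/constraint sets
  expect_error(truncate_rostrum(m, 0.2), "muscle attachment or constraint")
})

test_that("degenerate inputs fail meshing with an explanatory error", {
  p <- coarse_gracile()
  p$tip_fraction <- 0.5 # fine
  expect_s3_class(suppressWarnings(build_skull_mesh(p)), "skull_mesh")
  expect_error(morphotype_params(label = "x", total_skull_length = 100,
                                 rostrum_fraction = 0.6,
                                 rostrum_base_height = 10,
                                 rostrum_base_width = 8,
                                 cranium_height = 20, cranium_width = 16,
                                 orbit_diameter = 10,
                                 target_edge_length = 4),
               "three elements thick")
})
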