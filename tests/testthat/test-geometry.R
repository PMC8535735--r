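test_that("geometry parameters enforce their invariants", {
  expect_s3_class(pfm_geometry(), "pfm_geometry")
  expect_error(pfm_geometry(length = -1), "positive")
  expect_error(pfm_geometry(hiatus_semiaxes = c(40, 15)), "fit strictly inside")
  expect_error(pfm_geometry(hiatus_center = c(12, 0)), "fit strictly inside")
  expect_error(pfm_geometry(sheet_thickness = 45), "smaller than the total height")
})

test_that("surrogate solid spans the published bounding box and is deterministic", {
  solid <- build_pfm_surrogate(default_geometry())
  mesh <- tetrahedralize(solid, 3)
  bb <- apply(mesh$nodes, 2, range)
  expect_equal(bb[, 1], c(-35, 35), tolerance = 1e-9)
  expect_equal(bb[, 2], c(-30, 30), tolerance = 1e-9)
  # lowest material line reaches -height within meshing tolerance
  expect_lt(abs(bb[1, 3] - (-40)), 0.5)
  expect_equal(bb[2, 3], 0, tolerance = 1e-9)

  # identical parameters give byte-identical descriptions and meshes
  solid2 <- build_pfm_surrogate(default_geometry())
  expect_identical(serialize(solid, NULL), serialize(solid2, NULL))
  expect_identical(serialize(mesh, NULL),
                   serialize(tetrahedralize(solid2, 3), NULL))
})

test_that("undeformed hiatus admits no sphere as large as the smallest head", {
  solid <- build_pfm_surrogate(default_geometry())
  # brute-force clearance oracle: a sphere descending along the hiatus axis
  # passes iff every material point keeps a horizontal distance >= R from the
  # axis; sample the solid densely and take the minimum.
  set.seed(42)
  bb <- solid$bbox
  pts <- cbind(runif(2e5, bb[1, 1], bb[2, 1]),
               runif(2e5, bb[1, 2], bb[2, 2]),
               runif(2e5, bb[1, 3], bb[2, 3]))
  inside <- solid_contains(solid, pts)
  ctr <- solid$params$hiatus_center
  r_axis <- sqrt((pts[inside, 1] - ctr[1])^2 + (pts[inside, 2] - ctr[2])^2)
  max_passing_diameter <- 2 * min(r_axis)
  expect_lt(max_passing_diameter, 80)
  # and the opening is a real opening: some sphere does pass
  expect_gt(max_passing_diameter, 10)
})

test_that("tetrahedralization produces valid, convergent meshes", {
  solid <- build_pfm_surrogate(default_geometry())
  m3 <- tetrahedralize(solid, 3)
  expect_true(all(pfmsim:::tet_signed_volumes(m3$nodes, m3$tets) > 0))
  expect_true(max(m3$tets) <= nrow(m3$nodes))
  expect_lt(abs(m3$median_edge - 3) / 3, 0.4)

  m4 <- tetrahedralize(solid, 4)
  expect_gt(nrow(m3$tets), nrow(m4$tets))  # refinement monotonicity

  # Monte-Carlo volume oracle at the 2 mm production resolution
  m2 <- tetrahedralize(solid, 2)
  vol_mc <- pfmsim:::solid_volume_mc(solid, n = 1e6, seed = 7)
  expect_lt(abs(m2$volume - vol_mc) / vol_mc, 0.05)
  # volume converged between 3 mm and 2 mm
  expect_lt(abs(m3$volume - m2$volume) / m2$volume, 0.05)

  expect_error(tetrahedralize(solid, 0.5), "target_edge")
  expect_error(tetrahedralize(solid, 6), "target_edge")
})

test_that("fixed-rim selection obeys band semantics", {
  geo <- default_geometry()
  mesh <- tetrahedralize(build_pfm_surrogate(geo), 5)
  m1 <- select_fixed_rim(mesh, geo, band = 1, edges = "xmin")
  expect_gt(length(m1$node_sets$fixed_rim), 0)
  # every fixed node lies within the band of the footprint boundary
  expect_true(all(m1$nodes[m1$node_sets$fixed_rim, 1] <= -geo$length / 2 + 1))
  # no fixed node on the hiatus rim
  ctr <- geo$hiatus_center
  m_h <- sqrt(((m1$nodes[m1$node_sets$fixed_rim, 1] - ctr[1]) / 25)^2 +
              ((m1$nodes[m1$node_sets$fixed_rim, 2] - ctr[2]) / 15)^2)
  expect_true(all(m_h > 1))
  # widening the band never shrinks the selection
  m2 <- select_fixed_rim(mesh, geo, band = 3, edges = "xmin")
  expect_true(all(m1$node_sets$fixed_rim %in% m2$node_sets$fixed_rim))
  # an empty selection errors: footprint of a larger nominal geometry
  big <- pfm_geometry(length = 100, width = 80)
  expect_error(select_fixed_rim(mesh, big, band = 0, edges = "xmin"),
               "selection error")
  expect_error(select_fixed_rim(mesh, geo, band = -1), "band")
  expect_error(select_fixed_rim(mesh, geo, edges = "north"), "unknown edge")
})

test_that("sphere placement honors the clearance gap and derived mass", {
  mesh <- coarse_mesh(5)
  sph <- place_sphere(mesh, 90, gap = 23)
  d <- sqrt(rowSums(sweep(mesh$nodes, 2, sph$center)^2))
  expect_equal(min(d) - sph$radius, 23, tolerance = 1e-9)
  expect_equal(sph$center[1:2], mesh$params$hiatus_center, tolerance = 1e-12)
  expect_equal(sph$vertical_velocity, 0)

  sph0 <- place_sphere(mesh, 90, gap = 0)
  d0 <- sqrt(rowSums(sweep(mesh$nodes, 2, sph0$center)^2))
  expect_equal(min(d0) - sph0$radius, 0, tolerance = 1e-9)

  expect_equal(place_sphere(mesh, 90, density = 7.86e-9)$mass, 3.0002e-3,
               tolerance = 1e-4)
  expect_equal(place_sphere(mesh, 80, density = 7.86e-9)$mass, 2.107e-3,
               tolerance = 1e-3)
  expect_error(place_sphere(mesh, -1), "diameter")
  expect_error(place_sphere(mesh, 90, gap = -2), "gap")
})

test_that("initial placement produces zero contact force for all diameters", {
  mesh <- coarse_mesh(5)
  for (D in c(80, 90, 100)) {
    sph <- place_sphere(mesh, D)
    con <- sphere_contact(mesh$nodes, matrix(0, nrow(mesh$nodes), 3), sph,
                          contact_params(penalty_stiffness = 10))
    expect_equal(sum(abs(con$forces)), 0)
  }
})
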