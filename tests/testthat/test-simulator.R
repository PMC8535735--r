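test_that("configuration invariants are enforced", {
  expect_error(simulation_config(duration = -1), "duration")
  expect_error(simulation_config(snapshot_interval = 0.04), "divide")
  expect_error(simulation_config(cfl_factor = 1.5), "cfl_factor")
  cfg <- simulation_config()
  expect_equal(cfg$duration, 0.15)
  expect_equal(cfg$snapshot_interval, 0.03)
  expect_equal(cfg$gravity, 9810)
  expect_equal(cfg$initial_gap, 23)
  expect_equal(cfg$contact$friction_coefficient, 0.03)
})

test_that("sphere in free fall matches the closed-form drop within 0.5%", {
  sph <- structure(list(diameter = 90, radius = 45, density = 7.86e-9,
                        mass = sphere_mass(90, 7.86e-9),
                        center = c(0, 0, 60), vertical_velocity = 0),
                   class = "rigid_sphere")
  run <- run_simulation(NULL, NULL, sph, simulation_config(contact_enabled = FALSE))
  drop <- sph$center[3] - run$final_state$sphere_z
  expect_lt(abs(drop / (0.5 * 9810 * 0.15^2) - 1), 0.005)
  expect_equal(0.5 * 9810 * 0.15^2, 110.3625)
})

test_that("force-free motion is uniform and straight", {
  sph <- structure(list(diameter = 10, radius = 5, density = 1e-9,
                        mass = sphere_mass(10, 1e-9),
                        center = c(0, 0, 100), vertical_velocity = -40),
                   class = "rigid_sphere")
  cfg <- simulation_config(duration = 0.1, snapshot_interval = 0.05,
                           gravity = 0, contact_enabled = FALSE)
  st <- initialize_state(NULL, NULL, sph, cfg)
  for (i in 1:50) step_state(st, 0.002)
  expect_equal(st$sphere_z, 100 - 40 * 0.1, tolerance = 1e-9)
  expect_equal(st$sphere_v, -40, tolerance = 1e-12)
})

test_that("initialization rejects penetration and starts with a clean ledger", {
  mesh <- coarse_mesh(5)
  cfg <- simulation_config(contact = contact_params(penalty_stiffness = 12))
  st <- initialize_state(mesh, material_params(), place_sphere(mesh, 90), cfg)
  led <- pfmsim:::ledger_now(st)
  expect_equal(led$work, 0)
  expect_equal(led$kinetic, 0)
  expect_equal(led$strain, 0)
  expect_equal(led$friction, 0)
  # touching (gap 0) is admissible, zero contact force
  st0 <- initialize_state(mesh, material_params(),
                          place_sphere(mesh, 90, gap = 0), cfg)
  expect_equal(st0$max_penetration, 0)
  # an already-penetrating sphere is rejected
  sph_bad <- place_sphere(mesh, 90, gap = 0)
  sph_bad$center[3] <- sph_bad$center[3] - 5
  expect_error(initialize_state(mesh, material_params(), sph_bad, cfg),
               "setup error")
})

test_that("a short descent keeps constraints, snapshots and energy honest", {
  run <- short_run()
  # snapshot schedule: floor(duration / interval) + 1 states
  expect_length(run$snapshots, 3)
  expect_equal(vapply(run$snapshots, `[[`, 0, "time"), c(0, 0.03, 0.06),
               tolerance = 1e-9)
  # fixed-rim nodes never move
  fixed <- run$mesh$node_sets$fixed_rim
  for (sn in run$snapshots)
    expect_equal(max(abs(sn$u[fixed, ])), 0)
  # displacement at t = 0 is identically zero
  expect_equal(max(abs(run$snapshots[[1]]$u)), 0)
  # energy ledger: residual within 5% of peak work at every snapshot
  work_peak <- max(vapply(run$snapshots, function(s) s$ledger$work, 0))
  for (sn in run$snapshots) {
    led <- sn$ledger
    resid <- led$work - (led$kinetic + led$strain + led$contact_spring +
                         led$friction + led$damping)
    expect_lt(abs(resid), 0.05 * max(work_peak, 1e-9))
  }
  # dissipation terms never decrease along the monitors
  expect_true(all(diff(run$monitors$friction) > -1e-9))
  expect_true(all(diff(run$monitors$damping) > -1e-9))
})

test_that("reruns with identical inputs are bit-identical", {
  mesh <- coarse_mesh(5)
  cfg <- simulation_config(duration = 0.03, snapshot_interval = 0.03,
                           contact = contact_params(penalty_stiffness = 12))
  r1 <- run_simulation(mesh, material_params(), place_sphere(mesh, 90), cfg)
  r2 <- run_simulation(mesh, material_params(), place_sphere(mesh, 90), cfg)
  expect_identical(serialize(r1$monitors, NULL), serialize(r2$monitors, NULL))
})

test_that("divergence raises a structured instability error", {
  mesh <- coarse_mesh(5)
  # a wildly excessive time step must blow up and be reported as such
  cfg <- simulation_config(contact = contact_params(penalty_stiffness = 12))
  st <- initialize_state(mesh, material_params(), place_sphere(mesh, 90), cfg)
  st$v <- matrix(1e7, nrow(mesh$nodes), 3)  # absurd state
  st$v[mesh$node_sets$fixed_rim, ] <- 0
  expect_error(
    for (i in 1:200) {
      step_state(st, 10 * st$dt0)
      if (!all(is.finite(st$u)) || max(abs(st$u)) > 10 * 70)
        stop(errorCondition("instability detected: displacements diverged",
                            class = c("pfm_instability_error", "error",
                                      "condition")))
    },
    class = "pfm_instability_error")
})

test_that("run manifest determines reruns and flags standard diameters", {
  run <- short_run()
  man <- run_manifest(run)
  expect_s3_class(man, "pfm_manifest")
  expect_true(man$standard_diameter)
  expect_equal(man$mesh$n_tets, nrow(run$mesh$tets))
  man2 <- run_manifest(short_run())
  expect_identical(man$config_hash, man2$config_hash)
})
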