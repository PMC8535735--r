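test_that("material constructor validates Table-style constants", {
  m <- material_params()
  expect_equal(m$young_modulus, 0.2)
  expect_equal(m$poisson_ratio, 0.4)
  expect_equal(m$density, 1.12e-9)
  expect_error(material_params(poisson_ratio = 0.5), "invalid material")
  expect_error(material_params(young_modulus = 0), "invalid material")
  lc <- lame_constants(m)
  expect_equal(lc$lambda, 0.2857, tolerance = 1e-3)
  expect_equal(lc$mu, 0.07143, tolerance = 1e-3)
})

test_that("sphere mass follows the closed form", {
  expect_equal(sphere_mass(90, 7.86e-9) * 1000, 3.0002, tolerance = 1e-4)
  expect_equal(sphere_mass(80, 7.86e-9), 2.107e-3, tolerance = 1e-4)
  expect_equal(sphere_mass(50, 0), 0)
})

test_that("Green strain obeys closed forms and objectivity", {
  expect_equal(green_strain(diag(3)), matrix(0, 3, 3))
  lam <- 1.3
  E <- green_strain(diag(c(lam, 1, 1)))
  expect_equal(E[1, 1], (lam^2 - 1) / 2)
  expect_equal(sum(abs(E)) - abs(E[1, 1]), 0)
  R <- random_rotation(3)
  expect_equal(green_strain(R), matrix(0, 3, 3), tolerance = 1e-12)
  expect_error(green_strain(diag(c(-1, 1, 1))), "inverted")
})

test_that("Saint Venant-Kirchhoff stress matches Hooke in the small-strain limit", {
  mat <- material_params()
  expect_equal(svk_stress(matrix(0, 3, 3), mat), matrix(0, 3, 3))
  # uniaxial stress with lateral contraction solved to zero lateral stress
  slope <- pfmsim:::uniaxial_secant_modulus(mat, 1e-3)
  expect_lt(abs(slope / mat$young_modulus - 1), 0.005)
})

test_that("Cauchy push-forward preserves invariants under rotation", {
  mat <- material_params()
  set.seed(11)
  F <- diag(3) + 0.1 * matrix(rnorm(9), 3, 3)
  if (det(F) <= 0) F <- diag(3) + 0.01 * matrix(rnorm(9), 3, 3)
  S <- svk_stress(green_strain(F), mat)
  sig <- cauchy_from_pk2(F, S)
  expect_equal(sig, t(sig), tolerance = 1e-12)
  expect_equal(cauchy_from_pk2(diag(3), S), S)
  R <- random_rotation(5)
  sig_rot <- cauchy_from_pk2(R %*% F, S)
  expect_equal(von_mises(sig_rot), von_mises(R %*% sig %*% t(R)),
               tolerance = 1e-10)
  # von Mises from components equals the eigenvalue-based oracle
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  vm_oracle <- sqrt(0.5 * ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                           (ev[3] - ev[1])^2))
  expect_equal(von_mises(sig), vm_oracle, tolerance = 1e-12)
  expect_error(cauchy_from_pk2(diag(c(-1, 1, 1)), S), "inverted")
})

test_that("element internal forces are energy-consistent and objective", {
  mat <- material_params()
  X <- unit_tet()
  expect_equal(element_internal_forces(X, matrix(0, 4, 3), mat)$forces,
               matrix(0, 4, 3))

  # rigid rotation leaves no force (objectivity of the Green measure)
  R <- random_rotation(7)
  u_rot <- X %*% t(R) - X
  f_rot <- element_internal_forces(X, u_rot, mat)$forces
  expect_lt(max(abs(f_rot)) / mat$young_modulus, 1e-8)

  # forces sum to zero and match central finite differences of the energy
  set.seed(4)
  u <- matrix(rnorm(12, 0, 0.1), 4, 3)
  out <- element_internal_forces(X, u, mat)
  expect_equal(colSums(out$forces), c(0, 0, 0), tolerance = 1e-12)
  h <- 1e-6
  for (nd in c(1L, 3L)) for (cc in c(1L, 2L, 3L)) {
    up <- u; up[nd, cc] <- up[nd, cc] + h
    um <- u; um[nd, cc] <- um[nd, cc] - h
    dE <- (element_internal_forces(X, up, mat)$energy -
           element_internal_forces(X, um, mat)$energy) / (2 * h)
    expect_equal(out$forces[nd, cc], -dE, tolerance = 1e-4 * max(abs(out$forces)))
  }
})

test_that("vectorized kernel agrees with the per-element reference", {
  mat <- material_params()
  X <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0.2, 0.1, 1.5))
  set.seed(9)
  u <- matrix(rnorm(12, 0, 0.2), 4, 3)
  ref <- element_internal_forces(X, u, mat)
  ker <- pfmsim:::precompute_kernel(single_tet_mesh(X), mat)
  out <- pfmsim:::kernel_internal_forces(ker, u, fields = TRUE)
  expect_equal(out$forces, unname(ref$forces), tolerance = 1e-12)
  sig6 <- pfmsim:::kernel_cauchy(out$F9, out$pk2)
  expect_equal(as.numeric(sig6),
               c(ref$cauchy_stress[1, 1], ref$cauchy_stress[2, 2],
                 ref$cauchy_stress[3, 3], ref$cauchy_stress[1, 2],
                 ref$cauchy_stress[1, 3], ref$cauchy_stress[2, 3]),
               tolerance = 1e-12)
  expect_equal(pfmsim:::kernel_strain_energy(ker, out$green), ref$energy,
               tolerance = 1e-12)
})

test_that("lumped masses conserve total mass and scale linearly", {
  mesh <- coarse_mesh(5)
  mat <- material_params()
  m <- lumped_nodal_masses(mesh, mat)
  expect_true(all(m > 0))
  expect_equal(sum(m), mat$density * mesh$volume, tolerance = 1e-12)
  mat2 <- material_params(density = 2 * mat$density)
  expect_equal(lumped_nodal_masses(mesh, mat2), 2 * m, tolerance = 1e-12)
  # single unit-volume tet splits evenly
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 6))  # V = 1
  mm <- lumped_nodal_masses(single_tet_mesh(X), material_params(density = 1.12e-9))
  expect_equal(mm, rep(2.8e-10, 4), tolerance = 1e-15)
})

test_that("wave speed and stable time step follow the closed forms", {
  mat <- material_params()
  expect_equal(dilatational_wave_speed(mat), 1.956e4, tolerance = 1e-3)
  mesh <- single_tet_mesh()
  mesh$characteristic_edge <- 2
  expect_equal(stable_dt(mesh, mat, 1), 2 / dilatational_wave_speed(mat))
  expect_equal(stable_dt(mesh, mat, 1), 1.02e-4, tolerance = 1e-2)
  mesh$characteristic_edge <- 1
  expect_equal(stable_dt(mesh, mat, 1), 0.5 * 1.02e-4, tolerance = 1e-2)
  expect_error(stable_dt(mesh, mat, 0), "cfl_factor")
})
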