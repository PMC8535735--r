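#' Isotropic material parameters
#'
#' Units follow the consistent mm--ton--s--MPa system: Young's modulus in MPa,
#' density in ton/mm^3 (so muscle is 1.12e-9).  The linear-elastic constants
#' are applied in the Green--Lagrange strain measure (Saint Venant--Kirchhoff
#' law), which keeps the two printed constants but stays objective at the
#' large rotations and stretches of labor.
#'
#' @param young_modulus E, MPa.
#' @param poisson_ratio nu, dimensionless, in (0, 0.5).
#' @param density rho, ton/mm^3.
#' @return An object of class `material_params`.
#' @export
material_params <- function(young_modulus = 0.2, poisson_ratio = 0.4,
                            density = 1.12e-9) {
  if (!is.finite(young_modulus) || young_modulus <= 0)
    stop("invalid material: young_modulus must be > 0", call. = FALSE)
  if (!is.finite(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("invalid material: poisson_ratio must lie strictly in (0, 0.5)", call. = FALSE)
  if (!is.finite(density) || density <= 0)
    stop("invalid material: density must be > 0", call. = FALSE)
  structure(list(young_modulus = young_modulus, poisson_ratio = poisson_ratio,
                 density = density),
            class = "material_params")
}

#' Lame constants of a material
#'
#' @param material A [material_params()] object.
#' @return Named list with `lambda` and `mu`, MPa.
#' @export
lame_constants <- function(material) {
  E <- material$young_modulus; nu <- material$poisson_ratio
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}

#' Mass of the rigid head sphere
#'
#' @param diameter Sphere diameter, mm.
#' @param density Density, ton/mm^3.
#' @return Mass in ton, `(pi/6) * D^3 * rho`.
#' @export
sphere_mass <- function(diameter, density) {
  if (any(diameter < 0) || any(density < 0))
    stop("diameter and density must be non-negative", call. = FALSE)
  pi / 6 * diameter^3 * density
}

#' Green--Lagrange strain from a deformation gradient
#'
#' @param F 3 x 3 deformation gradient with `det(F) > 0`.
#' @return Symmetric 3 x 3 strain `0.5 * (t(F) %*% F - I)`.
#' @export
green_strain <- function(F) {
  if (det(F) <= 0) stop("inverted element: det(F) must be > 0", call. = FALSE)
  0.5 * (crossprod(F) - diag(3))
}

#' Second Piola--Kirchhoff stress of the Saint Venant--Kirchhoff law
#'
#' @param E_gl Symmetric 3 x 3 Green--Lagrange strain.
#' @param material A [material_params()] object.
#' @return Symmetric 3 x 3 stress `lambda * tr(E) * I + 2 * mu * E`, MPa.
#' @export
svk_stress <- function(E_gl, material) {
  lc <- lame_constants(material)
  lc$lambda * sum(diag(E_gl)) * diag(3) + 2 * lc$mu * E_gl
}

#' Cauchy stress from deformation gradient and second Piola--Kirchhoff stress
#'
#' @param F 3 x 3 deformation gradient.
#' @param S Symmetric 3 x 3 second Piola--Kirchhoff stress, MPa.
#' @return Symmetric Cauchy stress `F S t(F) / det(F)`, MPa.
#' @export
cauchy_from_pk2 <- function(F, S) {
  J <- det(F)
  if (J <= 0) stop("inverted element: det(F) must be > 0", call. = FALSE)
  sig <- F %*% S %*% t(F) / J
  (sig + t(sig)) / 2
}

#' Internal forces and state of a single linear tetrahedron
#'
#' Total-Lagrangian Saint Venant--Kirchhoff kernel: the four nodal forces are
#' the negative gradient of the element strain energy with respect to the
#' current nodal positions; they sum to zero.
#'
#' @param X 4 x 3 reference nodal coordinates, mm (positive volume ordering).
#' @param u 4 x 3 nodal displacements, mm.
#' @param material A [material_params()] object.
#' @return List with `forces` (4 x 3, N), `F`, `green_strain`, `pk2_stress`,
#'   `cauchy_stress` (3 x 3 each), `energy` (mJ) and `volume` (mm^3).
#' @export
element_internal_forces <- function(X, u, material) {
  Dm <- t(X[2:4, , drop = FALSE] - matrix(X[1, ], 3, 3, byrow = TRUE))
  V0 <- det(Dm) / 6
  if (V0 <= 0) stop("element has non-positive reference volume", call. = FALSE)
  Bm <- solve(Dm)
  x <- X + u
  Ds <- t(x[2:4, , drop = FALSE] - matrix(x[1, ], 3, 3, byrow = TRUE))
  F <- Ds %*% Bm
  if (det(F) <= 0)
    stop("inverted current configuration (det F <= 0)", call. = FALSE)
  E_gl <- green_strain(F)
  S <- svk_stress(E_gl, material)
  P <- F %*% S
  H <- -V0 * P %*% t(Bm)            # columns: forces on nodes 2..4
  forces <- rbind(-rowSums(H), t(H))
  lc <- lame_constants(material)
  trE <- sum(diag(E_gl))
  energy <- V0 * (lc$lambda / 2 * trE^2 + lc$mu * sum(E_gl^2))
  list(forces = forces, F = F, green_strain = E_gl, pk2_stress = S,
       cauchy_stress = cauchy_from_pk2(F, S), energy = energy, volume = V0)
}

#' Lumped nodal masses of a mesh
#'
#' Each tet's mass `rho * V` is split equally among its four nodes.
#'
#' @param mesh A `pfm_mesh`.
#' @param material A [material_params()] object.
#' @return Numeric vector of nodal masses, ton.
#' @export
lumped_nodal_masses <- function(mesh, material) {
  vol <- tet_signed_volumes(mesh$nodes, mesh$tets)
  if (any(vol <= 0)) stop("mesh error: non-positive element volume", call. = FALSE)
  em <- material$density * vol / 4
  m <- rowsum(rep(em, 4L), group = as.vector(mesh$tets), reorder = TRUE)
  out <- numeric(nrow(mesh$nodes))
  out[as.integer(rownames(m))] <- m
  if (any(out <= 0)) stop("mesh error: node with zero lumped mass", call. = FALSE)
  out
}

#' Dilatational wave speed of a material
#'
#' @param material A [material_params()] object.
#' @return `sqrt(E (1 - nu) / ((1 + nu) (1 - 2 nu) rho))`, mm/s.
#' @export
dilatational_wave_speed <- function(material) {
  E <- material$young_modulus; nu <- material$poisson_ratio
  sqrt(E * (1 - nu) / ((1 + nu) * (1 - 2 * nu) * material$density))
}

#' Stable explicit time step of a mesh
#'
#' CFL bound: `cfl_factor` times the smallest element characteristic length
#' divided by the dilatational wave speed.
#'
#' @param mesh A `pfm_mesh` (its `characteristic_edge` is the length scale).
#' @param material A [material_params()] object.
#' @param cfl_factor Safety factor in (0, 1].
#' @return Time step, s.
#' @export
stable_dt <- function(mesh, material, cfl_factor = 0.8) {
  if (!is.finite(cfl_factor) || cfl_factor <= 0 || cfl_factor > 1)
    stop("cfl_factor must lie in (0, 1]", call. = FALSE)
  cfl_factor * mesh$characteristic_edge / dilatational_wave_speed(material)
}

# ---- vectorized whole-mesh kernel (internal) --------------------------------

# column index of entry (a, b) in an E x 9 column-major 3 x 3 store
.c9 <- function(a, b) (b - 1L) * 3L + a

# Precompute reference-configuration arrays for the explicit solver.
# kappa_c is the volumetric compression-barrier stiffness (MPa): the Saint
# Venant-Kirchhoff law softens and can invert under strong compression, so
# the solver augments it with W_vol = kappa_c/2 (J - 1)^2 for J < 1, whose
# force contribution kappa_c (J - 1) cof(F) is well-defined for any J and
# pushes crushed or inverted elements back towards J = 1.  This mimics the
# stiff compressive response of the corotational small-strain law used by
# commercial explicit solvers while leaving the tensile behavior untouched.
precompute_kernel <- function(mesh, material, kappa_c = 0) {
  tets <- mesh$tets
  nodes <- mesh$nodes
  E <- nrow(tets)
  d1 <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  d2 <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  d3 <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  detD <- d1[, 1] * (d2[, 2] * d3[, 3] - d2[, 3] * d3[, 2]) -
          d1[, 2] * (d2[, 1] * d3[, 3] - d2[, 3] * d3[, 1]) +
          d1[, 3] * (d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1])
  V0 <- detD / 6
  if (any(V0 <= 0)) stop("mesh error: non-positive element volume", call. = FALSE)
  # inverse of Dm = [d1 d2 d3] (columns): row i of the inverse is the cross
  # product of the other two columns over the determinant
  cross3 <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
  r1 <- cross3(d2, d3) / detD
  r2 <- cross3(d3, d1) / detD
  r3 <- cross3(d1, d2) / detD
  Bm <- matrix(0, E, 9)
  for (b in 1:3) {
    Bm[, .c9(1, b)] <- r1[, b]
    Bm[, .c9(2, b)] <- r2[, b]
    Bm[, .c9(3, b)] <- r3[, b]
  }
  lc <- lame_constants(material)
  scatter <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  # sparse assembly operator: nodal force = A %*% stacked element forces
  A <- Matrix::sparseMatrix(i = scatter, j = seq_along(scatter), x = 1,
                            dims = c(nrow(nodes), 4L * E))
  # volume-weighted element-to-node averaging operator (the standard
  # "nephogram" smoothing used when reporting peak field values)
  An <- Matrix::sparseMatrix(i = scatter, j = rep(seq_len(E), 4L),
                             x = rep(V0, 4L), dims = c(nrow(nodes), E))
  An_den <- as.numeric(An %*% rep(1, E))
  list(i1 = tets[, 1], i2 = tets[, 2], i3 = tets[, 3], i4 = tets[, 4],
       Bm = Bm, V0 = V0, lambda = lc$lambda, mu = lc$mu, kappa_c = kappa_c,
       nE = E, nN = nrow(nodes), X = nodes, scatter = scatter, A = A,
       An = An, An_den = An_den)
}

# Volume-weighted average of a per-element scalar at the nodes.
kernel_nodal_average <- function(ker, field) {
  as.numeric(ker$An %*% field) / ker$An_den
}

# Deformation gradients (E x 9) for current positions p (N x 3).
kernel_defgrad <- function(ker, p) {
  d1 <- p[ker$i2, , drop = FALSE] - p[ker$i1, , drop = FALSE]
  d2 <- p[ker$i3, , drop = FALSE] - p[ker$i1, , drop = FALSE]
  d3 <- p[ker$i4, , drop = FALSE] - p[ker$i1, , drop = FALSE]
  Bm <- ker$Bm
  F9 <- matrix(0, ker$nE, 9)
  for (b in 1:3) {
    b1 <- Bm[, .c9(1, b)]; b2 <- Bm[, .c9(2, b)]; b3 <- Bm[, .c9(3, b)]
    for (a in 1:3)
      F9[, .c9(a, b)] <- d1[, a] * b1 + d2[, a] * b2 + d3[, a] * b3
  }
  F9
}

# Green strain components (E x 6: 11, 22, 33, 12, 13, 23) from F9.
kernel_green <- function(F9) {
  g <- matrix(0, nrow(F9), 6)
  for (b in 1:3) {
    f1 <- F9[, .c9(1, b)]; f2 <- F9[, .c9(2, b)]; f3 <- F9[, .c9(3, b)]
    g[, b] <- 0.5 * (f1 * f1 + f2 * f2 + f3 * f3 - 1)
  }
  pair <- rbind(c(1, 2), c(1, 3), c(2, 3))
  for (r in 1:3) {
    a <- pair[r, 1]; b <- pair[r, 2]
    g[, 3 + r] <- 0.5 * (F9[, .c9(1, a)] * F9[, .c9(1, b)] +
                         F9[, .c9(2, a)] * F9[, .c9(2, b)] +
                         F9[, .c9(3, a)] * F9[, .c9(3, b)])
  }
  g
}

# SVK second PK stress components (E x 6) from Green strain components.
kernel_pk2 <- function(ker, g) {
  trE <- g[, 1] + g[, 2] + g[, 3]
  s <- 2 * ker$mu * g
  s[, 1] <- s[, 1] + ker$lambda * trE
  s[, 2] <- s[, 2] + ker$lambda * trE
  s[, 3] <- s[, 3] + ker$lambda * trE
  s
}

sym6_full <- function(s, a, b) {
  if (a == b) return(s[, a])
  i <- a + b  # (1,2)->3 -> col 4; (1,3)->4 -> col 5; (2,3)->5 -> col 6
  s[, i + 1L]
}

# Internal nodal forces (N x 3) plus element fields; the workhorse of the
# explicit loop, written with flat local vectors to minimize allocations.
# Returns forces only unless fields = TRUE.
kernel_internal_forces <- function(ker, u, fields = FALSE) {
  p <- ker$X + u
  e1 <- p[ker$i2, , drop = FALSE] - p[ker$i1, , drop = FALSE]
  e2 <- p[ker$i3, , drop = FALSE] - p[ker$i1, , drop = FALSE]
  e3 <- p[ker$i4, , drop = FALSE] - p[ker$i1, , drop = FALSE]
  Bm <- ker$Bm
  b11 <- Bm[, 1]; b21 <- Bm[, 2]; b31 <- Bm[, 3]
  b12 <- Bm[, 4]; b22 <- Bm[, 5]; b32 <- Bm[, 6]
  b13 <- Bm[, 7]; b23 <- Bm[, 8]; b33 <- Bm[, 9]
  f11 <- e1[, 1] * b11 + e2[, 1] * b21 + e3[, 1] * b31
  f21 <- e1[, 2] * b11 + e2[, 2] * b21 + e3[, 2] * b31
  f31 <- e1[, 3] * b11 + e2[, 3] * b21 + e3[, 3] * b31
  f12 <- e1[, 1] * b12 + e2[, 1] * b22 + e3[, 1] * b32
  f22 <- e1[, 2] * b12 + e2[, 2] * b22 + e3[, 2] * b32
  f32 <- e1[, 3] * b12 + e2[, 3] * b22 + e3[, 3] * b32
  f13 <- e1[, 1] * b13 + e2[, 1] * b23 + e3[, 1] * b33
  f23 <- e1[, 2] * b13 + e2[, 2] * b23 + e3[, 2] * b33
  f33 <- e1[, 3] * b13 + e2[, 3] * b23 + e3[, 3] * b33
  g11 <- 0.5 * (f11 * f11 + f21 * f21 + f31 * f31 - 1)
  g22 <- 0.5 * (f12 * f12 + f22 * f22 + f32 * f32 - 1)
  g33 <- 0.5 * (f13 * f13 + f23 * f23 + f33 * f33 - 1)
  g12 <- 0.5 * (f11 * f12 + f21 * f22 + f31 * f32)
  g13 <- 0.5 * (f11 * f13 + f21 * f23 + f31 * f33)
  g23 <- 0.5 * (f12 * f13 + f22 * f23 + f32 * f33)
  ltr <- ker$lambda * (g11 + g22 + g33)
  two_mu <- 2 * ker$mu
  s11 <- ltr + two_mu * g11
  s22 <- ltr + two_mu * g22
  s33 <- ltr + two_mu * g33
  s12 <- two_mu * g12
  s13 <- two_mu * g13
  s23 <- two_mu * g23
  p11 <- f11 * s11 + f12 * s12 + f13 * s13
  p12 <- f11 * s12 + f12 * s22 + f13 * s23
  p13 <- f11 * s13 + f12 * s23 + f13 * s33
  p21 <- f21 * s11 + f22 * s12 + f23 * s13
  p22 <- f21 * s12 + f22 * s22 + f23 * s23
  p23 <- f21 * s13 + f22 * s23 + f23 * s33
  p31 <- f31 * s11 + f32 * s12 + f33 * s13
  p32 <- f31 * s12 + f32 * s22 + f33 * s23
  p33 <- f31 * s13 + f32 * s23 + f33 * s33
  if (ker$kappa_c > 0) {
    J <- f11 * (f22 * f33 - f23 * f32) - f12 * (f21 * f33 - f23 * f31) +
         f13 * (f21 * f32 - f22 * f31)
    vfac <- ker$kappa_c * pmin(J - 1, 0)
    p11 <- p11 + vfac * (f22 * f33 - f23 * f32)
    p12 <- p12 + vfac * (f23 * f31 - f21 * f33)
    p13 <- p13 + vfac * (f21 * f32 - f22 * f31)
    p21 <- p21 + vfac * (f13 * f32 - f12 * f33)
    p22 <- p22 + vfac * (f11 * f33 - f13 * f31)
    p23 <- p23 + vfac * (f12 * f31 - f11 * f32)
    p31 <- p31 + vfac * (f12 * f23 - f13 * f22)
    p32 <- p32 + vfac * (f13 * f21 - f11 * f23)
    p33 <- p33 + vfac * (f11 * f22 - f12 * f21)
  }
  V0 <- ker$V0
  nE <- ker$nE
  fmat <- matrix(0, 4L * nE, 3)
  i0 <- seq_len(nE)
  h1 <- -V0 * (p11 * b11 + p12 * b12 + p13 * b13)
  h2 <- -V0 * (p11 * b21 + p12 * b22 + p13 * b23)
  h3 <- -V0 * (p11 * b31 + p12 * b32 + p13 * b33)
  fmat[i0, 1] <- -(h1 + h2 + h3)
  fmat[nE + i0, 1] <- h1; fmat[2L * nE + i0, 1] <- h2; fmat[3L * nE + i0, 1] <- h3
  h1 <- -V0 * (p21 * b11 + p22 * b12 + p23 * b13)
  h2 <- -V0 * (p21 * b21 + p22 * b22 + p23 * b23)
  h3 <- -V0 * (p21 * b31 + p22 * b32 + p23 * b33)
  fmat[i0, 2] <- -(h1 + h2 + h3)
  fmat[nE + i0, 2] <- h1; fmat[2L * nE + i0, 2] <- h2; fmat[3L * nE + i0, 2] <- h3
  h1 <- -V0 * (p31 * b11 + p32 * b12 + p33 * b13)
  h2 <- -V0 * (p31 * b21 + p32 * b22 + p33 * b23)
  h3 <- -V0 * (p31 * b31 + p32 * b32 + p33 * b33)
  fmat[i0, 3] <- -(h1 + h2 + h3)
  fmat[nE + i0, 3] <- h1; fmat[2L * nE + i0, 3] <- h2; fmat[3L * nE + i0, 3] <- h3
  fint <- as.matrix(ker$A %*% fmat)
  if (!fields) return(list(forces = fint))
  F9 <- cbind(f11, f21, f31, f12, f22, f32, f13, f23, f33)
  g <- cbind(g11, g22, g33, g12, g13, g23)
  s <- cbind(s11, s22, s33, s12, s13, s23)
  colnames(F9) <- NULL; colnames(g) <- NULL; colnames(s) <- NULL
  list(forces = fint, F9 = F9, green = g, pk2 = s)
}

# Total strain energy (mJ): SVK part from Green strain components, plus the
# volumetric compression barrier when J is supplied and kappa_c > 0.
kernel_strain_energy <- function(ker, g, J = NULL) {
  trE <- g[, 1] + g[, 2] + g[, 3]
  w <- sum(ker$V0 * (ker$lambda / 2 * trE^2 +
                     ker$mu * (g[, 1]^2 + g[, 2]^2 + g[, 3]^2 +
                               2 * (g[, 4]^2 + g[, 5]^2 + g[, 6]^2))))
  if (ker$kappa_c > 0 && !is.null(J))
    w <- w + sum(ker$V0 * ker$kappa_c / 2 * pmin(J - 1, 0)^2)
  w
}

kernel_detF <- function(F9) {
  F9[, 1] * (F9[, 5] * F9[, 9] - F9[, 8] * F9[, 6]) -
  F9[, 4] * (F9[, 2] * F9[, 9] - F9[, 8] * F9[, 3]) +
  F9[, 7] * (F9[, 2] * F9[, 6] - F9[, 5] * F9[, 3])
}

# Cauchy stress components (E x 6) from F9 and PK2 components: F S F^T / J.
kernel_cauchy <- function(F9, s) {
  J <- kernel_detF(F9)
  P9 <- matrix(0, nrow(F9), 9)
  for (a in 1:3) for (b in 1:3) {
    P9[, .c9(a, b)] <- F9[, .c9(a, 1)] * sym6_full(s, 1, b) +
                       F9[, .c9(a, 2)] * sym6_full(s, 2, b) +
                       F9[, .c9(a, 3)] * sym6_full(s, 3, b)
  }
  sig <- matrix(0, nrow(F9), 6)
  cols <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (r in 1:6) {
    a <- cols[r, 1]; b <- cols[r, 2]
    sig[, r] <- (P9[, .c9(a, 1)] * F9[, .c9(b, 1)] +
                 P9[, .c9(a, 2)] * F9[, .c9(b, 2)] +
                 P9[, .c9(a, 3)] * F9[, .c9(b, 3)]) / J
  }
  sig
}
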