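# Shared fixtures: built in code, memoized within a test file.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_geometry <- function() pfm_geometry()

coarse_mesh <- function(edge = 5) {
  memo(paste0("mesh_", edge), {
    geo <- default_geometry()
    select_fixed_rim(tetrahedralize(build_pfm_surrogate(geo), edge), geo)
  })
}

# a well-shaped reference tetrahedron
unit_tet <- function() rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

# single-tet mesh object sufficient for the element kernels
single_tet_mesh <- function(X = unit_tet()) {
  structure(list(nodes = X, tets = matrix(1:4, 1, 4), node_sets = list(),
                 characteristic_edge = min(pfmsim:::tet_altitudes(X, matrix(1:4, 1, 4))),
                 nominal_edge = 1, volume = abs(det(rbind(X[2, ] - X[1, ],
                                                          X[3, ] - X[1, ],
                                                          X[4, ] - X[1, ]))) / 6,
                 params = NULL),
            class = "pfm_mesh")
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# short coarse descent run for solver-level unit tests
short_run <- function() {
  memo("short_run", {
    mesh <- coarse_mesh(5)
    cfg <- simulation_config(duration = 0.06, snapshot_interval = 0.03,
                             contact = contact_params(penalty_stiffness = 12))
    run_simulation(mesh, material_params(), place_sphere(mesh, 90), cfg)
  })
}
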