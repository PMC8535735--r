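config_spec <- function() {
  list(
    geometry = c("length", "width", "height", "sheet_thickness",
                 "hiatus_semiaxes", "bowl_profile", "rng_seed"),
    material = c("young_modulus", "poisson_ratio", "density"),
    sphere = c("diameter", "density", "gap"),
    contact = c("friction_coefficient", "penalty_stiffness",
                "friction_regularization_velocity", "penetration_tolerance"),
    simulation = c("duration", "snapshot_interval", "gravity", "cfl_factor",
                   "damping_ratio", "initial_gap", "contact_enabled",
                   "monitor_points", "rng_seed"),
    mesh = c("target_edge", "fixed_edges", "band")
  )
}

#' Load a run configuration from a YAML file
#'
#' The file may contain the sections `geometry`, `material`, `sphere`,
#' `contact`, `simulation` and `mesh`; any omitted key falls back to the
#' package defaults (the published muscle dimensions and material constants,
#' friction coefficient 0.03, 23 mm initial gap, 0.15 s duration).  Unknown
#' keys are rejected with the list of valid keys; invariant violations are
#' reported by the respective constructor.
#'
#' @param path Path to a YAML config file (an empty or missing-section file
#'   yields the full default set).
#' @return A list with `geometry`, `material`, `sphere` (diameter/density/gap
#'   list), `contact`, `simulation`, `mesh` (target_edge, fixed_edges, band).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  spec <- config_spec()
  bad_sec <- setdiff(names(raw), names(spec))
  if (length(bad_sec))
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "),
         "; valid sections: ", paste(names(spec), collapse = ", "), call. = FALSE)
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), spec[[sec]])
    if (length(bad))
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "),
           "; valid keys: ", paste(spec[[sec]], collapse = ", "), call. = FALSE)
  }
  geometry <- do.call(pfm_geometry, raw$geometry %||% list())
  material <- do.call(material_params, raw$material %||% list())
  contact <- do.call(contact_params, raw$contact %||% list())
  sim_args <- raw$simulation %||% list()
  sim_args$contact <- contact
  simulation <- do.call(simulation_config, sim_args)
  sphere <- utils::modifyList(list(diameter = 90, density = 7.86e-9,
                                   gap = simulation$initial_gap),
                              raw$sphere %||% list())
  if (sphere$diameter <= 0) stop("validation error: sphere diameter must be > 0", call. = FALSE)
  mesh <- utils::modifyList(list(target_edge = 3, fixed_edges = "xmin",
                                 band = NULL), raw$mesh %||% list())
  list(geometry = geometry, material = material, sphere = sphere,
       contact = contact, simulation = simulation, mesh = mesh)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x) formatC(x, format = "g", digits = 8)

# Write one legacy-VTK ASCII unstructured-grid file with nodal displacement
# and per-element invariant fields.
write_vtk_snapshot <- function(path, mesh, u, vm = NULL, ps = NULL, pe = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); e <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0",
               "pfmsim field snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(mesh$nodes, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", e, 5L * e), con)
  writeLines(apply(mesh$tets - 1L, 1, function(r) paste(c(4L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", e), con)
  writeLines(rep("10", e), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines("VECTORS displacement float", con)
  writeLines(apply(u, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  if (!is.null(vm)) {
    writeLines(sprintf("CELL_DATA %d", e), con)
    for (nm in c("von_mises", "max_principal_stress", "max_principal_strain")) {
      val <- switch(nm, von_mises = vm, max_principal_stress = ps,
                    max_principal_strain = pe)
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(fmt_num(val), con)
    }
  }
  invisible(path)
}

#' Write the snapshot series of a run as VTK files plus a time-series index
#'
#' One legacy-VTK ASCII file per snapshot (displacement vectors on nodes;
#' equivalent stress and maximum principal stress/strain on elements) and a
#' ParaView `.series` JSON index mapping files to times.
#'
#' @param run A `pfm_run`.
#' @param mesh The mesh the run used (defaults to `run$mesh`).
#' @param outdir Output directory (created if needed).
#' @param basename File stem for the series.
#' @return Character vector of the files written (index last), invisibly.
#' @export
write_snapshot_series <- function(run, mesh = run$mesh, outdir,
                                  basename = "pfm") {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory ", outdir, call. = FALSE)
  files <- character(0)
  entries <- list()
  for (i in seq_along(run$snapshots)) {
    sn <- run$snapshots[[i]]
    f <- file.path(outdir, sprintf("%s_%03d.vtk", basename, i - 1L))
    write_vtk_snapshot(f, mesh, sn$u,
                       vm = vm_vec(sn$cauchy), ps = maxp_vec(sn$cauchy),
                       pe = maxp_vec(sn$green))
    files <- c(files, f)
    entries[[i]] <- list(name = base::basename(f), time = sn$time)
  }
  idx <- file.path(outdir, paste0(basename, ".vtk.series"))
  jsonlite::write_json(list(`file-series-version` = "1.0", files = entries),
                       idx, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, idx))
}

#' Read back a legacy-VTK snapshot written by this package
#'
#' Minimal reader for round-trip verification of [write_snapshot_series()]
#' output (ASCII unstructured grid with the fields this package writes).
#'
#' @param path A `.vtk` file.
#' @return List with `nodes`, `tets`, `displacement`, and any cell scalars.
#' @export
read_vtk_snapshot <- function(path) {
  lines <- readLines(path)
  num <- function(l) scan(text = l, quiet = TRUE)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  nodes <- matrix(num(lines[(ip + 1):(ip + n)]), n, 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  e <- as.integer(strsplit(lines[ic], " +")[[1]][2])
  cells <- matrix(as.integer(num(lines[(ic + 1):(ic + e)])), e, 5, byrow = TRUE)
  iv <- grep("^VECTORS displacement", lines)[1]
  disp <- matrix(num(lines[(iv + 1):(iv + n)]), n, 3, byrow = TRUE)
  out <- list(nodes = nodes, tets = cells[, 2:5] + 1L, displacement = disp)
  for (is in grep("^SCALARS", lines)) {
    nm <- strsplit(lines[is], " +")[[1]][2]
    out[[nm]] <- num(lines[(is + 2):(is + 1 + e)])
  }
  out
}

#' Export a mesh as an Abaqus INP deck
#'
#' Nodes, C3D4 elements and an NSET for the fixed rim; intended as a
#' case-exchange convenience for cross-checking in commercial solvers.
#'
#' @param mesh A `pfm_mesh`.
#' @param path Output `.inp` path.
#' @return The path, invisibly.
#' @export
write_abaqus_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines("pfmsim surrogate pelvic floor muscle mesh (mm-ton-s units)", con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.8g, %.8g, %.8g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D4, ELSET=PFM", con)
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  if (!is.null(mesh$node_sets$fixed_rim)) {
    writeLines("*NSET, NSET=FIXED_RIM", con)
    ids <- mesh$node_sets$fixed_rim
    for (i in seq(1, length(ids), by = 8))
      writeLines(paste(ids[i:min(i + 7, length(ids))], collapse = ", "), con)
  }
  invisible(path)
}

#' Export a mesh in Gmsh MSH 2.2 ASCII format
#'
#' @param mesh A `pfm_mesh`.
#' @param path Output `.msh` path.
#' @return The path, invisibly.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.8g %.8g %.8g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$tets))), con)
  writeLines(sprintf("%d 4 2 1 1 %d %d %d %d", seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Run manifest
#'
#' Provenance record that fully determines a rerun: config hash, package
#' version, seed, mesh statistics, material echo and solver status flags.
#'
#' @param run A `pfm_run`.
#' @return A list of class `pfm_manifest`.
#' @export
run_manifest <- function(run) {
  cfg_file <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_file))
  jsonlite::write_json(list(config = run$config, material = run$material,
                            sphere = run$sphere[c("diameter", "density")],
                            params = run$params),
                       cfg_file, auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(list(
    config_hash = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("pfmsim")),
    rng_seed = run$config$rng_seed,
    mesh = if (!is.null(run$mesh))
      list(n_nodes = nrow(run$mesh$nodes), n_tets = nrow(run$mesh$tets),
           characteristic_edge = run$mesh$characteristic_edge,
           nominal_edge = run$mesh$nominal_edge) else NULL,
    material = run$material,
    diameter = run$sphere$diameter,
    standard_diameter = run$sphere$diameter %in% c(80, 90, 100),
    n_steps = run$diagnostics$n_steps,
    dt0 = run$diagnostics$dt0,
    max_penetration = run$diagnostics$max_penetration,
    energy_residual_frac = run$diagnostics$energy_residual_frac,
    completed = TRUE
  ), class = "pfm_manifest")
}
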