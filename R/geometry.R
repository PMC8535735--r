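#' Parametric pelvic-floor-muscle geometry parameters
#'
#' Describes the synthetic PFM surrogate: a downward-sagging elastic sheet
#' ("hammock") spanning a `length` x `width` footprint, sagging so that the
#' solid's bounding box is exactly `length` x `width` x `height`, pierced by a
#' central elliptical urogenital hiatus.  The surrogate stands in for a
#' subject-specific MRI-derived levator ani model; only the bounding
#' dimensions are anatomical targets, the rest is a parametric idealization.
#'
#' Coordinates: X is the `length` (70 mm) direction, Y the `width` (60 mm)
#' direction, Z vertical with descent towards -Z.  The sheet's upper rim lies
#' at z = 0 and its lowest material point at z = -`height`.
#'
#' @param length Footprint extent in X, mm.
#' @param width Footprint extent in Y, mm.
#' @param height Total vertical extent of the solid (sag plus thickness), mm.
#' @param sheet_thickness Sheet thickness, measured vertically, mm.
#' @param hiatus_semiaxes Semi-axes (X, Y) of the elliptical hiatus, mm.  The
#'   default 25 x 15 mm opening is smaller than every simulated head so that
#'   passage requires stretching the muscle.
#' @param hiatus_center In-plane center (X, Y) of the hiatus, mm.  The default
#'   shifts the opening anteriorly (towards +X), away from the skeletal
#'   attachment at the -X end, mirroring the anterior position of the
#'   urogenital hiatus relative to the posterior levator plate.
#' @param bowl_profile Shape exponent p >= 1 of the sag profile
#'   `(1 - rho)^p`, where rho is the normalized in-plane coordinate running
#'   from 0 at the hiatus rim to 1 at the outer footprint boundary.  Larger
#'   values concentrate the funnel near the hiatus.
#' @param rng_seed Integer seed recorded with the geometry (reserved for
#'   randomized anatomy variants; the default surrogate is fully
#'   deterministic).
#' @return An object of class `pfm_geometry`.
#' @export
pfm_geometry <- function(length = 70, width = 60, height = 40,
                         sheet_thickness = 6, hiatus_semiaxes = c(25, 15),
                         hiatus_center = c(6, 0), bowl_profile = 2,
                         rng_seed = 1L) {
  p <- list(length = length, width = width, height = height,
            sheet_thickness = sheet_thickness,
            hiatus_semiaxes = as.numeric(hiatus_semiaxes),
            hiatus_center = as.numeric(hiatus_center),
            bowl_profile = bowl_profile, rng_seed = as.integer(rng_seed))
  class(p) <- "pfm_geometry"
  validate_pfm_geometry(p)
  p
}

validate_pfm_geometry <- function(p) {
  lin <- c(p$length, p$width, p$height, p$sheet_thickness, p$hiatus_semiaxes)
  if (any(!is.finite(lin)) || any(lin <= 0))
    stop("all linear dimensions of a pfm_geometry must be positive", call. = FALSE)
  if (length(p$hiatus_semiaxes) != 2L)
    stop("hiatus_semiaxes must be a pair (a_x, a_y) in mm", call. = FALSE)
  if (length(p$hiatus_center) != 2L || any(!is.finite(p$hiatus_center)))
    stop("hiatus_center must be a finite pair (x, y) in mm", call. = FALSE)
  if (abs(p$hiatus_center[1]) + p$hiatus_semiaxes[1] >= p$length / 2 ||
      abs(p$hiatus_center[2]) + p$hiatus_semiaxes[2] >= p$width / 2)
    stop("invalid parameter: hiatus must fit strictly inside the length x width footprint",
         call. = FALSE)
  if (p$sheet_thickness >= p$height)
    stop("sheet_thickness must be smaller than the total height", call. = FALSE)
  if (!is.finite(p$bowl_profile) || p$bowl_profile < 1)
    stop("bowl_profile must be a finite exponent >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.pfm_geometry <- function(x, ...) {
  cat(sprintf("PFM surrogate geometry: %g x %g x %g mm, sheet %g mm, hiatus %g x %g mm (semi-axes)\n",
              x$length, x$width, x$height, x$sheet_thickness,
              x$hiatus_semiaxes[1], x$hiatus_semiaxes[2]))
  invisible(x)
}

#' Build the PFM surrogate solid
#'
#' Produces an implicit description of the hammock solid: the region between
#' the sag surface `z_top(x, y)` and `z_top - sheet_thickness`, over the
#' rectangular footprint minus the vertical elliptical hiatus cylinder.  The
#' sag is zero on the footprint boundary and maximal (`height -
#' sheet_thickness`) on the hiatus rim, so the solid's bounding box equals
#' `length x width x height` and its lowest line is the hiatus rim.
#'
#' The description is plain data (parameters only), so two builds from equal
#' parameters serialize identically.
#'
#' @param params A [pfm_geometry()] object.
#' @return An object of class `pfm_solid`.
#' @export
build_pfm_surrogate <- function(params) {
  validate_pfm_geometry(params)
  solid <- list(
    params = params,
    sag = params$height - params$sheet_thickness,
    bbox = rbind(min = c(-params$length / 2, -params$width / 2, -params$height),
                 max = c(params$length / 2, params$width / 2, 0))
  )
  class(solid) <- "pfm_solid"
  solid
}

# Elliptical hiatus coordinate: m = 1 on the hiatus rim, m > 1 outside.
hiatus_coord <- function(solid, x, y) {
  p <- solid$params
  sqrt(((x - p$hiatus_center[1]) / p$hiatus_semiaxes[1])^2 +
       ((y - p$hiatus_center[2]) / p$hiatus_semiaxes[2])^2)
}

#' Upper sag surface of the surrogate solid
#'
#' @param solid A `pfm_solid`.
#' @param x,y Coordinates, mm (vectorized).
#' @return z of the upper surface, mm (NA inside the hiatus footprint).
#' @export
solid_z_top <- function(solid, x, y) {
  p <- solid$params
  m <- hiatus_coord(solid, x, y)
  # scale factor along the ray from the hiatus center to the footprint edge
  dx <- x - p$hiatus_center[1]
  dy <- y - p$hiatus_center[2]
  kx <- ifelse(dx > 0, (p$length / 2 - p$hiatus_center[1]) / dx,
               ifelse(dx < 0, (-p$length / 2 - p$hiatus_center[1]) / dx, Inf))
  ky <- ifelse(dy > 0, (p$width / 2 - p$hiatus_center[2]) / dy,
               ifelse(dy < 0, (-p$width / 2 - p$hiatus_center[2]) / dy, Inf))
  m_edge <- pmin(kx, ky) * m
  rho <- pmin(pmax((m - 1) / (m_edge - 1), 0), 1)
  z <- -solid$sag * (1 - rho)^p$bowl_profile
  z[m < 1 - 1e-12] <- NA_real_
  z
}

#' Point-membership test for the surrogate solid
#'
#' @param solid A `pfm_solid`.
#' @param pts n x 3 matrix of coordinates, mm.
#' @return Logical vector: TRUE where the point lies inside the solid.
#' @export
solid_contains <- function(solid, pts) {
  pts <- rbind(pts)
  p <- solid$params
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  inside_fp <- abs(x) <= p$length / 2 & abs(y) <= p$width / 2
  m <- hiatus_coord(solid, x, y)
  out <- inside_fp & m > 1
  zt <- rep(NA_real_, length(x))
  zt[out] <- solid_z_top(solid, x[out], y[out])
  out & !is.na(zt) & z <= zt & z >= zt - p$sheet_thickness
}

# Monte-Carlo volume of the implicit solid (oracle used in tests and to
# cross-check meshing).
solid_volume_mc <- function(solid, n = 1e5, seed = 1L) {
  set.seed(seed)
  bb <- solid$bbox
  pts <- cbind(stats::runif(n, bb[1, 1], bb[2, 1]),
               stats::runif(n, bb[1, 2], bb[2, 2]),
               stats::runif(n, bb[1, 3], bb[2, 3]))
  vol_box <- prod(bb[2, ] - bb[1, ])
  mean(solid_contains(solid, pts)) * vol_box
}

#' Tetrahedralize the surrogate solid
#'
#' Structured meshing: the footprint is divided into an `nx` x `ny` grid of
#' columns (cells whose center falls inside the hiatus are dropped), each
#' column is extruded vertically through the sheet thickness in `nz` layers,
#' and every hexahedral cell is split into six tetrahedra along a globally
#' consistent main diagonal (Kuhn/Freudenthal subdivision), which guarantees
#' conforming faces between neighbors.  Node ordering of every tet is fixed so
#' that its signed volume is strictly positive.
#'
#' @param solid A `pfm_solid`.
#' @param target_edge Target edge length, mm, in `[1, 5]`.
#' @return An object of class `pfm_mesh` with fields `nodes` (N x 3, mm),
#'   `tets` (E x 4 node indices), `node_sets` (named list, initially empty),
#'   `characteristic_edge` (min element altitude, mm; the explicit-dynamics
#'   length scale), `nominal_edge`, `median_edge`, `volume` and `params`.
#' @export
tetrahedralize <- function(solid, target_edge = 3) {
  if (!inherits(solid, "pfm_solid")) stop("solid must be a pfm_solid", call. = FALSE)
  if (!is.finite(target_edge) || target_edge < 1 || target_edge > 5)
    stop("target_edge must lie in [1, 5] mm", call. = FALSE)
  p <- solid$params
  nz <- max(2L, as.integer(round(p$sheet_thickness / target_edge)))
  xs <- graded_axis(solid, target_edge, axis = 1L)
  ys <- graded_axis(solid, target_edge, axis = 2L)
  nx <- length(xs) - 1L
  ny <- length(ys) - 1L

  # columns kept: cell-center outside the hiatus ellipse
  ic <- rep(seq_len(nx), times = ny)
  jc <- rep(seq_len(ny), each = nx)
  xc <- (xs[ic] + xs[ic + 1L]) / 2
  yc <- (ys[jc] + ys[jc + 1L]) / 2
  keep <- hiatus_coord(solid, xc, yc) > 1
  ic <- ic[keep]; jc <- jc[keep]

  # nodes: union of corners of kept columns, all nz + 1 layers
  corner_id <- unique(c((jc - 1L) * (nx + 1L) + ic,
                        (jc - 1L) * (nx + 1L) + ic + 1L,
                        jc * (nx + 1L) + ic,
                        jc * (nx + 1L) + ic + 1L))
  corner_id <- sort(corner_id)
  col_lookup <- integer((nx + 1L) * (ny + 1L))
  col_lookup[corner_id] <- seq_along(corner_id)
  gx <- xs[(corner_id - 1L) %% (nx + 1L) + 1L]
  gy <- ys[(corner_id - 1L) %/% (nx + 1L) + 1L]
  # corners of kept boundary cells that fall inside the hiatus footprint are
  # projected radially onto the rim, so the polygonal hole inscribes the true
  # ellipse and the mesh reaches the full sag depth
  m_corner <- hiatus_coord(solid, gx, gy)
  inside <- m_corner < 1
  if (any(inside)) {
    cx <- p$hiatus_center[1]; cy <- p$hiatus_center[2]
    gx[inside] <- cx + (gx[inside] - cx) / m_corner[inside]
    gy[inside] <- cy + (gy[inside] - cy) / m_corner[inside]
  }

  # cleanup: merge in-plane corner pairs left closer than a fraction of the
  # target edge by the rim projection (they would otherwise produce sliver
  # prisms along the hiatus boundary); footprint-boundary corners take
  # precedence over rim corners over interior ones, so the bounding box is
  # preserved
  on_boundary <- abs(abs(gx) - p$length / 2) < 1e-9 |
                 abs(abs(gy) - p$width / 2) < 1e-9
  priority <- ifelse(on_boundary, 2L, ifelse(inside, 1L, 0L))
  merge_map <- merge_close_points(gx, gy, priority, 0.35 * target_edge)
  gx <- gx[merge_map$keep]; gy <- gy[merge_map$keep]
  col_remap <- merge_map$map  # old corner index -> new corner index
  ztop <- solid_z_top(solid, gx, gy)
  ztop[is.na(ztop)] <- -solid$sag

  # vertical extrusion through the sheet thickness: consistent with the
  # implicit solid definition (thickness measured along Z), exact prism
  # volumes, and robustly positive tets on the steep funnel wall
  ncol_nodes <- length(gx)
  nodes <- matrix(0, ncol_nodes * (nz + 1L), 3)
  for (k in 0:nz) {
    idx <- k * ncol_nodes + seq_len(ncol_nodes)
    nodes[idx, 1] <- gx
    nodes[idx, 2] <- gy
    nodes[idx, 3] <- ztop - (k / nz) * p$sheet_thickness
  }

  node_id <- function(col, k) k * ncol_nodes + col  # col: merged corner index

  # hex corners per cell and layer; local vertex v(di,dj,dk)
  c00 <- col_remap[col_lookup[(jc - 1L) * (nx + 1L) + ic]]
  c10 <- col_remap[col_lookup[(jc - 1L) * (nx + 1L) + ic + 1L]]
  c01 <- col_remap[col_lookup[jc * (nx + 1L) + ic]]
  c11 <- col_remap[col_lookup[jc * (nx + 1L) + ic + 1L]]

  # Kuhn subdivision: six tets sharing the (0,0,0)-(1,1,1) diagonal; each tet
  # follows a monotone path 000 -> 111.  Note Z layers grow downwards.
  paths <- list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  tet_list <- vector("list", nz * 6L)
  ti <- 0L
  for (k in 0:(nz - 1L)) {
    v <- list()  # v[[di + 2*dj + 4*dk + 1]]
    v[[1]] <- node_id(c00, k);     v[[2]] <- node_id(c10, k)
    v[[3]] <- node_id(c01, k);     v[[4]] <- node_id(c11, k)
    v[[5]] <- node_id(c00, k + 1L); v[[6]] <- node_id(c10, k + 1L)
    v[[7]] <- node_id(c01, k + 1L); v[[8]] <- node_id(c11, k + 1L)
    for (pth in paths) {
      d <- c(0L, 0L, 0L)
      a <- d; a[pth[1]] <- 1L
      b <- a; b[pth[2]] <- 1L
      vid <- function(d) v[[d[1] + 2L * d[2] + 4L * d[3] + 1L]]
      ti <- ti + 1L
      tet_list[[ti]] <- cbind(vid(c(0L, 0L, 0L)), vid(a), vid(b), vid(c(1L, 1L, 1L)))
    }
  }
  tets <- do.call(rbind, tet_list)

  # drop tets collapsed by the corner merge (repeated vertices or vanishing
  # volume), then enforce positive orientation
  dup <- tets[, 1] == tets[, 2] | tets[, 1] == tets[, 3] | tets[, 1] == tets[, 4] |
         tets[, 2] == tets[, 3] | tets[, 2] == tets[, 4] | tets[, 3] == tets[, 4]
  tets <- tets[!dup, , drop = FALSE]
  vol <- tet_signed_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- tets[flip, 3L]
    tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
    vol <- abs(vol)
  }
  vol_eps <- (0.05 * target_edge)^3
  ok <- vol > vol_eps
  tets <- tets[ok, , drop = FALSE]
  vol <- vol[ok]
  # drop nodes no longer referenced and compact indices
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tets <- matrix(remap[tets], ncol = 4L)
  if (!nrow(tets))
    stop("meshing error: no valid tetrahedra produced; ",
         "try a different target_edge", call. = FALSE)

  edges <- tet_edge_lengths(nodes, tets)
  mesh <- structure(list(
    nodes = nodes, tets = tets, node_sets = list(),
    characteristic_edge = min(tet_altitudes(nodes, tets, vol)),
    nominal_edge = target_edge,
    median_edge = stats::median(edges),
    volume = sum(vol),
    params = p
  ), class = "pfm_mesh")
  validate_mesh(mesh)
  mesh
}

# Greedy union-find merge of 2D points closer than `thresh`; the surviving
# representative of each cluster is a highest-priority member.  Returns
# `keep` (indices of surviving points, sorted) and `map` (old index -> new
# index into the surviving set).
merge_close_points <- function(x, y, priority, thresh) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  d2 <- thresh^2
  for (i in seq_len(n - 1L)) {
    dx <- x[(i + 1L):n] - x[i]
    close_j <- which(dx^2 + (y[(i + 1L):n] - y[i])^2 < d2) + i
    for (j in close_j) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) {
        if (priority[ri] >= priority[rj]) parent[rj] <- ri else parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- sort(unique(root))
  map <- match(root, keep)
  list(keep = keep, map = map)
}

# Graded grid lines along one in-plane axis: spacing follows the surface
# arc length (capped anisotropy) so that elements on the steep funnel wall
# are not overly stretched.  Mirror-symmetric; always contains 0 and the
# footprint boundary.
graded_axis <- function(solid, target_edge, axis, cap = 2.5, nfine = 801L) {
  p <- solid$params
  half <- if (axis == 1L) p$length / 2 else p$width / 2
  other_half <- if (axis == 1L) p$width / 2 else p$length / 2
  tf <- seq(-half, half, length.out = nfine)
  to <- seq(-other_half, other_half, length.out = 81L)
  # max |dz/dt| over the transverse direction, by finite differences
  h <- 2 * half / (nfine - 1L)
  slope <- numeric(nfine)
  for (i in seq_len(nfine)) {
    tp <- min(tf[i] + h, half); tm <- max(tf[i] - h, -half)
    if (axis == 1L) {
      z1 <- solid_z_top(solid, rep(tp, length(to)), to)
      z2 <- solid_z_top(solid, rep(tm, length(to)), to)
    } else {
      z1 <- solid_z_top(solid, to, rep(tp, length(to)))
      z2 <- solid_z_top(solid, to, rep(tm, length(to)))
    }
    d <- abs(z1 - z2) / (tp - tm)
    d <- d[is.finite(d)]
    slope[i] <- if (length(d)) max(d) else 0
  }
  w <- pmin(sqrt(1 + slope^2), cap)
  arc <- c(0, cumsum((w[-1] + w[-nfine]) / 2 * diff(tf)))
  n_cell <- max(4L, as.integer(round(arc[nfine] / target_edge)))
  th <- stats::approx(arc, tf, xout = seq(0, arc[nfine], length.out = n_cell + 1L),
                      ties = "ordered")$y
  th[1] <- -half; th[n_cell + 1L] <- half
  th
}

tet_signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
    a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
    a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

tri_areas <- function(nodes, i, j, k) {
  u <- nodes[j, , drop = FALSE] - nodes[i, , drop = FALSE]
  v <- nodes[k, , drop = FALSE] - nodes[i, , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# altitude from the largest face: the stability-relevant element length
tet_altitudes <- function(nodes, tets, vol = NULL) {
  if (is.null(vol)) vol <- abs(tet_signed_volumes(nodes, tets))
  amax <- pmax(tri_areas(nodes, tets[, 1], tets[, 2], tets[, 3]),
               tri_areas(nodes, tets[, 1], tets[, 2], tets[, 4]),
               tri_areas(nodes, tets[, 1], tets[, 3], tets[, 4]),
               tri_areas(nodes, tets[, 2], tets[, 3], tets[, 4]))
  3 * vol / amax
}

tet_edge_lengths <- function(nodes, tets) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  unlist(lapply(seq_len(nrow(pairs)), function(r) {
    d <- nodes[tets[, pairs[r, 1]], , drop = FALSE] -
         nodes[tets[, pairs[r, 2]], , drop = FALSE]
    sqrt(rowSums(d^2))
  }))
}

mesh_edge_list <- function(tets) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  e <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r)
    cbind(tets[, pairs[r, 1]], tets[, pairs[r, 2]])))
  unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

mesh_is_connected <- function(mesh) {
  n <- nrow(mesh$nodes)
  e <- mesh_edge_list(mesh$tets)
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  visited <- logical(n)
  frontier <- 1L
  visited[1L] <- TRUE
  while (length(frontier)) {
    nb <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    frontier <- nb[!visited[nb]]
    visited[frontier] <- TRUE
  }
  all(visited)
}

#' Validate a `pfm_mesh`
#'
#' Checks the structural invariants: positive signed volumes, in-range node
#' indices, and (optionally) single connected component.
#'
#' @param mesh A `pfm_mesh`.
#' @param check_connectivity Also run the (slower) connectivity check.
#' @return The mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh, check_connectivity = TRUE) {
  n <- nrow(mesh$nodes)
  if (any(mesh$tets < 1L) || any(mesh$tets > n))
    stop("mesh error: tet node index out of range", call. = FALSE)
  vol <- tet_signed_volumes(mesh$nodes, mesh$tets)
  if (any(vol <= 0))
    stop("mesh error: non-positive element volume", call. = FALSE)
  if (check_connectivity && !mesh_is_connected(mesh))
    stop("mesh error: mesh is not a single connected component", call. = FALSE)
  invisible(mesh)
}

#' @export
print.pfm_mesh <- function(x, ...) {
  cat(sprintf("PFM mesh: %d nodes, %d tets, volume %.0f mm^3, median edge %.2f mm, min altitude %.2f mm\n",
              nrow(x$nodes), nrow(x$tets), x$volume, x$median_edge,
              x$characteristic_edge))
  if (length(x$node_sets))
    cat("  node sets:", paste(sprintf("%s (%d)", names(x$node_sets),
                                      lengths(x$node_sets)), collapse = ", "), "\n")
  invisible(x)
}

#' Select the fixed attachment band of the muscle sheet
#'
#' Populates the mesh's `"fixed_rim"` node set with all nodes within `band` mm
#' of the chosen outer footprint edge(s).  The emulated loading fixes the
#' sheet along one end of the length (X) direction -- the skeletal attachment
#' of the pubococcygeus -- so the default is the `"xmin"` edge; `"perimeter"`
#' fixes the whole outer margin.
#'
#' @param mesh A `pfm_mesh`.
#' @param params The [pfm_geometry()] the mesh was built from (defines the
#'   footprint boundary).
#' @param band Band tolerance, mm: nodes within this in-plane distance of the
#'   selected edges are fixed.
#' @param edges Character vector from `"xmin"`, `"xmax"`, `"ymin"`, `"ymax"`,
#'   or the shorthand `"perimeter"` (all four).
#' @param contact_shadow Width, mm, of the bone-backed strip adjacent to the
#'   fixed edges that is excluded from the head's contact surface (the pubic
#'   bone shields the tissue right at the attachment; the head slides past
#'   it).  Stored as `node_sets$contact_surface`.
#' @return The mesh with `node_sets$fixed_rim` and `node_sets$contact_surface`
#'   populated.
#' @export
select_fixed_rim <- function(mesh, params = mesh$params, band = NULL,
                             edges = "xmin", contact_shadow = 6) {
  if (identical(edges, "xboth")) edges <- c("xmin", "xmax")
  if (is.null(band)) band <- 0.51 * mesh$nominal_edge
  if (!is.finite(band) || band < 0)
    stop("band tolerance must be a non-negative length in mm", call. = FALSE)
  if (identical(edges, "perimeter")) edges <- c("xmin", "xmax", "ymin", "ymax")
  bad <- setdiff(edges, c("xmin", "xmax", "ymin", "ymax"))
  if (length(bad))
    stop("unknown edge selector(s): ", paste(bad, collapse = ", "), call. = FALSE)
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  sel <- rep(FALSE, nrow(mesh$nodes))
  if ("xmin" %in% edges) sel <- sel | x <= -params$length / 2 + band
  if ("xmax" %in% edges) sel <- sel | x >= params$length / 2 - band
  if ("ymin" %in% edges) sel <- sel | y <= -params$width / 2 + band
  if ("ymax" %in% edges) sel <- sel | y >= params$width / 2 - band
  idx <- which(sel)
  if (!length(idx))
    stop("selection error: no nodes within ", band,
         " mm of the requested boundary edges", call. = FALSE)
  a <- params$hiatus_semiaxes[1]; b <- params$hiatus_semiaxes[2]
  m <- sqrt(((x[idx] - params$hiatus_center[1]) / a)^2 +
            ((y[idx] - params$hiatus_center[2]) / b)^2)
  if (any(m <= 1 + 1e-9))
    stop("selection error: fixed band reaches the hiatus rim; reduce band",
         call. = FALSE)
  mesh$node_sets$fixed_rim <- idx
  shadow <- rep(FALSE, nrow(mesh$nodes))
  if ("xmin" %in% edges) shadow <- shadow | x <= -params$length / 2 + contact_shadow
  if ("xmax" %in% edges) shadow <- shadow | x >= params$length / 2 - contact_shadow
  if ("ymin" %in% edges) shadow <- shadow | y <= -params$width / 2 + contact_shadow
  if ("ymax" %in% edges) shadow <- shadow | y >= params$width / 2 - contact_shadow
  mesh$node_sets$contact_surface <- setdiff(which(!shadow), idx)
  mesh
}

#' Place the rigid fetal-head sphere above the muscle
#'
#' Centers the sphere on the hiatus axis (X = Y = 0) at the height for which
#' the minimum clearance between the sphere surface and any mesh node equals
#' `gap`: the sphere starts `gap` mm away from the muscle and the initial
#' contact force is exactly zero (touching, not penetrating, when `gap = 0`).
#'
#' @param mesh A `pfm_mesh`.
#' @param diameter Biparietal diameter, mm (80, 90 or 100 in the emulated
#'   study; other values are allowed).
#' @param density Head density, ton/mm^3.  The default reproduces a 3 kg
#'   newborn head-concentrated mass at 90 mm diameter.
#' @param gap Initial clearance, mm (default 23).
#' @return An object of class `rigid_sphere` with fields `diameter`, `radius`,
#'   `density`, `mass` (ton), `center` (mm), `vertical_velocity` (mm/s).  The
#'   sphere translates along Z only.
#' @export
place_sphere <- function(mesh, diameter, density = 7.86e-9, gap = 23) {
  if (!is.finite(diameter) || diameter <= 0) stop("diameter must be positive", call. = FALSE)
  if (!is.finite(gap) || gap < 0) stop("gap must be non-negative", call. = FALSE)
  r <- diameter / 2
  ctr <- if (!is.null(mesh$params$hiatus_center)) mesh$params$hiatus_center
         else c(0, 0)
  dxy2 <- (mesh$nodes[, 1] - ctr[1])^2 + (mesh$nodes[, 2] - ctr[2])^2
  reach <- (r + gap)^2
  under <- dxy2 < reach
  if (!any(under)) stop("no mesh nodes beneath the sphere footprint", call. = FALSE)
  zc <- max(mesh$nodes[under, 3] + sqrt(reach - dxy2[under]))
  structure(list(diameter = diameter, radius = r, density = density,
                 mass = sphere_mass(diameter, density),
                 center = c(ctr[1], ctr[2], zc), vertical_velocity = 0),
            class = "rigid_sphere")
}

#' @export
print.rigid_sphere <- function(x, ...) {
  cat(sprintf("Rigid head sphere: D = %g mm, mass = %.4g ton (%.3g kg), center z = %.2f mm\n",
              x$diameter, x$mass, x$mass * 1000, x$center[3]))
  invisible(x)
}
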