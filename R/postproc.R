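check_symmetric <- function(S, tol = 1e-8) {
  if (!is.matrix(S) || any(dim(S) != c(3, 3)))
    stop("input must be a 3 x 3 matrix", call. = FALSE)
  scale <- max(abs(S), 1e-300)
  if (max(abs(S - t(S))) > tol * scale)
    stop("input error: tensor is not symmetric within tolerance", call. = FALSE)
  invisible(S)
}

#' Equivalent (von Mises) stress of a symmetric tensor
#'
#' `sqrt(0.5 * ((s1 - s2)^2 + (s2 - s3)^2 + (s3 - s1)^2))` on the principal
#' values; rotation invariant, zero for hydrostatic states.
#'
#' @param S Symmetric 3 x 3 stress tensor, MPa.
#' @return Scalar equivalent stress, MPa.
#' @export
von_mises <- function(S) {
  check_symmetric(S)
  sqrt(0.5 * ((S[1, 1] - S[2, 2])^2 + (S[2, 2] - S[3, 3])^2 +
              (S[3, 3] - S[1, 1])^2) +
       3 * (S[1, 2]^2 + S[1, 3]^2 + S[2, 3]^2))
}

#' Maximum principal value of a symmetric tensor
#'
#' @param S Symmetric 3 x 3 tensor.
#' @return Largest eigenvalue.
#' @export
max_principal <- function(S) {
  check_symmetric(S)
  max(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

# Vectorized invariants on E x 6 symmetric component arrays (11,22,33,12,13,23).

vm_vec <- function(s) {
  sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 + (s[, 3] - s[, 1])^2) +
       3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
}

# Largest eigenvalue via the trigonometric closed form for symmetric 3 x 3.
maxp_vec <- function(s) {
  q <- (s[, 1] + s[, 2] + s[, 3]) / 3
  a11 <- s[, 1] - q; a22 <- s[, 2] - q; a33 <- s[, 3] - q
  p2 <- a11^2 + a22^2 + a33^2 + 2 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)
  p <- sqrt(p2 / 6)
  out <- q
  nz <- p > 1e-300
  if (any(nz)) {
    b11 <- a11[nz] / p[nz]; b22 <- a22[nz] / p[nz]; b33 <- a33[nz] / p[nz]
    b12 <- s[nz, 4] / p[nz]; b13 <- s[nz, 5] / p[nz]; b23 <- s[nz, 6] / p[nz]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
            b13 * (b12 * b23 - b22 * b13)
    phi <- acos(pmin(pmax(detB / 2, -1), 1)) / 3
    out[nz] <- q[nz] + 2 * p[nz] * cos(phi)
  }
  out
}

#' Displacement extrema of a completed run
#'
#' Maximum descent `u_Z` (descent-positive: the largest downward nodal
#' displacement over all nodes and times) and the `u_X` span (largest
#' instantaneous `max(u_X) - min(u_X)` over nodes), each with its occurrence
#' time, read from the dense monitor series.
#'
#' @param run A `pfm_run` from [run_simulation()].
#' @return List `max_uZ`, `t_uZ`, `uX_span`, `t_uX` (mm, s).
#' @export
displacement_extrema <- function(run) {
  mon <- run$monitors
  if (is.null(mon) || !nrow(mon)) stop("input error: empty monitor series", call. = FALSE)
  iz <- which.max(mon$uZ_max)
  ix <- which.max(mon$uX_span)
  list(max_uZ = mon$uZ_max[iz], t_uZ = mon$t[iz],
       uX_span = mon$uX_span[ix], t_uX = mon$t[ix])
}

#' Extension ratios of the pelvic floor muscle
#'
#' Vertical ratio: maximum descent divided by the model height; horizontal
#' ratio: `u_X` span divided by the model length, both in percent.
#'
#' @param max_uZ Maximum descent, mm.
#' @param uX_span Maximum instantaneous `u_X` span, mm.
#' @param height Model height, mm (default 40).
#' @param length Model length, mm (default 70).
#' @return Named vector `c(ratio_Z, ratio_X)`, percent.
#' @export
extension_ratios <- function(max_uZ, uX_span, height = 40, length = 70) {
  if (height <= 0 || length <= 0)
    stop("input error: height and length must be positive", call. = FALSE)
  if (max_uZ < 0 || uX_span < 0)
    stop("input error: displacement extrema must be non-negative", call. = FALSE)
  c(ratio_Z = 100 * max_uZ / height, ratio_X = 100 * uX_span / length)
}

#' Metrics report for one or more completed runs
#'
#' The machine-readable analog of the study's summary tables: per head
#' diameter, the peak equivalent (von Mises) stress, peak maximum principal
#' stress and strain -- each with occurrence time (from the dense monitors)
#' and end-time value (from the final snapshot) -- plus displacement extrema
#' and extension ratios.
#'
#' @param runs A single `pfm_run` or a list of them.
#' @param height,length Model dimensions for the extension ratios, mm;
#'   defaults are taken from each run's geometry.
#' @return A `data.frame` of class `pfm_metrics`, one row per run.
#' @export
peak_report <- function(runs, height = NULL, length = NULL) {
  if (inherits(runs, "pfm_run")) runs <- list(runs)
  rows <- lapply(runs, function(run) {
    mon <- run$monitors
    if (is.null(mon) || !nrow(mon)) stop("input error: empty monitor series", call. = FALSE)
    final <- run$snapshots[[base::length(run$snapshots)]]
    if (is.null(final) || abs(final$time - run$config$duration) > 1e-9)
      stop("input error: final snapshot missing", call. = FALSE)
    h <- if (is.null(height)) run$params$height else height
    l <- if (is.null(length)) run$params$length else length
    ivm <- which.max(mon$vm_max)
    ips <- which.max(mon$ps_max)
    ipe <- which.max(mon$pe_max)
    iend <- nrow(mon)  # the final monitor sample coincides with t = duration
    ext <- displacement_extrema(run)
    ratios <- extension_ratios(ext$max_uZ, ext$uX_span, h, l)
    data.frame(
      bpd = run$sphere$diameter,
      max_eq_stress = mon$vm_max[ivm], t_eq_stress = mon$t[ivm],
      end_eq_stress = mon$vm_max[iend],
      max_p_stress = mon$ps_max[ips], t_p_stress = mon$t[ips],
      end_p_stress = mon$ps_max[iend],
      max_p_strain = mon$pe_max[ipe], t_p_strain = mon$t[ipe],
      end_p_strain = mon$pe_max[iend],
      max_uZ = ext$max_uZ, t_uZ = ext$t_uZ,
      uX_span = ext$uX_span, t_uX = ext$t_uX,
      ratio_Z_pct = unname(ratios["ratio_Z"]),
      ratio_X_pct = unname(ratios["ratio_X"])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pfm_metrics", "data.frame")
  out
}

#' Write a metrics report to CSV and/or JSON
#'
#' @param report A `pfm_metrics` data frame from [peak_report()].
#' @param csv,json Output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_metrics <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report, json, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  invisible(report)
}
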