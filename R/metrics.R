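# metrics: cell/region deformation metrics from a micro solution —
# volumetric strain, inertia-ellipsoid aspect ratios, effective (von Mises)
# stress/strain and maximum shear, volume-averaged over element sets.

#' Effective (von Mises) scalar of a symmetric tensor
#'
#' `sqrt(((p1-p2)^2 + (p2-p3)^2 + (p1-p3)^2) / 2)` with `p1 >= p2 >= p3` the
#' principal values. Non-negative; zero exactly for hydrostatic tensors.
#' Applied identically to Cauchy stress and Green-Lagrange strain.
#'
#' @param tensor 3 x 3 symmetric numeric matrix.
#' @return Scalar effective value.
#' @export
effective_scalar <- function(tensor) {
  p <- principal_values(tensor)
  sqrt(((p[1] - p[2])^2 + (p[2] - p[3])^2 + (p[1] - p[3])^2) / 2)
}

#' Maximum shear of a symmetric tensor
#'
#' `(p1 - p3) / 2`, half the spread of the principal values; the classical
#' tensorial maximum shear. Non-negative.
#'
#' @param tensor 3 x 3 symmetric numeric matrix.
#' @return Scalar maximum shear.
#' @export
max_shear <- function(tensor) {
  p <- principal_values(tensor)
  (p[1] - p[3]) / 2
}

principal_values <- function(tensor) {
  tensor <- matrix(as.numeric(tensor), 3, 3)
  if (max(abs(tensor - t(tensor))) > 1e-8 * max(1, max(abs(tensor))))
    stop("tensor must be symmetric")
  sort(eigen((tensor + t(tensor)) / 2, symmetric = TRUE,
             only.values = TRUE)$values, decreasing = TRUE)
}

# Analytic eigenvalues of many symmetric 3x3 tensors stored as m x 9
# row-major rows; returns m x 3 (descending). Vectorized Cardano form.
symeig3_rows <- function(S) {
  A11 <- S[, 1]; A12 <- (S[, 2] + S[, 4]) / 2; A13 <- (S[, 3] + S[, 7]) / 2
  A22 <- S[, 5]; A23 <- (S[, 6] + S[, 8]) / 2; A33 <- S[, 9]
  q <- (A11 + A22 + A33) / 3
  p1 <- A12^2 + A13^2 + A23^2
  p2 <- (A11 - q)^2 + (A22 - q)^2 + (A33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  e1 <- e2 <- e3 <- q
  nz <- p > 1e-300
  if (any(nz)) {
    B11 <- (A11[nz] - q[nz]) / p[nz]; B22 <- (A22[nz] - q[nz]) / p[nz]
    B33 <- (A33[nz] - q[nz]) / p[nz]
    B12 <- A12[nz] / p[nz]; B13 <- A13[nz] / p[nz]; B23 <- A23[nz] / p[nz]
    detB <- B11 * (B22 * B33 - B23^2) - B12 * (B12 * B33 - B23 * B13) +
      B13 * (B12 * B23 - B22 * B13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    e3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2[nz] <- 3 * q[nz] - e1[nz] - e3[nz]
  }
  cbind(e1, e2, e3, deparse.level = 0)
}

effective_scalar_rows <- function(S) {
  p <- symeig3_rows(S)
  sqrt(((p[, 1] - p[, 2])^2 + (p[, 2] - p[, 3])^2 + (p[, 1] - p[, 3])^2) / 2)
}

max_shear_rows <- function(S) {
  p <- symeig3_rows(S)
  (p[, 1] - p[, 3]) / 2
}

set_ids <- function(model, set) {
  ids <- model$mesh$sets[[set]]
  if (is.null(ids))
    stop("element set '", set, "' not found in the micro model")
  if (!length(ids)) stop("element set '", set, "' is empty")
  ids
}

# centroid-rule volumes and deformed centroids for a node configuration
set_centroids_volumes <- function(mesh, ids, nodes) {
  m <- length(ids)
  cent <- matrix(0, m, 3)
  vol <- numeric(m)
  for (r in seq_len(m)) {
    co <- nodes[mesh$elements[ids[r], ], , drop = FALSE]
    cent[r, ] <- colMeans(co)
    vol[r] <- hex_element_volume(co, "centroid", element = ids[r])
  }
  list(centroids = cent, volumes = vol)
}

#' Volumetric strain of an element set
#'
#' `(sum(V_deformed) - sum(V_undeformed)) / sum(V_undeformed)` with
#' centroid-rule element volumes in both configurations.
#'
#' @param solution A converged `micro_solution`.
#' @param set Element set name (e.g. `"Cell_1"`).
#' @return Scalar volumetric strain (negative in compression).
#' @export
volumetric_strain <- function(solution, set) {
  stopifnot(inherits(solution, "micro_solution"))
  ids <- set_ids(solution$model, set)
  v0 <- sum(solution$vol_ref[ids])
  v1 <- sum(solution$vol_def[ids])
  (v1 - v0) / v0
}

#' Unit-density moment-of-inertia tensor of an element set
#'
#' Assembled from element centroid positions and volumes about the set's
#' volume centroid, so it is invariant to rigid translation.
#'
#' @param centroids m x 3 matrix of element centroid positions.
#' @param volumes Length-m element volumes (the unit-density masses).
#' @return 3 x 3 symmetric inertia tensor.
#' @export
inertia_tensor <- function(centroids, volumes) {
  centroids <- as.matrix(centroids)
  if (!nrow(centroids)) stop("empty element set")
  m <- sum(volumes)
  cg <- colSums(centroids * volumes) / m
  r <- sweep(centroids, 2, cg)
  Ixx <- sum(volumes * (r[, 2]^2 + r[, 3]^2))
  Iyy <- sum(volumes * (r[, 1]^2 + r[, 3]^2))
  Izz <- sum(volumes * (r[, 1]^2 + r[, 2]^2))
  Ixy <- -sum(volumes * r[, 1] * r[, 2])
  Ixz <- -sum(volumes * r[, 1] * r[, 3])
  Iyz <- -sum(volumes * r[, 2] * r[, 3])
  matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3, 3)
}

#' Semi-axes of the ellipsoid of best fit
#'
#' Inverts the principal moments of a solid homogeneous ellipsoid: with
#' eigenvalues `l1 >= l2 >= l3` of the inertia tensor and total volume `m`
#' (unit density), `a^2 = 5 (l1 + l2 - l3) / (2 m)` and permutations.
#'
#' @param inertia 3 x 3 symmetric inertia tensor.
#' @param volume Total set volume (the unit-density mass).
#' @return Semi-axes sorted `a >= b >= c`.
#' @export
ellipsoid_axes <- function(inertia, volume) {
  l <- principal_values(inertia)
  if (any(l <= 0)) stop("inertia tensor must be positive definite")
  a2 <- 5 * (l[1] + l[2] - l[3]) / (2 * volume)
  b2 <- 5 * (l[1] - l[2] + l[3]) / (2 * volume)
  c2 <- 5 * (-l[1] + l[2] + l[3]) / (2 * volume)
  if (min(a2, b2, c2) <= 0)
    stop("infeasible principal moments: no real ellipsoid matches them")
  sort(sqrt(c(a2, b2, c2)), decreasing = TRUE)
}

#' Best-fit ellipsoid semi-axes of an element set
#'
#' @param mesh A [hex_mesh()].
#' @param ids Element indices of the set.
#' @param nodes Nodal positions of the configuration to measure (defaults to
#'   the mesh's undeformed nodes).
#' @return Semi-axes sorted `a >= b >= c`.
#' @export
set_shape_axes <- function(mesh, ids, nodes = mesh$nodes) {
  cv <- set_centroids_volumes(mesh, ids, nodes)
  ellipsoid_axes(inertia_tensor(cv$centroids, cv$volumes), sum(cv$volumes))
}

#' Aspect-ratio change of a cell set
#'
#' Fits a solid ellipsoid to the set in the undeformed and deformed
#' configurations and returns the change (deformed minus undeformed) of the
#' three axis ratios: major/minor, major/middle, middle/minor.
#'
#' @param solution A converged `micro_solution`.
#' @param set Element set name.
#' @return Named numeric vector `c(maj_min, maj_mid, mid_min)`.
#' @export
aspect_ratio_change <- function(solution, set) {
  stopifnot(inherits(solution, "micro_solution"))
  mesh <- solution$model$mesh
  ids <- set_ids(solution$model, set)
  ax0 <- set_shape_axes(mesh, ids)
  ax1 <- set_shape_axes(mesh, ids, mesh$nodes + solution$U)
  ar <- function(ax) c(maj_min = ax[[1]] / ax[[3]],
                       maj_mid = ax[[1]] / ax[[2]],
                       mid_min = ax[[2]] / ax[[3]])
  ar(ax1) - ar(ax0)
}

#' Volume-averaged metric over an element set
#'
#' `sum(V_def * metric) / sum(V_def)` with deformed element volumes as the
#' weights.
#'
#' @param solution A converged `micro_solution`.
#' @param set Element set name.
#' @param metric One of `"effective_strain"`, `"max_shear_strain"`,
#'   `"effective_stress"`, `"max_shear_stress"`, `"volume_ratio"`, or a
#'   numeric vector of per-element values (length = number of elements).
#' @return Scalar volume-averaged value.
#' @export
volume_averaged_metric <- function(solution, set, metric = "effective_strain") {
  stopifnot(inherits(solution, "micro_solution"))
  if (solution$status != "converged")
    stop("solution did not converge; no metrics available")
  ids <- set_ids(solution$model, set)
  vals <- if (is.numeric(metric)) {
    metric
  } else {
    switch(match.arg(metric, c("effective_strain", "max_shear_strain",
                               "effective_stress", "max_shear_stress",
                               "volume_ratio")),
           effective_strain = effective_scalar_rows(solution$E),
           max_shear_strain = max_shear_rows(solution$E),
           effective_stress = effective_scalar_rows(solution$sigma),
           max_shear_stress = max_shear_rows(solution$sigma),
           volume_ratio = solution$vol_def / solution$vol_ref)
  }
  w <- solution$vol_def[ids]
  sum(w * vals[ids]) / sum(w)
}

#' Full deformation-metric record of a micro solution
#'
#' One row per cell: aspect-ratio changes, volumetric strain, volume-averaged
#' effective strain, maximum shear strain and effective stress (MPa), plus
#' the PCM and ECM volume-averaged effective strain/stress repeated on every
#' row. Failed solutions give a single row of NAs with `status = "failed"`.
#'
#' @param solution A `micro_solution`.
#' @return A data.frame, one row per cell.
#' @export
micro_metrics <- function(solution) {
  stopifnot(inherits(solution, "micro_solution"))
  model <- solution$model
  ncell <- model$geometry$n
  if (solution$status != "converged") {
    return(data.frame(cell = if (ncell) seq_len(max(ncell, 1L)) else 1L,
                      dAR_maj_min = NA_real_, dAR_maj_mid = NA_real_,
                      dAR_mid_min = NA_real_, vol_strain = NA_real_,
                      eff_strain = NA_real_, max_shear = NA_real_,
                      eff_stress = NA_real_, pcm_eff_strain = NA_real_,
                      pcm_eff_stress = NA_real_, ecm_eff_strain = NA_real_,
                      ecm_eff_stress = NA_real_,
                      status = "failed")[seq_len(max(ncell, 1L)), ])
  }
  eff_E <- effective_scalar_rows(solution$E)
  shr_E <- max_shear_rows(solution$E)
  eff_S <- effective_scalar_rows(solution$sigma)
  region <- function(set, vals) {
    if (is.null(model$mesh$sets[[set]]) || !length(model$mesh$sets[[set]]))
      return(NA_real_)
    volume_averaged_metric(solution, set, vals)
  }
  pcm_eff <- region("PCM", eff_E); pcm_sig <- region("PCM", eff_S)
  ecm_eff <- region("ECM", eff_E); ecm_sig <- region("ECM", eff_S)
  rows <- lapply(seq_len(ncell), function(k) {
    set <- paste0("Cell_", k)
    dar <- aspect_ratio_change(solution, set)
    data.frame(cell = k,
               dAR_maj_min = dar[["maj_min"]], dAR_maj_mid = dar[["maj_mid"]],
               dAR_mid_min = dar[["mid_min"]],
               vol_strain = volumetric_strain(solution, set),
               eff_strain = volume_averaged_metric(solution, set, eff_E),
               max_shear = volume_averaged_metric(solution, set, shr_E),
               eff_stress = volume_averaged_metric(solution, set, eff_S),
               pcm_eff_strain = pcm_eff, pcm_eff_stress = pcm_sig,
               ecm_eff_strain = ecm_eff, ecm_eff_stress = ecm_sig,
               status = "converged")
  })
  do.call(rbind, rows)
}
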