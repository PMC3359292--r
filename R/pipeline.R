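# pipeline: macro -> micro batch orchestration, aggregation, and the
# summary analyses (through-origin regressions, quartiles, sensitivity).

#' Macro effective strain of a deformation gradient
#'
#' Effective (von Mises) scalar of the Green-Lagrange strain
#' `E = (F'F - I)/2` of a macro element's deformation gradient; the x-axis
#' of the macro-to-micro response regressions.
#'
#' @param F 3 x 3 deformation gradient.
#' @return Scalar effective strain.
#' @export
macro_effective_strain <- function(F) {
  F <- matrix(as.numeric(F), 3, 3)
  effective_scalar((crossprod(F) - diag(3)) / 2)
}

#' Solve one micro job for a given deformation gradient
#'
#' Applies affine boundary conditions for `F`, solves, and returns the
#' metric rows with provenance. Mechanical failure is contained: the rows
#' carry `status = "failed"` instead of raising.
#'
#' @param model A micro model with materials attached.
#' @param F 3 x 3 macro deformation gradient.
#' @param settings [solver_settings()].
#' @param element Macro element id recorded as provenance.
#' @return Metric rows (see [micro_metrics()]) with `element` and
#'   `macro_eff_strain` columns prepended.
#' @export
run_micro_job <- function(model, F, settings = solver_settings(),
                          element = NA_integer_) {
  rows <- tryCatch({
    bcs <- apply_boundary_conditions(model$mesh, F)
    sol <- solve_static(model, bcs, settings)
    df <- micro_metrics(sol)
    if (sol$status != "converged")
      df$status <- paste0("failed: ", sol$reason)
    df
  }, error = function(e) {
    df <- micro_metrics(structure(list(status = "failed", model = model),
                                  class = "micro_solution"))
    df$status <- paste0("failed: ", conditionMessage(e))
    df
  })
  cbind(data.frame(element = element,
                   macro_eff_strain = macro_effective_strain(F)),
        rows)
}

#' Run the macro-to-micro batch
#'
#' Extracts centroid deformation gradients for an element set, filters the
#' deforming elements, and solves one independent micro model per element on
#' a process pool. One fixed chondron geometry (and mesh) is shared by all
#' jobs. A failed job is recorded in the manifest and skipped; it never
#' aborts the batch, and the results table is identical for any worker
#' count.
#'
#' @param state A [macro_state()].
#' @param set_name Macro element set to process.
#' @param model A micro model with materials attached, or `NULL` to build
#'   one from `geometry`/`resolution`/`materials`.
#' @param geometry,resolution,materials Used when `model` is `NULL`:
#'   a [place_chondrons()] geometry (default single chondron), voxel
#'   resolution, and [material_table()].
#' @param settings [solver_settings()] shared by all jobs.
#' @param workers Process count (`parallel::mclapply`).
#' @param tol Deformation filter threshold (see
#'   [filter_deforming_elements()]).
#' @param manifest_path Optional path for a JSON job manifest.
#' @return A `batch_result`: list with `results` (metric rows of converged
#'   jobs), `manifest` (element, status, message), and counts.
#' @export
run_batch <- function(state, set_name = "all", model = NULL,
                      geometry = place_chondrons(1), resolution = 20L,
                      materials = material_table(),
                      settings = solver_settings(), workers = 1L,
                      tol = 1e-3, manifest_path = NULL) {
  stopifnot(inherits(state, "macro_state"), workers >= 1L)
  if (is.null(model))
    model <- assign_materials(build_micro_mesh(geometry, resolution),
                              materials)
  if (is.null(model$materials))
    stop("micro model has no materials; call assign_materials() first")
  tbl <- element_deformation_gradients(state, set_name, "centroid")
  tbl <- filter_deforming_elements(tbl, tol)
  njob <- length(tbl$element)
  jobs <- seq_len(njob)
  worker <- function(r) {
    run_micro_job(model, defgrad_tensor(tbl, r), settings,
                  element = tbl$element[r])
  }
  out <- if (workers > 1L) {
    parallel::mclapply(jobs, worker, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(jobs, worker)
  }
  rows <- do.call(rbind, out)
  failed <- startsWith(rows$status, "failed")
  manifest <- do.call(rbind, lapply(out, function(df) {
    data.frame(element = df$element[1],
               status = if (any(startsWith(df$status, "failed")))
                 "failed" else "converged",
               message = sub("^failed:? ?", "", df$status[1]))
  }))
  if (!is.null(manifest_path))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  structure(list(results = rows[!failed, , drop = FALSE],
                 manifest = manifest,
                 n_jobs = njob, n_failed = sum(manifest$status == "failed")),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat("batch_result:", x$n_jobs, "job(s),", x$n_failed, "failed\n")
  cat("  results:", nrow(x$results), "cell row(s)\n")
  invisible(x)
}

#' Least-squares regression through the origin
#'
#' Fits `y = slope * x` with no intercept: `slope = sum(x y) / sum(x^2)`,
#' `SSR = sum((y - slope x)^2)`.
#'
#' @param x,y Numeric vectors of equal length (`n >= 1`).
#' @return A `regression_result`: list with `slope`, `ssr`, `n`.
#' @export
regress_through_origin <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (all(x == 0)) stop("cannot regress through the origin: all x are zero")
  slope <- sum(x * y) / sum(x * x)
  structure(list(slope = slope, ssr = sum((y - slope * x)^2),
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("through-origin regression: slope = %.4f, SSR = %.4g (n = %d)\n",
              x$slope, x$ssr, x$n))
  invisible(x)
}

#' Per-cell through-origin regressions of a batch results table
#'
#' Regresses a micro metric against the macro effective strain separately
#' for every cell id and summarizes the slopes.
#'
#' @param results A batch results data.frame (needs columns
#'   `macro_eff_strain`, `cell`, and the metric).
#' @param metric Results column to regress (default `"dAR_maj_min"`).
#' @return List with `per_cell` (cell, slope, ssr, n) and `summary`
#'   (min/avg/max slope).
#' @export
per_cell_regressions <- function(results, metric = "dAR_maj_min") {
  stopifnot(metric %in% names(results))
  cells <- sort(unique(results$cell))
  rows <- lapply(cells, function(k) {
    d <- results[results$cell == k & is.finite(results[[metric]]), ]
    if (!nrow(d)) {
      warning("cell ", k, " has no finite data; excluded")
      return(NULL)
    }
    r <- regress_through_origin(d$macro_eff_strain, d[[metric]])
    data.frame(cell = k, slope = r$slope, ssr = r$ssr, n = r$n)
  })
  per_cell <- do.call(rbind, rows)
  list(per_cell = per_cell,
       summary = c(min = min(per_cell$slope), avg = mean(per_cell$slope),
                   max = max(per_cell$slope)))
}

#' Five-number quartile summary
#'
#' Minimum, first quartile, median, third quartile and maximum, with
#' quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param values Numeric vector (`n >= 1`).
#' @return Named numeric vector `c(min, q1, median, q3, max)`.
#' @export
quartile_summary <- function(values) {
  stopifnot(length(values) >= 1, is.numeric(values))
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

#' Material sensitivity study
#'
#' Solves the same micro geometry under one volume-preserving compressive
#' deformation gradient for several material tables (by default: the study
#' table, the study table scaled by 10, and the study table with PCM
#' stiffness divided by 10) and reports, per case, the quartile summary of
#' the per-cell ratio of cell to ECM volume-averaged effective strain.
#'
#' @param geometry A [place_chondrons()] geometry (the 11-chondron construct
#'   in the reference protocol).
#' @param resolution Voxel resolution of the shared mesh.
#' @param F Driving deformation gradient; default 10% nominal compression
#'   with volume-preserving lateral expansion. An identity (or
#'   non-deforming) `F` is rejected, since strain ratios are undefined.
#' @param cases Named list of [material_table()]s.
#' @param settings [solver_settings()].
#' @return List with `quartiles` (named list of quartile summaries),
#'   `ratios` (per-case per-cell ratio vectors), and `mean_cell_eff_strain`
#'   (named vector).
#' @export
sensitivity_study <- function(geometry = place_chondrons(11, seed = 7L),
                              resolution = 30L,
                              F = diag(c(0.9^-0.5, 0.9^-0.5, 0.9)),
                              cases = list(
                                reference = material_table(),
                                scaled_x10 = scale_material_table(
                                  material_table(), 10),
                                pcm_div10 = reduce_pcm_stiffness(
                                  material_table(), 10)),
                              settings = solver_settings(n_steps = 2L)) {
  F <- matrix(as.numeric(F), 3, 3)
  if (max(abs(F - diag(3))) < 1e-12)
    stop("identity deformation gradient: strain ratios are undefined")
  base <- build_micro_mesh(geometry, resolution)
  ratios <- list(); mean_cell <- numeric(0)
  for (nm in names(cases)) {
    model <- assign_materials(base, cases[[nm]])
    bcs <- apply_boundary_conditions(model$mesh, F)
    sol <- solve_static(model, bcs, settings)
    if (sol$status != "converged")
      stop("sensitivity case '", nm, "' failed to converge: ", sol$reason)
    eff <- effective_scalar_rows(sol$E)
    ecm <- volume_averaged_metric(sol, "ECM", eff)
    rk <- vapply(seq_len(geometry$n), function(k)
      volume_averaged_metric(sol, paste0("Cell_", k), eff) / ecm, 0)
    ratios[[nm]] <- rk
    mean_cell[nm] <- mean(vapply(seq_len(geometry$n), function(k)
      volume_averaged_metric(sol, paste0("Cell_", k), eff), 0))
  }
  list(quartiles = lapply(ratios, quartile_summary), ratios = ratios,
       mean_cell_eff_strain = mean_cell)
}

#' Export a per-element metric as a VTK fringe plot
#'
#' Writes the macro mesh with a CELL_DATA scalar array holding the metric
#' for computed elements and `nan` as the sentinel for elements without a
#' value (their count is reported in a message).
#'
#' @param state A [macro_state()].
#' @param elements Macro element indices carrying values.
#' @param values Numeric vector aligned with `elements`.
#' @param file Output `.vtk` path.
#' @param name Array name.
#' @return `file`, invisibly.
#' @export
export_fringe <- function(state, elements, values, file, name = "metric") {
  stopifnot(inherits(state, "macro_state"), length(elements) == length(values))
  m <- nrow(state$mesh$elements)
  col <- rep(NaN, m)
  col[elements] <- values
  n_missing <- sum(is.nan(col))
  if (n_missing)
    message(n_missing, " element(s) without a computed value written as nan")
  cs <- list(); cs[[name]] <- col
  write_vtk(state$mesh, file,
            point_vectors = list(displacement = state$deformed -
                                   state$undeformed),
            cell_scalars = cs)
}

#' Write batch results to CSV
#'
#' One row per cell per converged micro model; schema is the column set of
#' [micro_metrics()] plus `element` and `macro_eff_strain`.
#'
#' @param batch A `batch_result`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_results_csv <- function(batch, file) {
  stopifnot(inherits(batch, "batch_result"))
  utils::write.csv(batch$results, file, row.names = FALSE)
  invisible(file)
}
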