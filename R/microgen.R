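# microgen: chondron-in-ECM micro geometries and labelled voxel hex meshes.
# Micro coordinates are in micrometres (um).

#' Place chondrons in an ECM block
#'
#' Generates `n` chondron centers (chondrocyte sphere of `cell_radius` plus a
#' concentric PCM shell of `pcm_thickness`) inside a cubic ECM block. A single
#' chondron is placed at the block centroid; multiple chondrons are placed by
#' rejection sampling under two constraints: chondron surfaces are separated
#' pairwise by at least `min_separation`, and every chondron surface stays at
#' least `boundary_margin` from the block boundary. Both default to the PCM
#' thickness.
#'
#' @param n Number of chondrons (>= 0).
#' @param block Edge length of the cubic ECM block (um).
#' @param cell_radius Chondrocyte radius (um).
#' @param pcm_thickness PCM shell thickness (um).
#' @param min_separation Minimum surface-to-surface separation (um).
#' @param boundary_margin Minimum surface-to-boundary distance (um).
#' @param seed Integer seed making the placement reproducible.
#' @param max_attempts Rejection samples allowed per chondron before the
#'   packing is declared infeasible.
#' @return An object of class `chondron_geometry`.
#' @export
place_chondrons <- function(n, block = 100, cell_radius = 7.5,
                            pcm_thickness = 3.3,
                            min_separation = pcm_thickness,
                            boundary_margin = pcm_thickness,
                            seed = 1L, max_attempts = 10000L) {
  stopifnot(n >= 0, block > 0, cell_radius > 0, pcm_thickness >= 0,
            min_separation >= 0, boundary_margin >= 0)
  R <- cell_radius + pcm_thickness  # chondron radius
  lo <- R + boundary_margin
  hi <- block - R - boundary_margin
  if (n > 0 && hi <= lo)
    stop(packing_error("chondron radius plus margin exceeds the block"))
  centers <- matrix(numeric(0), 0, 3)
  if (n == 1) {
    centers <- matrix(block / 2, 1, 3)
  } else if (n > 1) {
    dmin <- 2 * R + min_separation
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(as.integer(seed))
    centers <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- stats::runif(3, lo, hi)
        ok <- if (k == 1) TRUE else {
          d2 <- rowSums((centers[seq_len(k - 1), , drop = FALSE] -
                           matrix(p, k - 1, 3, byrow = TRUE))^2)
          all(d2 >= dmin^2)
        }
        if (ok) { centers[k, ] <- p; placed <- TRUE; break }
      }
      if (!placed)
        stop(packing_error(sprintf(
          "could not place chondron %d of %d after %d attempts", k, n,
          max_attempts)))
    }
  }
  structure(list(n = as.integer(n), block = block, cell_radius = cell_radius,
                 pcm_thickness = pcm_thickness,
                 min_separation = min_separation,
                 boundary_margin = boundary_margin,
                 centers = centers, seed = as.integer(seed)),
            class = "chondron_geometry")
}

packing_error <- function(msg) {
  structure(class = c("cellscale_packing_infeasible", "error", "condition"),
            list(message = paste0("packing infeasible: ", msg), call = NULL))
}

#' @export
print.chondron_geometry <- function(x, ...) {
  cat("chondron_geometry:", x$n, "chondron(s) in a", x$block, "um block\n")
  cat("  cell radius", x$cell_radius, "um, PCM thickness", x$pcm_thickness,
      "um, seed", x$seed, "\n")
  cat("  analytic ECM volume fraction:",
      sprintf("%.4f", ecm_volume_fraction(x)), "\n")
  invisible(x)
}

#' Analytic ECM volume fraction of a chondron geometry
#'
#' Chondron spheres are non-overlapping by construction, so the ECM fraction
#' is `1 - n (4/3) pi (cell_radius + pcm_thickness)^3 / block^3`.
#'
#' @param g A [place_chondrons()] geometry.
#' @return Fraction of the block volume occupied by ECM, in `[0, 1]`.
#' @export
ecm_volume_fraction <- function(g) {
  stopifnot(inherits(g, "chondron_geometry"))
  R <- g$cell_radius + g$pcm_thickness
  1 - g$n * (4 / 3) * pi * R^3 / g$block^3
}

#' Voxel-mesh a chondron geometry into a labelled micro model
#'
#' Discretizes the block with a structured `r x r x r` grid of hexahedra and
#' labels each element by the region membership of its centroid: inside a
#' chondrocyte sphere -> `Cell`, inside a chondron sphere but outside the
#' cell -> `PCM`, else `ECM`. Labelled volumes converge to the analytic
#' sphere/shell volumes as `r` grows (first order in `1/r`).
#'
#' @param g A [place_chondrons()] geometry.
#' @param resolution Elements per edge (`r >= 10`).
#' @return An object of class `micro_model`: mesh, per-element `region`
#'   factor, per-element `cell_id` (0 = not a cell element), geometry, and
#'   empty material/provenance slots. Element sets `ECM`, `PCM`, `Cell` and
#'   `Cell_k` are registered on the mesh.
#' @export
build_micro_mesh <- function(g, resolution = 30L) {
  stopifnot(inherits(g, "chondron_geometry"))
  r <- as.integer(resolution)
  if (r < 10L) stop("`resolution` must be at least 10 elements per edge")
  mesh <- structured_hex_mesh(r, r, r, lower = c(0, 0, 0),
                              upper = rep(g$block, 3))
  h <- g$block / r
  ctr <- expand.grid(x = (seq_len(r) - 0.5) * h,
                     y = (seq_len(r) - 0.5) * h,
                     z = (seq_len(r) - 0.5) * h)
  ctr <- as.matrix(ctr)
  m <- nrow(ctr)
  region <- rep("ECM", m)
  cell_id <- integer(m)
  Rch <- g$cell_radius + g$pcm_thickness
  if (g$n > 0) {
    for (k in seq_len(g$n)) {
      d2 <- rowSums((ctr - matrix(g$centers[k, ], m, 3, byrow = TRUE))^2)
      in_cell <- d2 <= g$cell_radius^2
      in_chon <- d2 <= Rch^2
      region[in_chon & !in_cell] <- "PCM"
      region[in_cell] <- "Cell"
      cell_id[in_cell] <- k
    }
  }
  region <- factor(region, levels = c("ECM", "PCM", "Cell"))
  if (g$n > 0) {
    empty <- setdiff(seq_len(g$n), unique(cell_id[cell_id > 0]))
    if (length(empty))
      warning("resolution ", r, " leaves chondron(s) ",
              paste(empty, collapse = ", "),
              " with no Cell elements; increase `resolution`")
  }
  sets <- list(ECM = which(region == "ECM"),
               PCM = which(region == "PCM"),
               Cell = which(region == "Cell"))
  for (k in seq_len(g$n))
    sets[[paste0("Cell_", k)]] <- which(cell_id == k)
  mesh$sets <- c(mesh$sets, sets)
  structure(list(mesh = mesh, region = region, cell_id = cell_id,
                 geometry = g, resolution = r, materials = NULL,
                 provenance = list()),
            class = "micro_model")
}

#' @export
print.micro_model <- function(x, ...) {
  cat("micro_model:", x$resolution, "^3 voxel hexahedra,",
      x$geometry$n, "chondron(s)\n")
  cat("  elements: ", sum(x$region == "ECM"), " ECM, ",
      sum(x$region == "PCM"), " PCM, ", sum(x$region == "Cell"),
      " Cell\n", sep = "")
  if (!is.null(x$materials)) {
    cat("  materials attached (c1 MPa): ",
        paste(sprintf("%s %.4g", rownames(x$materials), x$materials$c1),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Attach a material table to a micro model
#'
#' @param model A [build_micro_mesh()] model.
#' @param table A [material_table()] covering every region present.
#' @return The model with materials attached.
#' @export
assign_materials <- function(model, table = material_table()) {
  stopifnot(inherits(model, "micro_model"), inherits(table, "material_table"))
  present <- unique(as.character(model$region))
  missing <- setdiff(present, rownames(table))
  if (length(missing))
    stop("material table lacks region(s): ", paste(missing, collapse = ", "))
  model$materials <- table
  model
}

#' Labelled region volumes of a micro model
#'
#' Sums voxel element volumes per region label (exact for the regular grid:
#' every voxel has volume `(block/r)^3`).
#'
#' @param model A `micro_model`.
#' @return Named numeric vector of ECM/PCM/Cell volumes (um^3).
#' @export
region_volumes <- function(model) {
  stopifnot(inherits(model, "micro_model"))
  h3 <- (model$geometry$block / model$resolution)^3
  tapply(rep(h3, length(model$region)), model$region, sum, default = 0)
}

#' Write / read a chondron geometry as JSON
#'
#' @param g A `chondron_geometry`.
#' @param file JSON path.
#' @return `file` invisibly, or the geometry for the reader.
#' @export
write_geometry_json <- function(g, file) {
  stopifnot(inherits(g, "chondron_geometry"))
  jsonlite::write_json(unclass(g), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_geometry_json
#' @param file JSON path written by [write_geometry_json()].
#' @export
read_geometry_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  centers <- matrix(as.numeric(x$centers), ncol = 3)
  structure(list(n = as.integer(x$n), block = x$block,
                 cell_radius = x$cell_radius, pcm_thickness = x$pcm_thickness,
                 min_separation = x$min_separation,
                 boundary_margin = x$boundary_margin,
                 centers = centers, seed = as.integer(x$seed)),
            class = "chondron_geometry")
}
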