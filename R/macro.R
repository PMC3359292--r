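# macro_io: reading a macro-scale solution and extracting per-element
# deformation gradients. Macro coordinates are in mm; the deformation gradient
# is dimensionless, so nothing unit-bearing crosses to the micro scale (um).

#' Construct a macro-scale solution state
#'
#' Bundles a hexahedral mesh with undeformed and deformed nodal positions.
#'
#' @param mesh A [hex_mesh()]; its `nodes` are the undeformed positions (mm).
#' @param deformed n x 3 matrix of deformed nodal positions (mm), or `NULL`
#'   if `displacement` is given.
#' @param displacement Optional n x 3 displacement matrix; deformed positions
#'   are then `mesh$nodes + displacement`.
#' @return An object of class `macro_state`.
#' @export
macro_state <- function(mesh, deformed = NULL, displacement = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  if (is.null(deformed)) {
    if (is.null(displacement))
      stop("either `deformed` or `displacement` must be supplied")
    displacement <- as.matrix(displacement)
    if (!identical(dim(displacement), dim(mesh$nodes)))
      stop("displacement array is not congruent with the mesh (",
           nrow(mesh$nodes), " nodes expected)")
    deformed <- mesh$nodes + displacement
  }
  deformed <- as.matrix(deformed)
  storage.mode(deformed) <- "double"
  if (!identical(dim(deformed), dim(mesh$nodes)))
    stop("deformed positions are not congruent with the mesh (",
         nrow(mesh$nodes), " nodes expected)")
  structure(list(mesh = mesh, undeformed = mesh$nodes, deformed = deformed),
            class = "macro_state")
}

#' @export
print.macro_state <- function(x, ...) {
  cat("macro_state:", nrow(x$mesh$nodes), "nodes,",
      nrow(x$mesh$elements), "hexahedra\n")
  umax <- max(abs(x$deformed - x$undeformed))
  cat("  max |displacement| component:", signif(umax, 4), "\n")
  invisible(x)
}

#' Read a macro-scale solution from VTK or CSV sources
#'
#' `mesh_source` is either the path of a legacy ASCII VTK unstructured grid
#' (hexahedra only) or a list `list(nodes = , elements = )` of CSV paths
#' (`id,x,y,z` and `id,n0..n7[,set]`, 0-based indices). The deformed state
#' comes from, in order of precedence: `deformed_source` (a CSV of deformed
#' positions `id,x,y,z` or of displacements `id,ux,uy,uz`, or a second VTK
#' whose points are the deformed positions), or a `displacement` POINT_DATA
#' vector field in the mesh VTK itself.
#'
#' @param mesh_source VTK path or `list(nodes=, elements=)` CSV paths.
#' @param deformed_source Optional path as described above.
#' @param quiet Suppress the node/element count message.
#' @return A [macro_state()].
#' @export
read_macro_state <- function(mesh_source, deformed_source = NULL, quiet = FALSE) {
  pv <- list()
  if (is.character(mesh_source) && length(mesh_source) == 1L) {
    vtk <- read_vtk(mesh_source)
    mesh <- vtk$mesh
    pv <- vtk$point_vectors
  } else if (is.list(mesh_source) &&
             all(c("nodes", "elements") %in% names(mesh_source))) {
    nodes <- read_nodes_csv(mesh_source$nodes)
    el <- read_elements_csv(mesh_source$elements, nrow(nodes))
    mesh <- hex_mesh(nodes, el$elements, el$sets)
  } else {
    stop("`mesh_source` must be a VTK path or list(nodes=, elements=) of CSV paths")
  }
  deformed <- NULL; displacement <- NULL
  if (!is.null(deformed_source)) {
    if (grepl("\\.vtk$", deformed_source, ignore.case = TRUE)) {
      deformed <- read_vtk(deformed_source)$mesh$nodes
    } else {
      df <- utils::read.csv(deformed_source)
      df <- df[order(df$id), ]
      if (all(c("x", "y", "z") %in% names(df))) {
        deformed <- as.matrix(df[, c("x", "y", "z")])
      } else if (all(c("ux", "uy", "uz") %in% names(df))) {
        displacement <- as.matrix(df[, c("ux", "uy", "uz")])
      } else {
        stop(deformed_source, " must have columns x,y,z or ux,uy,uz")
      }
    }
  } else if (!is.null(pv[["displacement"]])) {
    displacement <- pv[["displacement"]]
  } else {
    stop("no deformed state: supply `deformed_source` or a 'displacement' ",
         "point vector in the mesh VTK")
  }
  st <- macro_state(mesh, deformed = deformed, displacement = displacement)
  if (!quiet)
    message("macro state: ", nrow(mesh$nodes), " nodes, ",
            nrow(mesh$elements), " hexahedra, ",
            length(mesh$sets), " element set(s)")
  st
}

#' Per-element deformation gradients of a macro state
#'
#' Extracts `F` for every element of a named set, sampling either once at the
#' element centroid or at the eight 2x2x2 Gauss points. Each record carries
#' the maximum componentwise deviation of its tensor(s) from the identity,
#' used by [filter_deforming_elements()].
#'
#' @param state A [macro_state()].
#' @param set_name Element set to process (default `"all"`).
#' @param scheme `"centroid"` or `"gauss8"`.
#' @return An object of class `defgrad_table`: a list with `element`
#'   (indices), `scheme`, `F` (array `n_el x n_points x 3 x 3`), and
#'   `deviation` (max over sampled points and components of `|F - I|`).
#' @export
element_deformation_gradients <- function(state, set_name = "all",
                                          scheme = c("centroid", "gauss8")) {
  stopifnot(inherits(state, "macro_state"))
  scheme <- match.arg(scheme)
  mesh <- state$mesh
  ids <- mesh$sets[[set_name]]
  if (is.null(ids))
    stop("element set '", set_name, "' not found; available: ",
         paste(names(mesh$sets), collapse = ", "))
  pts <- if (scheme == "centroid") matrix(0, 1, 3) else hex_gauss_points()
  npts <- nrow(pts)
  Fs <- array(NA_real_, c(length(ids), npts, 3, 3))
  dev <- numeric(length(ids))
  I3 <- diag(3)
  for (r in seq_along(ids)) {
    e <- ids[r]
    X <- element_coords(mesh, e, state$undeformed)
    x <- element_coords(mesh, e, state$deformed)
    dmax <- 0
    for (k in seq_len(npts)) {
      Fk <- hex_deformation_gradient(X, x, pts[k, ], element = e)
      Fs[r, k, , ] <- Fk
      dmax <- max(dmax, max(abs(Fk - I3)))
    }
    dev[r] <- dmax
  }
  structure(list(element = ids, scheme = scheme, F = Fs, deviation = dev),
            class = "defgrad_table")
}

#' @export
print.defgrad_table <- function(x, ...) {
  cat("defgrad_table:", length(x$element), "elements, scheme =", x$scheme, "\n")
  if (length(x$deviation))
    cat("  deviation from identity: ",
        signif(min(x$deviation), 4), " .. ", signif(max(x$deviation), 4), "\n",
        sep = "")
  invisible(x)
}

#' Extract one tensor from a deformation-gradient table
#'
#' @param tbl A `defgrad_table`.
#' @param r Record (row) index.
#' @param k Sampling-point index (1 for centroid scheme).
#' @return A 3 x 3 matrix.
#' @export
defgrad_tensor <- function(tbl, r, k = 1L) {
  matrix(tbl$F[r, k, , ], 3, 3)
}

#' Keep records of elements that actually deform
#'
#' Retains records whose deformation gradient differs from the identity by
#' more than `tol` in any component (at any sampled point). Elements below
#' the threshold carry no mechanically meaningful strain and no micro model
#' is generated for them.
#'
#' @param tbl A `defgrad_table`.
#' @param tol Componentwise threshold (> 0); default `1e-3`.
#' @return A filtered `defgrad_table`.
#' @export
filter_deforming_elements <- function(tbl, tol = 1e-3) {
  stopifnot(inherits(tbl, "defgrad_table"), is.numeric(tol), tol > 0)
  keep <- tbl$deviation > tol
  structure(list(element = tbl$element[keep], scheme = tbl$scheme,
                 F = tbl$F[keep, , , , drop = FALSE],
                 deviation = tbl$deviation[keep]),
            class = "defgrad_table")
}

#' Within-element deformation-gradient variation residual
#'
#' For Gauss-point sampled records, characterizes how non-uniform `F` is over
#' each element: for every one of the 28 unique pairs of the 8 tensors, the
#' componentwise absolute differences are summed, and the largest pair sum is
#' the element's residual. Identical tensors give 0.
#'
#' @param tbl A `defgrad_table` with `scheme = "gauss8"`.
#' @return Numeric vector of residuals, one per record.
#' @export
variation_residual <- function(tbl) {
  stopifnot(inherits(tbl, "defgrad_table"))
  if (tbl$scheme != "gauss8")
    stop("variation_residual requires gauss8-sampled deformation gradients")
  n <- length(tbl$element)
  res <- numeric(n)
  for (r in seq_len(n)) {
    best <- 0
    for (a in 1:7) for (b in (a + 1):8) {
      s <- sum(abs(tbl$F[r, a, , ] - tbl$F[r, b, , ]))
      if (s > best) best <- s
    }
    res[r] <- best
  }
  res
}

#' Write a deformation-gradient table to CSV
#'
#' One row per element and sampling point: element id, point index, the nine
#' tensor components `F11..F33` (row-major), and the element's deviation from
#' identity.
#'
#' @param tbl A `defgrad_table`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_defgrad_csv <- function(tbl, file) {
  npts <- dim(tbl$F)[2]
  rows <- do.call(rbind, lapply(seq_along(tbl$element), function(r) {
    do.call(rbind, lapply(seq_len(npts), function(k) {
      Fk <- t(matrix(tbl$F[r, k, , ], 3, 3))  # row-major flatten
      data.frame(element = tbl$element[r], point = k,
                 t(as.vector(Fk)), deviation = tbl$deviation[r])
    }))
  }))
  names(rows)[3:11] <- c("F11", "F12", "F13", "F21", "F22", "F23",
                         "F31", "F32", "F33")
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
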