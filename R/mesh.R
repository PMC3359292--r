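#' Construct a hexahedral mesh
#'
#' A `hex_mesh` stores nodal positions, 8-node hexahedral connectivity in the
#' standard node ordering, and named element sets.
#'
#' @param nodes n x 3 numeric matrix of nodal positions.
#' @param elements m x 8 integer matrix of 1-based node indices.
#' @param sets Named list of integer vectors of 1-based element indices.
#'   A set named `"all"` covering every element is added if absent.
#' @return An object of class `hex_mesh`.
#' @export
hex_mesh <- function(nodes, elements, sets = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(nodes) != 3L) stop("`nodes` must have 3 columns")
  if (ncol(elements) != 8L) stop("`elements` must have 8 columns (hexahedra only)")
  if (anyNA(nodes) || anyNA(elements)) stop("mesh arrays must not contain NA")
  if (nrow(elements) > 0 &&
      (min(elements) < 1L || max(elements) > nrow(nodes)))
    stop("element connectivity references nodes outside 1..", nrow(nodes))
  if (!is.list(sets)) stop("`sets` must be a named list of element index vectors")
  sets <- lapply(sets, function(s) {
    s <- as.integer(s)
    if (length(s) && (min(s) < 1L || max(s) > nrow(elements)))
      stop("element set references elements outside 1..", nrow(elements))
    s
  })
  if (is.null(sets[["all"]])) sets[["all"]] <- seq_len(nrow(elements))
  structure(list(nodes = nodes, elements = elements, sets = sets),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat("hex_mesh:", nrow(x$nodes), "nodes,", nrow(x$elements), "hexahedra\n")
  cat("  sets:", paste(sprintf("%s (%d)", names(x$sets),
                               lengths(x$sets)), collapse = ", "), "\n")
  invisible(x)
}

#' Nodal coordinates of one element
#'
#' @param mesh A `hex_mesh`.
#' @param e Element index.
#' @param nodes Optional alternative nodal position matrix (e.g. deformed
#'   positions) congruent with the mesh.
#' @return 8 x 3 matrix of positions.
#' @export
element_coords <- function(mesh, e, nodes = mesh$nodes) {
  nodes[mesh$elements[e, ], , drop = FALSE]
}

#' Structured hexahedral grid over a box
#'
#' Builds an `nx x ny x nz` grid of hexahedra over an axis-aligned box with
#' standard node ordering.
#'
#' @param nx,ny,nz Number of elements per direction.
#' @param lower,upper Box corners (length-3 numeric).
#' @return A `hex_mesh`.
#' @export
structured_hex_mesh <- function(nx, ny, nz = nx,
                                lower = c(0, 0, 0), upper = c(1, 1, 1)) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  stopifnot(nx >= 1L, ny >= 1L, nz >= 1L, all(upper > lower))
  xs <- seq(lower[1], upper[1], length.out = nx + 1L)
  ys <- seq(lower[2], upper[2], length.out = ny + 1L)
  zs <- seq(lower[3], upper[3], length.out = nz + 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (nx + 1L) * (j + (ny + 1L) * k) + 1L
  idx <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  i <- idx$i; j <- idx$j; k <- idx$k
  elements <- cbind(nid(i,     j,     k),
                    nid(i + 1, j,     k),
                    nid(i + 1, j + 1, k),
                    nid(i,     j + 1, k),
                    nid(i,     j,     k + 1),
                    nid(i + 1, j,     k + 1),
                    nid(i + 1, j + 1, k + 1),
                    nid(i,     j + 1, k + 1))
  hex_mesh(nodes, elements)
}

# ---- VTK legacy (ASCII) unstructured grid I/O -------------------------------
# Minimal codec for the subset of the legacy format the pipeline exchanges:
# POINTS, CELLS/CELL_TYPES (hexahedra, VTK type 12 only), POINT_DATA VECTORS,
# and named CELL_DATA SCALARS.

#' Write a mesh to a legacy ASCII VTK unstructured grid
#'
#' @param mesh A `hex_mesh`.
#' @param file Output path.
#' @param point_vectors Named list of n x 3 matrices written as POINT_DATA
#'   VECTORS (e.g. `list(displacement = u)`).
#' @param cell_scalars Named list of length-m numeric vectors written as
#'   CELL_DATA SCALARS. Non-finite values are written as `nan`.
#' @param title Dataset title line.
#' @return `file`, invisibly.
#' @export
write_vtk <- function(mesh, file, point_vectors = list(), cell_scalars = list(),
                      title = "cellscale mesh") {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(apply(format(mesh$nodes, digits = 17, scientific = TRUE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(paste("CELLS", m, 9L * m), con)
  conn <- cbind(8L, mesh$elements - 1L)
  writeLines(apply(conn, 1, paste, collapse = " "), con)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(as.character(rep(12L, m)), con)
  if (length(point_vectors)) {
    writeLines(paste("POINT_DATA", n), con)
    for (nm in names(point_vectors)) {
      v <- point_vectors[[nm]]
      stopifnot(is.matrix(v), nrow(v) == n, ncol(v) == 3L)
      writeLines(paste("VECTORS", nm, "double"), con)
      writeLines(apply(format(v, digits = 17, scientific = TRUE, trim = TRUE),
                       1, paste, collapse = " "), con)
    }
  }
  if (length(cell_scalars)) {
    writeLines(paste("CELL_DATA", m), con)
    for (nm in names(cell_scalars)) {
      v <- as.numeric(cell_scalars[[nm]])
      stopifnot(length(v) == m)
      vs <- format(v, digits = 17, scientific = TRUE, trim = TRUE)
      vs[!is.finite(v)] <- "nan"
      writeLines(c(paste("SCALARS", nm, "double", "1"),
                   "LOOKUP_TABLE default", vs), con)
    }
  }
  invisible(file)
}

#' Read a legacy ASCII VTK unstructured grid of hexahedra
#'
#' Supports POINTS, CELLS, CELL_TYPES (all cells must be type 12), POINT_DATA
#' VECTORS and CELL_DATA SCALARS arrays.
#'
#' @param file Path to a legacy ASCII `.vtk` file.
#' @return A list with `mesh` (a [hex_mesh()]), `point_vectors` and
#'   `cell_scalars` (named lists, possibly empty).
#' @export
read_vtk <- function(file) {
  lines <- readLines(file, warn = FALSE)
  toks_of <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1]]
  # flatten all numeric tokens following a header line until count satisfied
  scan_block <- function(start, count) {
    vals <- numeric(0); i <- start
    while (length(vals) < count && i <= length(lines)) {
      tk <- toks_of(lines[i])
      if (length(tk)) vals <- c(vals, suppressWarnings(as.numeric(tk)))
      i <- i + 1L
    }
    if (length(vals) < count) stop("truncated VTK block at line ", start)
    list(vals = vals[seq_len(count)], next_line = i)
  }
  hdr <- grep("^DATASET", lines, value = TRUE)
  if (!length(hdr) || !grepl("UNSTRUCTURED_GRID", hdr[1]))
    stop("not a legacy VTK unstructured grid: ", file)
  nodes <- NULL; elements <- NULL; m <- 0L
  point_vectors <- list(); cell_scalars <- list()
  i <- 1L
  while (i <= length(lines)) {
    tk <- toks_of(lines[i])
    if (!length(tk)) { i <- i + 1L; next }
    key <- toupper(tk[1])
    if (key == "POINTS") {
      n <- as.integer(tk[2])
      b <- scan_block(i + 1L, 3L * n)
      nodes <- matrix(b$vals, ncol = 3, byrow = TRUE)
      i <- b$next_line
    } else if (key == "CELLS") {
      m <- as.integer(tk[2])
      b <- scan_block(i + 1L, as.integer(tk[3]))
      vals <- b$vals; elements <- matrix(NA_integer_, m, 8); pos <- 1L
      for (e in seq_len(m)) {
        npts <- as.integer(vals[pos])
        if (npts != 8L)
          stop("unsupported cell with ", npts, " nodes in ", file,
               " (only 8-node hexahedra are supported)")
        elements[e, ] <- as.integer(vals[pos + 1:8]) + 1L
        pos <- pos + npts + 1L
      }
      i <- b$next_line
    } else if (key == "CELL_TYPES") {
      b <- scan_block(i + 1L, as.integer(tk[2]))
      bad <- unique(b$vals[b$vals != 12])
      if (length(bad))
        stop("unsupported VTK cell type(s) ", paste(bad, collapse = ", "),
             " in ", file, " (only hexahedra, type 12, are supported)")
      i <- b$next_line
    } else if (key == "VECTORS") {
      b <- scan_block(i + 1L, 3L * nrow(nodes))
      point_vectors[[tk[2]]] <- matrix(b$vals, ncol = 3, byrow = TRUE)
      i <- b$next_line
    } else if (key == "SCALARS") {
      i <- i + 1L  # LOOKUP_TABLE line
      b <- scan_block(i + 1L, m)
      cell_scalars[[tk[2]]] <- b$vals
      i <- b$next_line
    } else {
      i <- i + 1L
    }
  }
  if (is.null(nodes) || is.null(elements)) stop("no POINTS/CELLS found in ", file)
  list(mesh = hex_mesh(nodes, elements),
       point_vectors = point_vectors, cell_scalars = cell_scalars)
}

# ---- CSV node/element tables ------------------------------------------------
# nodes.csv: id,x,y,z with 0-based ids; elements.csv: id,n0..n7[,set] with
# 0-based node indices; comma-separated with a header row.

read_nodes_csv <- function(file) {
  df <- utils::read.csv(file)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop(file, " must have columns id,x,y,z")
  df <- df[order(df$id), ]
  if (!identical(as.integer(df$id), seq_len(nrow(df)) - 1L))
    stop(file, ": node ids must be contiguous 0-based integers")
  as.matrix(df[, c("x", "y", "z")])
}

read_elements_csv <- function(file, n_nodes) {
  df <- utils::read.csv(file)
  ncols <- paste0("n", 0:7)
  if (!all(c("id", ncols) %in% names(df)))
    stop(file, " must have columns id,n0..n7[,set]")
  df <- df[order(df$id), ]
  conn <- as.matrix(df[, ncols]) + 1L
  if (min(conn) < 1L || max(conn) > n_nodes)
    stop(file, ": element connectivity out of node range")
  sets <- list()
  if ("set" %in% names(df)) {
    sets <- split(seq_len(nrow(df)), as.character(df$set))
  }
  list(elements = conn, sets = sets)
}
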