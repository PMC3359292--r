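#' @useDynLib cellscale, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Natural-coordinate corner signs of the standard (VTK) 8-node hexahedron.
# Node a sits at (xi, eta, zeta) = HEX_CORNERS[a, ]; shape function
# N_a = (1 + xi_a xi)(1 + eta_a eta)(1 + zeta_a zeta)/8.
HEX_CORNERS <- matrix(c(
  -1, -1, -1,
   1, -1, -1,
   1,  1, -1,
  -1,  1, -1,
  -1, -1,  1,
   1, -1,  1,
   1,  1,  1,
  -1,  1,  1), ncol = 3, byrow = TRUE)

#' Gauss points of the 2x2x2 rule on the natural cube
#'
#' Returns the eight Gauss points at (+-1/sqrt(3), +-1/sqrt(3), +-1/sqrt(3)),
#' ordered so that point `k` lies in the octant of corner node `k` of the
#' standard hexahedron node ordering. All weights are 1.
#'
#' @return An 8 x 3 numeric matrix of natural coordinates.
#' @export
hex_gauss_points <- function() {
  HEX_CORNERS / sqrt(3)
}

check_natural_point <- function(p) {
  if (!is.numeric(p) || length(p) != 3L || anyNA(p))
    stop("a natural point must be a numeric vector (xi, eta, zeta)")
  if (any(abs(p) > 1 + 1e-12))
    stop("natural point (", paste(signif(p, 4), collapse = ", "),
         ") lies outside the isoparametric cube [-1, 1]^3")
  invisible(p)
}

check_hex_coords <- function(coords, what = "coords") {
  if (!is.matrix(coords) || !identical(dim(coords), c(8L, 3L)) ||
      !is.numeric(coords) || anyNA(coords))
    stop("`", what, "` must be an 8 x 3 numeric matrix of nodal positions")
  invisible(coords)
}

#' Trilinear shape functions of the 8-node hexahedron
#'
#' Evaluates the eight trilinear shape functions at a point of the natural
#' (isoparametric) cube. The functions interpolate nodal values: weight `a`
#' is 1 at node `a`'s natural corner and the weights always sum to 1.
#'
#' @param p Natural coordinates `c(xi, eta, zeta)`, each in `[-1, 1]`.
#'   The element centroid is `c(0, 0, 0)`.
#' @return A numeric vector of 8 weights.
#' @examples
#' hex_shape_values(c(0, 0, 0))   # all 1/8
#' @export
hex_shape_values <- function(p) {
  check_natural_point(p)
  (1 + HEX_CORNERS[, 1] * p[1]) *
  (1 + HEX_CORNERS[, 2] * p[2]) *
  (1 + HEX_CORNERS[, 3] * p[3]) / 8
}

#' Shape-function gradients with respect to natural coordinates
#'
#' @inheritParams hex_shape_values
#' @return An 8 x 3 matrix; row `a` is the gradient of shape function `a`
#'   with respect to `(xi, eta, zeta)`. The rows sum to the zero vector
#'   (constant fields are reproduced exactly).
#' @export
hex_shape_gradients <- function(p) {
  check_natural_point(p)
  s <- HEX_CORNERS
  f1 <- 1 + s[, 1] * p[1]
  f2 <- 1 + s[, 2] * p[2]
  f3 <- 1 + s[, 3] * p[3]
  cbind(s[, 1] * f2 * f3, f1 * s[, 2] * f3, f1 * f2 * s[, 3]) / 8
}

#' Jacobian of the isoparametric map
#'
#' The Jacobian `J(p) = d x / d xi` maps the natural cube to the element in
#' global space; its determinant is the local ratio of global volume to
#' natural volume. For an untangled element the determinant is positive.
#'
#' @param coords 8 x 3 matrix of nodal positions (standard node ordering).
#' @param p Natural coordinates.
#' @return A 3 x 3 Jacobian matrix.
#' @export
hex_jacobian <- function(coords, p) {
  check_hex_coords(coords)
  crossprod(coords, hex_shape_gradients(p))  # t(coords) %*% dN
}

stop_inverted <- function(detJ, element = NULL) {
  where <- if (is.null(element)) "" else paste0(" (element ", element, ")")
  stop(structure(class = c("cellscale_inverted_element", "error", "condition"),
                 list(message = paste0("inverted or degenerate hexahedron", where,
                                       ": Jacobian determinant = ", signif(detJ, 6)),
                      call = sys.call(-1))))
}

#' Deformation gradient of a hexahedral element
#'
#' Computes `F = (d x / d xi) (d X / d xi)^{-1}` at a natural point from the
#' undeformed nodal positions `X` and deformed nodal positions `x`. `F` is
#' exact wherever the underlying deformation is affine, and is the trilinear
#' interpolant's gradient otherwise.
#'
#' @param undeformed 8 x 3 matrix of undeformed nodal positions.
#' @param deformed 8 x 3 matrix of deformed nodal positions.
#' @param p Natural coordinates at which to sample (defaults to the centroid).
#' @param element Optional element id used in error messages.
#' @return A 3 x 3 deformation gradient with positive determinant.
#' @export
hex_deformation_gradient <- function(undeformed, deformed, p = c(0, 0, 0),
                                     element = NULL) {
  check_hex_coords(undeformed, "undeformed")
  check_hex_coords(deformed, "deformed")
  dN <- hex_shape_gradients(p)
  J0 <- crossprod(undeformed, dN)
  d0 <- det(J0)
  if (!is.finite(d0) || d0 <= 0) stop_inverted(d0, element)
  J1 <- crossprod(deformed, dN)
  J1 %*% solve(J0)
}

#' Volume of a hexahedral element
#'
#' Two quadrature rules are provided. `"centroid"` evaluates the Jacobian
#' determinant once at the element centroid and multiplies by the natural
#' volume 8; it is exact for parallelepipeds (constant Jacobian). `"gauss8"`
#' uses the 2x2x2 Gauss rule, which integrates the trilinear isoparametric
#' volume exactly for any untangled hexahedron.
#'
#' @param coords 8 x 3 matrix of nodal positions.
#' @param rule `"centroid"` (default) or `"gauss8"`.
#' @param element Optional element id used in error messages.
#' @return The element volume (cube of the coordinate unit).
#' @export
hex_element_volume <- function(coords, rule = c("centroid", "gauss8"),
                               element = NULL) {
  rule <- match.arg(rule)
  check_hex_coords(coords)
  if (rule == "centroid") {
    d <- det(hex_jacobian(coords, c(0, 0, 0)))
    if (!is.finite(d) || d <= 0) stop_inverted(d, element)
    return(8 * d)
  }
  gp <- hex_gauss_points()
  v <- 0
  for (k in seq_len(8)) {
    d <- det(hex_jacobian(coords, gp[k, ]))
    if (!is.finite(d) || d <= 0) stop_inverted(d, element)
    v <- v + d
  }
  v
}
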