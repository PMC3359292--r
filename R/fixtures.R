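# fixtures: synthetic macro states with analytically known deformation
# fields, and the canonical micro load cases. These stand in for a real
# joint-scale solution so every pipeline stage is testable end to end.

#' Analytic deformation field
#'
#' A closed-form map `x(X)` with its exact deformation gradient `F(X)`,
#' used to manufacture macro solutions whose per-element deformation
#' gradients are known.
#'
#' Modes: `"affine"` (`x = F0 X + c`), `"uniaxial"` (axial stretch with
#' prescribed lateral stretch, volume-preserving by default),
#' `"simple_shear"` (`x1 = X1 + gamma X3`), `"combined"` (simple shear
#' composed with uniaxial stretch), and `"bending"`
#' (`x1 = X1 + kappa X3^2`, a spatially varying gradient `F13 = 2 kappa X3`
#' that no single trilinear element reproduces exactly).
#'
#' @param mode One of `"affine"`, `"uniaxial"`, `"simple_shear"`,
#'   `"combined"`, `"bending"`.
#' @param F0 3 x 3 matrix for `"affine"`.
#' @param translation Length-3 shift for `"affine"`.
#' @param stretch Axial (z) stretch for `"uniaxial"`/`"combined"`.
#' @param lateral Lateral stretch (default `stretch^-0.5`, volume
#'   preserving).
#' @param gamma Shear parameter for `"simple_shear"`/`"combined"`.
#' @param kappa Bending parameter (1/length) for `"bending"`.
#' @return An `analytic_deformation`: list with `map(X)` (n x 3 -> n x 3)
#'   and `F(X)` (length-3 point -> 3 x 3).
#' @export
analytic_deformation <- function(mode = c("affine", "uniaxial", "simple_shear",
                                          "combined", "bending"),
                                 F0 = diag(3), translation = c(0, 0, 0),
                                 stretch = 0.9, lateral = stretch^-0.5,
                                 gamma = 0.1, kappa = 0.05) {
  mode <- match.arg(mode)
  obj <- switch(mode,
    affine = {
      F0 <- matrix(as.numeric(F0), 3, 3)
      list(map = function(X) X %*% t(F0) +
             matrix(translation, nrow(X), 3, byrow = TRUE),
           F = function(X) F0)
    },
    uniaxial = {
      Fu <- diag(c(lateral, lateral, stretch))
      list(map = function(X) X %*% t(Fu), F = function(X) Fu)
    },
    simple_shear = {
      Fs <- diag(3); Fs[1, 3] <- gamma
      list(map = function(X) X %*% t(Fs), F = function(X) Fs)
    },
    combined = {
      Fs <- diag(c(lateral, lateral, stretch)); Fs[1, 3] <- gamma
      list(map = function(X) X %*% t(Fs), F = function(X) Fs)
    },
    bending = {
      list(map = function(X) cbind(X[, 1] + kappa * X[, 3]^2, X[, 2], X[, 3]),
           F = function(X) {
             Fb <- diag(3); Fb[1, 3] <- 2 * kappa * X[3]; Fb
           })
    })
  structure(c(obj, list(mode = mode)), class = "analytic_deformation")
}

#' Synthetic macro solution on a slab mesh
#'
#' Builds a structured hexahedral slab, applies an analytic deformation to
#' its nodes, and returns the resulting [macro_state()] together with the
#' field's exact `F` as an oracle. The map is rejected if it tangles any
#' element (non-positive Jacobian at a sampled grid of natural points).
#'
#' @param nx,ny,nz Elements per direction.
#' @param lower,upper Slab box corners (mm).
#' @param deformation An [analytic_deformation()].
#' @return List with `state` (a `macro_state`) and `oracle_F` (function of a
#'   length-3 position).
#' @export
synthetic_macro_solution <- function(nx, ny, nz, deformation,
                                     lower = c(0, 0, 0),
                                     upper = c(10, 10, 10)) {
  stopifnot(inherits(deformation, "analytic_deformation"))
  mesh <- structured_hex_mesh(nx, ny, nz, lower, upper)
  deformed <- deformation$map(mesh$nodes)
  # pre-check: exact F must be invertible on a sample grid of the domain
  smp <- as.matrix(expand.grid(seq(lower[1], upper[1], length.out = 4),
                               seq(lower[2], upper[2], length.out = 4),
                               seq(lower[3], upper[3], length.out = 4)))
  for (r in seq_len(nrow(smp)))
    if (det(deformation$F(smp[r, ])) <= 0)
      stop("deformation field tangles the domain (det F <= 0 at sampled point)")
  for (e in seq_len(nrow(mesh$elements))) {
    co <- element_coords(mesh, e, deformed)
    d <- det(hex_jacobian(co, c(0, 0, 0)))
    if (d <= 0) stop("deformation map tangles element ", e)
  }
  list(state = macro_state(mesh, deformed = deformed),
       oracle_F = deformation$F)
}

#' Canonical micro-scale load cases
#'
#' The fixed, deterministic load cases used throughout verification:
#' \describe{
#'   \item{unconfined_30}{-30% nominal z strain with free lateral expansion
#'     (mixed boundary conditions: only the z-faces are prescribed).}
#'   \item{volume_preserving_10}{10% nominal z compression with
#'     volume-preserving lateral expansion, the affine
#'     `F = diag(0.9^-0.5, 0.9^-0.5, 0.9)` with `det F = 1`.}
#'   \item{pure_shear}{simple shear, `F = I + 0.1 e1 (x) e3`.}
#' }
#'
#' @return Named list of cases; each has `name`, `bc_type`
#'   (`"affine"`/`"mixed"`), and either `F` or `stretch`.
#' @export
canonical_micro_cases <- function() {
  Fb <- diag(c(0.9^-0.5, 0.9^-0.5, 0.9))
  Fc <- diag(3); Fc[1, 3] <- 0.1
  list(
    unconfined_30 = list(name = "unconfined_30", bc_type = "mixed",
                         stretch = 0.7),
    volume_preserving_10 = list(name = "volume_preserving_10",
                                bc_type = "affine", F = Fb),
    pure_shear = list(name = "pure_shear", bc_type = "affine", F = Fc))
}
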