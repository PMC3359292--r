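# fe_solver: displacement-driven static solution of micro models under
# affine (or mixed) boundary conditions at finite strain.

#' Affine displacement boundary conditions from a deformation gradient
#'
#' Prescribes `u(X) = (F - I) X` on every node of the six faces of the block
#' (interior nodes stay free), transferring a macro-scale element deformation
#' gradient to the micro model boundary.
#'
#' @param mesh A [hex_mesh()] whose nodes span an axis-aligned block.
#' @param F 3 x 3 deformation gradient with positive determinant (a
#'   non-positive determinant is allowed here so a deliberately absurd job
#'   can be detected and contained by the solver rather than raising).
#' @return A `bc_set`: data.frame with columns `node`, `dof` (1..3), `value`,
#'   plus the driving `F` and an affine full-field guess as attributes.
#' @export
apply_boundary_conditions <- function(mesh, F) {
  stopifnot(inherits(mesh, "hex_mesh"))
  F <- matrix(as.numeric(F), 3, 3)
  X <- mesh$nodes
  rng <- apply(X, 2, range)
  tol <- 1e-8 * max(rng[2, ] - rng[1, ])
  on_face <- (abs(X[, 1] - rng[1, 1]) < tol) | (abs(X[, 1] - rng[2, 1]) < tol) |
             (abs(X[, 2] - rng[1, 2]) < tol) | (abs(X[, 2] - rng[2, 2]) < tol) |
             (abs(X[, 3] - rng[1, 3]) < tol) | (abs(X[, 3] - rng[2, 3]) < tol)
  nodes <- which(on_face)
  Ub <- X[nodes, , drop = FALSE] %*% t(F - diag(3))
  bc <- data.frame(node = rep(nodes, 3L),
                   dof = rep(1:3, each = length(nodes)),
                   value = as.vector(Ub))
  attr(bc, "F") <- F
  attr(bc, "guess") <- X %*% t(F - diag(3))
  class(bc) <- c("bc_set", "data.frame")
  bc
}

#' Mixed boundary conditions for unconfined uniaxial loading
#'
#' Prescribes the axial displacement `u_z = (stretch - 1) Z` on both z-faces
#' and leaves the lateral faces traction-free. Rigid lateral motion is
#' removed by symmetry supports: `u_x = 0` on the `x = min` face and
#' `u_y = 0` on the `y = min` face, consistent with a homogeneous uniaxial
#' state.
#'
#' @param mesh A [hex_mesh()] block.
#' @param stretch Axial stretch ratio (e.g. 0.7 for -30% nominal strain).
#' @param lateral_guess Initial guess for the lateral stretch (defaults to
#'   the incompressible value `stretch^-0.5`).
#' @return A `bc_set` (see [apply_boundary_conditions()]).
#' @export
unconfined_compression_bcs <- function(mesh, stretch,
                                       lateral_guess = stretch^-0.5) {
  stopifnot(inherits(mesh, "hex_mesh"), stretch > 0)
  X <- mesh$nodes
  rng <- apply(X, 2, range)
  tol <- 1e-8 * max(rng[2, ] - rng[1, ])
  zface <- which(abs(X[, 3] - rng[1, 3]) < tol | abs(X[, 3] - rng[2, 3]) < tol)
  xface <- which(abs(X[, 1] - rng[1, 1]) < tol)
  yface <- which(abs(X[, 2] - rng[1, 2]) < tol)
  bc <- rbind(
    data.frame(node = zface, dof = 3L, value = (stretch - 1) * X[zface, 3]),
    data.frame(node = xface, dof = 1L, value = 0),
    data.frame(node = yface, dof = 2L, value = 0))
  Fg <- diag(c(lateral_guess, lateral_guess, stretch))
  attr(bc, "F") <- NULL
  attr(bc, "guess") <- sweep(X, 2, rng[1, ]) %*% (Fg - diag(3)) +
    matrix(0, nrow(X), 3)
  class(bc) <- c("bc_set", "data.frame")
  bc
}

#' Cauchy stress of the uncoupled Mooney-Rivlin model
#'
#' Stress derived from `W = c1 (I1bar - 3) + c2 (I2bar - 3) + (K/2)(ln J)^2`:
#' the deviatoric part comes from the isochoric invariants and the pressure
#' is `K ln(J) / J`. The result is symmetric and vanishes at `F = I`.
#'
#' @param F 3 x 3 deformation gradient, `det F > 0`.
#' @param material Numeric vector/list with elements `c1`, `c2`, `K` (MPa).
#' @return 3 x 3 symmetric Cauchy stress (MPa).
#' @export
cauchy_stress <- function(F, material) {
  F <- matrix(as.numeric(F), 3, 3)
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("cauchy_stress requires det F > 0 (got ", signif(J, 6), ")")
  c1 <- material[["c1"]]; c2 <- material[["c2"]]; K <- material[["K"]]
  Bb <- J^(-2 / 3) * tcrossprod(F)     # isochoric left Cauchy-Green
  I1b <- sum(diag(Bb))
  M <- (c1 + c2 * I1b) * Bb - c2 * Bb %*% Bb
  dev <- M - diag(sum(diag(M)) / 3, 3)
  (2 / J) * dev + diag(K * log(J) / J, 3)
}

#' Solver settings
#'
#' @param n_steps Number of equal load increments.
#' @param rtol Relative residual-norm convergence tolerance per step.
#' @param max_iter Maximum Newton iterations per step.
#' @param line_search Use backtracking line search on the residual norm.
#' @param initial_guess `"affine"` seeds the full field with the boundary
#'   condition's affine map (exact for homogeneous blocks), `"zero"` starts
#'   from rest.
#' @param refactor_ratio Quasi-Newton control: the tangent is refactorized
#'   whenever an iteration shrinks the residual by less than this factor.
#' @return A `solver_settings` list.
#' @export
solver_settings <- function(n_steps = 10L, rtol = 1e-6, max_iter = 25L,
                            line_search = TRUE,
                            initial_guess = c("affine", "zero"),
                            refactor_ratio = 0.8) {
  stopifnot(n_steps >= 1, rtol > 0, max_iter >= 1)
  structure(list(n_steps = as.integer(n_steps), rtol = rtol,
                 max_iter = as.integer(max_iter),
                 line_search = isTRUE(line_search),
                 initial_guess = match.arg(initial_guess),
                 refactor_ratio = refactor_ratio),
            class = "solver_settings")
}

free_residual <- function(Rmat, free_idx) as.numeric(t(Rmat))[free_idx]

#' Solve a micro model statically
#'
#' Incremental Newton solution of the displacement-driven hyperelastic
#' problem. The tangent stiffness is the finite-difference-consistent
#' Hessian of the mean-dilatation element energy, factorized with CHOLMOD
#' and reused across iterations while convergence is healthy
#' (quasi-Newton); a backtracking line search guards each update.
#' Mechanical non-convergence never raises: the returned solution carries
#' `status = "failed"` with diagnostics so that batch processing continues.
#'
#' @param model A [build_micro_mesh()] model with materials attached
#'   ([assign_materials()]).
#' @param bcs A `bc_set` from [apply_boundary_conditions()] or
#'   [unconfined_compression_bcs()].
#' @param settings A [solver_settings()].
#' @return A `micro_solution`: nodal displacements `U` (um), per-element
#'   centroid deformation gradient `F` (m x 9, row-major), Green-Lagrange
#'   strain `E`, Cauchy stress `sigma` (MPa), element volumes in both
#'   configurations (centroid rule), `status` (`"converged"`/`"failed"`),
#'   and per-step residual diagnostics.
#' @export
solve_static <- function(model, bcs, settings = solver_settings()) {
  stopifnot(inherits(model, "micro_model"), inherits(bcs, "bc_set"),
            inherits(settings, "solver_settings"))
  if (is.null(model$materials))
    stop("model has no materials; call assign_materials() first")
  mesh <- model$mesh
  n <- nrow(mesh$nodes)
  mat <- as.matrix(model$materials[as.character(model$region),
                                   c("c1", "c2", "K")])
  fail <- function(why, diag_, U = NULL) {
    structure(list(U = U, F = NULL, E = NULL, sigma = NULL,
                   vol_ref = NULL, vol_def = NULL, Jbar = NULL,
                   status = "failed", reason = why, diagnostics = diag_,
                   model = model),
              class = "micro_solution")
  }
  if (anyNA(bcs$value) || any(!is.finite(bcs$value)))
    return(fail("non-finite prescribed displacements", list()))
  Fdrv <- attr(bcs, "F")
  if (!is.null(Fdrv) && det(Fdrv) <= 0)
    return(fail(sprintf("driving deformation gradient has det = %g <= 0",
                        det(Fdrv)), list()))

  setup <- fe_setup_cpp(mesh$nodes, mesh$elements)
  gdof <- 3L * (bcs$node - 1L) + bcs$dof        # dof order: node-major xyz
  if (anyDuplicated(gdof))
    stop("boundary condition set prescribes a dof more than once")
  freemap <- rep(0L, 3L * n)
  freemap[gdof] <- -1L
  free_idx <- which(freemap == 0L)
  freemap[free_idx] <- seq_along(free_idx) - 1L
  freemap[gdof] <- -1L
  nf <- length(free_idx)
  if (nf == 0L) stop("no free degrees of freedom")

  U <- matrix(0, n, 3)
  guess <- attr(bcs, "guess")
  use_guess <- settings$initial_guess == "affine" && !is.null(guess)
  set_constrained <- function(U, t) {
    Ut <- t(U)
    Ut[gdof] <- t * bcs$value
    t(Ut)
  }
  add_free <- function(U, dvec) {
    Ut <- t(U)
    Ut[free_idx] <- Ut[free_idx] + dvec
    t(Ut)
  }
  force_scale <- max(mat[, "c1"]) * (sum(setup$Ve))^(2 / 3)
  atol <- 1e-9 * force_scale
  diagnostics <- list()
  chol_fac <- NULL
  t_prev <- 0

  for (step in seq_len(settings$n_steps)) {
    tfrac <- step / settings$n_steps
    if (use_guess) {
      gfree <- as.numeric(t(guess))[free_idx]
      U <- add_free(U, (tfrac - t_prev) * gfree)
    }
    U <- set_constrained(U, tfrac)
    res <- fe_residual_cpp(U, mesh$elements, setup$Gref, setup$wdet,
                           setup$Ve, mat)
    if (!res$ok || res$minJ <= 0) {
      if (use_guess) {
        # predictor tangled the mesh; retreat to the previous iterate
        U <- add_free(U, -(tfrac - t_prev) *
                        as.numeric(t(guess))[free_idx])
        res <- fe_residual_cpp(U, mesh$elements, setup$Gref, setup$wdet,
                               setup$Ve, mat)
      }
      if (!res$ok || res$minJ <= 0)
        return(fail(sprintf("element inversion at load step %d", step),
                    diagnostics, U))
    }
    rnorm <- sqrt(sum(free_residual(res$R, free_idx)^2))
    r0 <- max(rnorm, atol)
    hist <- c(rnorm)
    need_factor <- TRUE
    fresh_factor <- FALSE
    solve_fun <- NULL
    converged <- rnorm <= max(settings$rtol * r0, atol)
    it <- 0L
    while (!converged && it < settings$max_iter) {
      it <- it + 1L
      if (need_factor) {
        tri <- fe_tangent_cpp(U, mesh$elements, setup$Gref, setup$wdet,
                              setup$Ve, mat, freemap)
        Kff <- Matrix::sparseMatrix(i = tri$i + 1L, j = tri$j + 1L, x = tri$x,
                                    dims = c(nf, nf))
        Kff <- Matrix::forceSymmetric(Kff)
        # Cholesky is used while the tangent is positive definite; an
        # indefinite state (CHOLMOD warns) falls back to a sparse LU
        # direction for this iteration.
        pd <- TRUE
        fac <- withCallingHandlers(
          tryCatch({
            if (is.null(chol_fac)) Matrix::Cholesky(Kff, LDL = FALSE,
                                                    super = TRUE)
            else Matrix::update(chol_fac, Kff)
          }, error = function(e) NULL),
          warning = function(w) {
            pd <<- FALSE
            invokeRestart("muffleWarning")
          })
        if (!is.null(fac)) chol_fac <- fac  # reuse the symbolic analysis
        solve_fun <- if (!is.null(fac) && pd) {
          local({
            f <- fac
            function(b) as.numeric(Matrix::solve(f, b, system = "A"))
          })
        } else {
          function(b) as.numeric(Matrix::solve(Kff, b))
        }
        need_factor <- FALSE
        fresh_factor <- TRUE
      }
      rfree <- free_residual(res$R, free_idx)
      du <- solve_fun(-rfree)
      accepted <- FALSE
      if (!anyNA(du) && all(is.finite(du))) {
        alpha <- 1
        for (ls in seq_len(if (settings$line_search) 10L else 1L)) {
          U_try <- add_free(U, alpha * du)
          res_try <- fe_residual_cpp(U_try, mesh$elements, setup$Gref,
                                     setup$wdet, setup$Ve, mat)
          if (res_try$ok && res_try$minJ > 0) {
            rn_try <- sqrt(sum(free_residual(res_try$R, free_idx)^2))
            if (is.finite(rn_try) &&
                (rn_try < rnorm || !settings$line_search)) {
              accepted <- TRUE
              break
            }
          }
          alpha <- alpha / 2
        }
      }
      if (!accepted) {
        if (!fresh_factor) {
          # stale quasi-Newton tangent: refactorize at this state and retry
          need_factor <- TRUE
          next
        }
        return(fail(sprintf(
          "line search failed at step %d iteration %d (residual %.3g)",
          step, it, rnorm), diagnostics, U))
      }
      # refactorize when the (quasi-)Newton contraction stalls
      rn_new <- sqrt(sum(free_residual(res_try$R, free_idx)^2))
      if (rn_new > settings$refactor_ratio * rnorm || alpha < 1)
        need_factor <- TRUE
      fresh_factor <- FALSE
      U <- U_try
      res <- res_try
      rnorm <- rn_new
      hist <- c(hist, rnorm)
      converged <- rnorm <= max(settings$rtol * r0, atol)
    }
    diagnostics[[step]] <- list(step = step, t = tfrac, iterations = it,
                                residuals = hist, converged = converged)
    if (!converged)
      return(fail(sprintf(
        "no convergence in %d iterations at load step %d (residual %.3g)",
        settings$max_iter, step, rnorm), diagnostics, U))
    t_prev <- tfrac
  }

  rec <- fe_recover_cpp(U, mesh$elements, setup$Gref, setup$wdet, setup$Ve,
                        setup$Gc, setup$detc, mat)
  Fel <- rec$F
  # Green-Lagrange E = (F^T F - I)/2, vectorized over elements (row-major F)
  E <- matrix(0, nrow(Fel), 9)
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (k in 1:3) acc <- acc + Fel[, 3 * (k - 1) + i] * Fel[, 3 * (k - 1) + j]
    E[, 3 * (i - 1) + j] <- (acc - (i == j)) / 2
  }
  structure(list(U = U, F = Fel, E = E, sigma = rec$sigma,
                 vol_ref = rec$vol_ref, vol_def = rec$vol_def,
                 Jbar = rec$Jbar, status = "converged", reason = NULL,
                 diagnostics = diagnostics, model = model),
            class = "micro_solution")
}

#' @export
print.micro_solution <- function(x, ...) {
  cat("micro_solution: status =", x$status, "\n")
  if (x$status == "failed") {
    cat("  reason:", x$reason, "\n")
  } else {
    cat("  max |u| =", signif(max(abs(x$U)), 4), "um;",
        length(x$diagnostics), "load step(s)\n")
  }
  invisible(x)
}

#' Export a micro solution as a legacy VTK file
#'
#' Writes the mesh with point-data displacements and cell-data region labels,
#' effective strain and effective stress.
#'
#' @param solution A converged `micro_solution`.
#' @param file Output `.vtk` path.
#' @return `file`, invisibly.
#' @export
write_solution_vtk <- function(solution, file) {
  stopifnot(inherits(solution, "micro_solution"))
  if (solution$status != "converged")
    stop("cannot export a failed solution")
  model <- solution$model
  write_vtk(model$mesh, file,
            point_vectors = list(displacement = solution$U),
            cell_scalars = list(
              region = as.integer(model$region),
              effective_strain = effective_scalar_rows(solution$E),
              effective_stress = effective_scalar_rows(solution$sigma)))
}
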