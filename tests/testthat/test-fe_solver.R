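test_that("affine boundary conditions prescribe u = (F - I) X on all faces", {
  mesh <- structured_hex_mesh(4, 4, 4, upper = c(100, 100, 100))
  bcs <- apply_boundary_conditions(mesh, diag(3))
  expect_true(all(bcs$value == 0))
  # every face node appears for all 3 dofs exactly once; interior absent
  X <- mesh$nodes
  face <- which(apply(X, 1, function(p) any(p %in% c(0, 100))))
  expect_setequal(unique(bcs$node), face)
  expect_equal(nrow(bcs), 3 * length(face))
  # corner arithmetic
  F <- diag(c(0.9, 1, 1))
  bc2 <- apply_boundary_conditions(mesh, F)
  corner <- which(X[, 1] == 100 & X[, 2] == 0 & X[, 3] == 0)
  expect_equal(bc2$value[bc2$node == corner & bc2$dof == 1], -10)
  expect_equal(bc2$value[bc2$node == corner & bc2$dof == 2], 0)
  # simple shear against the direct formula on 50 random face nodes
  Fs <- diag(3); Fs[1, 2] <- 0.1
  bc3 <- apply_boundary_conditions(mesh, Fs)
  set.seed(31)
  for (nd in sample(face, 50, replace = TRUE)) {
    u <- (Fs - diag(3)) %*% X[nd, ]
    for (d in 1:3)
      expect_equal(bc3$value[bc3$node == nd & bc3$dof == d], u[d])
  }
})

test_that("Cauchy stress matches the energy-differentiation oracle", {
  ecm <- c(c1 = 1.6892, c2 = 0, K = 83.3333)
  expect_equal(cauchy_stress(diag(3), ecm), matrix(0, 3, 3))
  # pure dilation: zero deviator, pressure K ln(a^3) / a^3
  for (a in c(0.9, 1.15)) {
    s <- cauchy_stress(a * diag(3), ecm)
    expect_equal(s, diag(ecm[["K"]] * log(a^3) / a^3, 3), tolerance = 1e-12)
  }
  # random F (including a c2 != 0 material) vs numerical dW/dF
  set.seed(32)
  mt <- c(c1 = 0.7, c2 = 0.25, K = 20)
  for (k in 1:10) {
    F <- diag(3) + 0.2 * matrix(stats::rnorm(9), 3, 3)
    if (det(F) < 0.4) next
    s <- cauchy_stress(F, mt)
    expect_equal(s, t(s), tolerance = 1e-12)
    s_fd <- fd_cauchy_stress(F, mt[["c1"]], mt[["c2"]], mt[["K"]])
    expect_lt(max(abs(s - s_fd)) / max(abs(s)), 1e-6)
  }
  expect_error(cauchy_stress(diag(c(-1, 1, 1)), ecm), "det F")
})

test_that("patch test: homogeneous blocks reproduce affine states exactly", {
  F <- matrix(c(0.94, 0.03, 0, 0.01, 1.05, 0.02, 0, 0, 0.92), 3, 3)
  tb <- material_table()
  for (region in rownames(tb)) {
    mat <- unlist(tb[region, ])
    m <- homogeneous_block(10, mat)
    sol <- solve_static(m, apply_boundary_conditions(m$mesh, F),
                        solver_settings(n_steps = 1))
    expect_equal(sol$status, "converged")
    Uaff <- m$mesh$nodes %*% t(F - diag(3))
    expect_lt(max(abs(sol$U - Uaff)), 1e-8)
    # uniform stress equal to the constitutive law's value
    sig_ref <- cauchy_stress(F, mat)
    for (e in c(1, 50, nrow(sol$sigma)))
      expect_equal(matrix(sol$sigma[e, ], 3, 3), sig_ref, tolerance = 1e-8)
  }
})

test_that("unconfined uniaxial solution matches the 1D compressible oracle", {
  ecm <- c(c1 = 1.6892, c2 = 0, K = 83.3333)
  m <- homogeneous_block(10, ecm)
  for (lam in c(0.8, 1.2)) {
    sol <- solve_static(m, unconfined_compression_bcs(m$mesh, lam),
                        solver_settings(n_steps = 2))
    expect_equal(sol$status, "converged")
    orc <- uniaxial_1d_oracle(lam, ecm[["c1"]], ecm[["c2"]], ecm[["K"]])
    sig <- matrix(sol$sigma[1, ], 3, 3)
    expect_lt(abs(sig[3, 3] - orc$sigma_zz) / abs(orc$sigma_zz), 1e-3)
    # lateral faces are stress-free
    expect_lt(abs(sig[1, 1]), 1e-3 * abs(sig[3, 3]))
  }
})

test_that("lateral expansion approaches incompressible kinematics as K grows", {
  # -30% nominal z strain, free lateral: lateral stretch -> 0.7^-0.5
  stiff <- c(c1 = 1.6892, c2 = 0, K = 100 * 83.3333)
  m <- homogeneous_block(10, stiff)
  sol <- solve_static(m, unconfined_compression_bcs(m$mesh, 0.7),
                      solver_settings(n_steps = 4))
  expect_equal(sol$status, "converged")
  X <- m$mesh$nodes
  xmax <- which(X[, 1] == max(X[, 1]))
  lat <- mean((X[xmax, 1] + sol$U[xmax, 1]) / X[xmax, 1])
  expect_lt(abs(lat - 0.7^-0.5) / 0.7^-0.5, 0.005)
})

test_that("solution is invariant under node renumbering", {
  g <- place_chondrons(1)
  model <- assign_materials(build_micro_mesh(g, 12), material_table())
  F <- diag(c(0.96, 1.01, 0.95))
  sol <- solve_static(model, apply_boundary_conditions(model$mesh, F),
                      fast_settings())
  set.seed(33)
  n <- nrow(model$mesh$nodes)
  perm <- sample(n)              # new position i holds old node perm[i]
  inv <- integer(n); inv[perm] <- seq_len(n)
  mesh2 <- hex_mesh(model$mesh$nodes[perm, ],
                    matrix(inv[model$mesh$elements], ncol = 8),
                    model$mesh$sets)
  model2 <- model
  model2$mesh <- mesh2
  sol2 <- solve_static(model2, apply_boundary_conditions(mesh2, F),
                       fast_settings())
  expect_equal(sol2$status, "converged")
  expect_lt(max(abs(sol2$U - sol$U[perm, ])), 1e-8)
})

test_that("cells deform more than the surrounding matrix under compression", {
  g <- place_chondrons(1)
  model <- assign_materials(build_micro_mesh(g, 16), material_table())
  F <- diag(c(0.9^-0.5, 0.9^-0.5, 0.9))
  sol <- solve_static(model, apply_boundary_conditions(model$mesh, F),
                      fast_settings())
  expect_equal(sol$status, "converged")
  cell <- volume_averaged_metric(sol, "Cell", "effective_strain")
  ecm <- volume_averaged_metric(sol, "ECM", "effective_strain")
  expect_gt(cell, ecm)
  expect_true(all(sol$Jbar > 0))
})

test_that("mechanical failure is contained as a status, not an error", {
  g <- place_chondrons(1)
  model <- assign_materials(build_micro_mesh(g, 12), material_table())
  # deformation gradient with negative determinant: absurd on purpose
  bad <- apply_boundary_conditions(model$mesh, diag(c(-1, 1, 1)))
  sol <- expect_no_error(solve_static(model, bad, solver_settings()))
  expect_equal(sol$status, "failed")
  expect_match(sol$reason, "det")
  # non-finite prescribed displacement
  bcs <- apply_boundary_conditions(model$mesh, diag(c(0.9, 1, 1)))
  bcs$value[5] <- NaN
  sol2 <- expect_no_error(solve_static(model, bcs, solver_settings()))
  expect_equal(sol2$status, "failed")
})

test_that("Newton residuals decrease monotonically in converged steps", {
  g <- place_chondrons(1)
  model <- assign_materials(build_micro_mesh(g, 12), material_table())
  F <- diag(c(0.9^-0.5, 0.9^-0.5, 0.9))
  sol <- solve_static(model, apply_boundary_conditions(model$mesh, F),
                      solver_settings(n_steps = 4, initial_guess = "zero"))
  expect_equal(sol$status, "converged")
  for (d in sol$diagnostics)
    expect_true(all(diff(d$residuals) < 0))
})

test_that("solution export writes displacements and metrics to VTK", {
  dir <- withr::local_tempdir()
  m <- homogeneous_block(10)
  F <- diag(c(0.95, 1, 1))
  sol <- solve_static(m, apply_boundary_conditions(m$mesh, F),
                      solver_settings(n_steps = 1))
  f <- file.path(dir, "sol.vtk")
  write_solution_vtk(sol, f)
  back <- read_vtk(f)
  expect_equal(back$point_vectors$displacement, sol$U)
  expect_true("effective_strain" %in% names(back$cell_scalars))
})
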