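test_that("effective scalar: canonical values and frame indifference", {
  expect_equal(effective_scalar(matrix(0, 3, 3)), 0)
  expect_equal(effective_scalar(diag(c(5, 0, 0))), 5)
  expect_equal(effective_scalar(diag(c(2, 2, 2))), 0)
  set.seed(41)
  for (k in 1:20) {
    Tm <- matrix(stats::rnorm(9), 3, 3); Tm <- (Tm + t(Tm)) / 2
    Q <- random_rotation()
    expect_equal(effective_scalar(Q %*% Tm %*% t(Q)), effective_scalar(Tm))
    expect_equal(max_shear(Q %*% Tm %*% t(Q)), max_shear(Tm))
    expect_gte(effective_scalar(Tm), 0)
    expect_gte(max_shear(Tm), 0)
  }
})

test_that("max shear equals the sampled-orientation oracle", {
  expect_equal(max_shear(matrix(0, 3, 3)), 0)
  expect_equal(max_shear(diag(c(0.3, 0, -0.3))), 0.3)
  set.seed(42)
  Tm <- matrix(stats::rnorm(9), 3, 3); Tm <- (Tm + t(Tm)) / 2
  # shear traction magnitude over many sampled plane normals
  N <- matrix(stats::rnorm(3 * 60000), ncol = 3)
  N <- N / sqrt(rowSums(N^2))
  tn <- N %*% Tm
  normal <- rowSums(tn * N)
  shear <- sqrt(pmax(rowSums(tn^2) - normal^2, 0))
  expect_lt(abs(max(shear) - max_shear(Tm)), 1e-3)
})

test_that("vectorized principal values agree with eigen()", {
  set.seed(43)
  S <- matrix(0, 50, 9)
  for (r in 1:50) {
    Tm <- matrix(stats::rnorm(9), 3, 3); Tm <- (Tm + t(Tm)) / 2
    S[r, ] <- as.vector(t(Tm))
  }
  P <- cellscale:::symeig3_rows(S)
  for (r in 1:50) {
    Tm <- matrix(S[r, ], 3, 3, byrow = TRUE)
    expect_equal(P[r, ], sort(eigen(Tm, symmetric = TRUE,
                                    only.values = TRUE)$values,
                              decreasing = TRUE), tolerance = 1e-10)
  }
})

test_that("inertia tensor of a voxel cube matches the discrete closed form", {
  r <- 20L; L <- 2
  h <- L / r
  ctr <- as.matrix(expand.grid(x = (seq_len(r) - 0.5) * h - L / 2,
                               y = (seq_len(r) - 0.5) * h - L / 2,
                               z = (seq_len(r) - 0.5) * h - L / 2))
  vols <- rep(h^3, nrow(ctr))
  m <- sum(vols)
  I <- inertia_tensor(ctr, vols)
  # centroid point masses of a cube: I = m (L^2 - h^2) / 6 per axis, exactly
  expect_equal(I, diag(m * (L^2 - h^2) / 6, 3), tolerance = 1e-10)
  # translation invariance (centroid-relative assembly)
  I2 <- inertia_tensor(ctr + matrix(c(5, -3, 11), nrow(ctr), 3, byrow = TRUE),
                       vols)
  expect_equal(I2, I, tolerance = 1e-8)
})

test_that("ellipsoid axes recover spheres and analytic ellipsoids", {
  mesh <- voxel_sphere_mesh(50)
  ids <- mesh$sets$sphere
  # symmetric voxel sphere: near-equal principal moments, axes near R = 1
  cv <- cellscale:::set_centroids_volumes(mesh, ids, mesh$nodes)
  I <- inertia_tensor(cv$centroids, cv$volumes)
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_lt((ev[1] - ev[3]) / ev[1], 0.01)
  ax <- ellipsoid_axes(I, sum(cv$volumes))
  expect_equal(ax, rep(1, 3), tolerance = 0.01)
  # analytic ellipsoid with semi-axes (0.9, 0.45, 0.45): voxel selection
  h <- 2 * 1.02 / 50
  ctr <- as.matrix(expand.grid(x = (seq_len(50) - 0.5) * h - 1.02,
                               y = (seq_len(50) - 0.5) * h - 1.02,
                               z = (seq_len(50) - 0.5) * h - 1.02))
  ide <- which((ctr[, 1] / 0.9)^2 + (ctr[, 2] / 0.45)^2 +
                 (ctr[, 3] / 0.45)^2 <= 1)
  axe <- ellipsoid_axes(inertia_tensor(ctr[ide, ], rep(h^3, length(ide))),
                        h^3 * length(ide))
  expect_equal(axe, c(0.9, 0.45, 0.45), tolerance = 0.02)
  # infeasible principal moments are refused (violate triangle feasibility)
  expect_error(ellipsoid_axes(diag(c(10, 1, 1)), 1), "infeasible")
})

test_that("shape measurement is isometry- and dilation-insensitive", {
  mesh <- voxel_sphere_mesh(40)
  ids <- mesh$sets$sphere
  ax0 <- set_shape_axes(mesh, ids)
  ar0 <- ax0[1] / ax0[3]
  # rigid rotation: aspect ratios unchanged within mesh tolerance
  Q <- random_rotation()
  axQ <- set_shape_axes(mesh, ids, mesh$nodes %*% t(Q))
  expect_equal(axQ[1] / axQ[3], ar0, tolerance = 1e-6)
  # pure dilation: shape preserved exactly, axes scale
  axD <- set_shape_axes(mesh, ids, 1.3 * mesh$nodes)
  expect_equal(axD[1] / axD[3], ar0, tolerance = 1e-12)
  expect_equal(axD[1] / ax0[1], 1.3, tolerance = 1e-10)
})

test_that("affine deformation of a sphere reproduces closed-form axis ratios", {
  # 10% volume-preserving elongation: semi-axes (1.1, 1.1^-.5, 1.1^-.5)R
  mesh <- voxel_sphere_mesh(44)
  ids <- mesh$sets$sphere
  F <- diag(c(1.1, 1.1^-0.5, 1.1^-0.5))
  ax0 <- set_shape_axes(mesh, ids)
  ax1 <- set_shape_axes(mesh, ids, mesh$nodes %*% t(F))
  dAR <- ax1[1] / ax1[3] - ax0[1] / ax0[3]
  expect_equal(dAR, 1.1 / 1.1^-0.5 - 1, tolerance = 0.005)
  # general affine map: inertia axes match the mapped ellipsoid's axes
  A <- matrix(c(1.2, 0.1, 0, 0, 0.9, 0.05, 0, 0, 0.95), 3, 3)
  axA <- set_shape_axes(mesh, ids, mesh$nodes %*% t(A))
  expect_equal(axA, sort(sqrt(eigen(A %*% t(A))$values), decreasing = TRUE),
               tolerance = 0.01)
})

test_that("volumetric strain: exact for uniform dilation, bounded for isochoric", {
  m <- homogeneous_block(10)
  a <- 1.03
  sol <- solve_static(m, apply_boundary_conditions(m$mesh, a * diag(3)),
                      solver_settings(n_steps = 1))
  expect_equal(volumetric_strain(sol, "all"), a^3 - 1, tolerance = 1e-10)
  # volume-preserving affine map: volumetric strain ~ 0 (exact kinematics)
  F <- diag(c(0.9^-0.5, 0.9^-0.5, 0.9))
  sol2 <- solve_static(m, apply_boundary_conditions(m$mesh, F),
                       solver_settings(n_steps = 1))
  expect_lt(abs(volumetric_strain(sol2, "all")), 1e-6)
  expect_error(volumetric_strain(sol, "nope"), "not found")
})

test_that("volume averaging weights by deformed element volumes", {
  fake <- structure(list(status = "converged", vol_def = c(1, 3),
                         vol_ref = c(10, 10),
                         model = list(mesh = list(sets = list(S = c(1L, 2L))))),
                    class = "micro_solution")
  expect_equal(volume_averaged_metric(fake, "S", c(4, 8)), 7)
  # uniform metric: the average is that value regardless of weights
  expect_equal(volume_averaged_metric(fake, "S", c(6, 6)), 6)
  fake$model$mesh$sets$empty <- integer(0)
  expect_error(volume_averaged_metric(fake, "empty"), "empty")
})

test_that("micro_metrics summarizes per-cell and per-region deformation", {
  g <- place_chondrons(1)
  model <- assign_materials(build_micro_mesh(g, 14), material_table())
  F <- diag(c(0.95^-0.5, 0.95^-0.5, 0.95))
  sol <- solve_static(model, apply_boundary_conditions(model$mesh, F),
                      fast_settings())
  mm <- micro_metrics(sol)
  expect_equal(nrow(mm), 1)
  expect_gt(mm$dAR_maj_min, 0)       # compression elongates laterally
  expect_lt(mm$vol_strain, 0.01)     # nearly isochoric load
  expect_gt(mm$eff_strain, mm$ecm_eff_strain)  # amplification
  expect_gt(mm$max_shear, 0)
  expect_gt(mm$eff_stress, 0)
  expect_equal(mm$status, "converged")
})
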