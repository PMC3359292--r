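write_csv_fixture <- function(dir) {
  mesh <- structured_hex_mesh(2, 1, 1, upper = c(2, 1, 1))
  nodes <- data.frame(id = seq_len(nrow(mesh$nodes)) - 1L,
                      x = mesh$nodes[, 1], y = mesh$nodes[, 2],
                      z = mesh$nodes[, 3])
  el <- data.frame(id = 0:1, mesh$elements - 1L, set = c("left", "right"))
  names(el)[2:9] <- paste0("n", 0:7)
  nf <- file.path(dir, "nodes.csv"); ef <- file.path(dir, "elements.csv")
  write.csv(nodes, nf, row.names = FALSE)
  write.csv(el, ef, row.names = FALSE)
  list(nodes = nf, elements = ef, mesh = mesh)
}

test_that("CSV fixtures load into a validated macro state", {
  dir <- withr::local_tempdir()
  fx <- write_csv_fixture(dir)
  disp <- data.frame(id = seq_len(12) - 1L, ux = 0.1 * fx$mesh$nodes[, 1],
                     uy = 0, uz = 0)
  df <- file.path(dir, "disp.csv")
  write.csv(disp, df, row.names = FALSE)
  st <- read_macro_state(list(nodes = fx$nodes, elements = fx$elements), df,
                         quiet = TRUE)
  expect_s3_class(st, "macro_state")
  expect_equal(nrow(st$mesh$nodes), 12)
  expect_equal(nrow(st$mesh$elements), 2)
  expect_named(st$mesh$sets, c("left", "right", "all"), ignore.order = TRUE)
  expect_equal(st$deformed[, 1], 1.1 * st$undeformed[, 1])
  # deformed positions given directly work the same way
  pos <- data.frame(id = seq_len(12) - 1L,
                    x = 1.1 * fx$mesh$nodes[, 1],
                    y = fx$mesh$nodes[, 2], z = fx$mesh$nodes[, 3])
  pf <- file.path(dir, "pos.csv")
  write.csv(pos, pf, row.names = FALSE)
  st2 <- read_macro_state(list(nodes = fx$nodes, elements = fx$elements),
                          pf, quiet = TRUE)
  expect_equal(st2$deformed, st$deformed)
})

test_that("VTK round trip preserves mesh, displacements and cell scalars", {
  dir <- withr::local_tempdir()
  mesh <- structured_hex_mesh(2, 2, 1, upper = c(2, 2, 1))
  u <- 0.05 * mesh$nodes
  f <- file.path(dir, "mesh.vtk")
  write_vtk(mesh, f, point_vectors = list(displacement = u),
            cell_scalars = list(metric = c(1.5, 2.5, NaN, -3)))
  back <- read_vtk(f)
  expect_equal(back$mesh$nodes, mesh$nodes)
  expect_equal(back$mesh$elements, mesh$elements)
  expect_equal(back$point_vectors$displacement, u)
  expect_equal(back$cell_scalars$metric[c(1, 2, 4)], c(1.5, 2.5, -3))
  expect_true(is.nan(back$cell_scalars$metric[3]))
  # the displacement field is picked up as the deformed state
  st <- read_macro_state(f, quiet = TRUE)
  expect_equal(st$deformed, mesh$nodes + u)
})

test_that("non-hexahedral cells are rejected with a descriptive error", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "wedge.vtk")
  writeLines(c("# vtk DataFile Version 3.0", "wedge", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               "POINTS 6 double",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1", "1 0 1", "0 1 1",
               "CELLS 1 7", "6 0 1 2 3 4 5",
               "CELL_TYPES 1", "13"), f)
  expect_error(read_vtk(f), "unsupported")
})

test_that("affine fields give the exact F on every element, identity gives none", {
  F0 <- matrix(c(0.95, 0.02, 0, 0.01, 1.04, -0.03, 0, 0.02, 0.9), 3, 3)
  fx <- synthetic_macro_solution(3, 2, 2, analytic_deformation("affine",
                                                               F0 = F0))
  tbl <- element_deformation_gradients(fx$state, "all", "centroid")
  for (r in seq_along(tbl$element))
    expect_lt(max(abs(defgrad_tensor(tbl, r) - F0)), 1e-12)
  # undeformed state: all identity, zero deviation
  st0 <- macro_state(fx$state$mesh, deformed = fx$state$mesh$nodes)
  tbl0 <- element_deformation_gradients(st0, "all", "centroid")
  expect_equal(max(tbl0$deviation), 0)
  expect_length(filter_deforming_elements(tbl0, 1e-3)$element, 0)
})

test_that("centroid-sampled F converges to the analytic field under refinement", {
  # sinusoidal bending-like field: F13 = A w cos(w X3), not representable
  # by a single trilinear element, so sampling error must shrink with h
  A <- 0.5; w <- 0.35
  def <- structure(list(
    map = function(X) cbind(X[, 1] + A * sin(w * X[, 3]), X[, 2], X[, 3]),
    F = function(X) { Fb <- diag(3); Fb[1, 3] <- A * w * cos(w * X[3]); Fb },
    mode = "sinusoid"), class = "analytic_deformation")
  errs <- sapply(c(2, 4, 8), function(n) {
    fx <- synthetic_macro_solution(1, 1, n, def)
    tbl <- element_deformation_gradients(fx$state, "all", "centroid")
    mesh <- fx$state$mesh
    e <- 0
    for (r in seq_along(tbl$element)) {
      ctr <- colMeans(element_coords(mesh, tbl$element[r]))
      e <- max(e, max(abs(defgrad_tensor(tbl, r) - def$F(ctr))))
    }
    e
  })
  expect_true(all(diff(errs) < 0))
  # observed order >= 1: halving h at least halves the error
  expect_gt(errs[1] / errs[2], 2)
  expect_gt(errs[2] / errs[3], 2)
})

test_that("quadratic bending is captured exactly at element centroids", {
  fx <- synthetic_macro_solution(2, 2, 4,
                                 analytic_deformation("bending", kappa = 0.04))
  tbl <- element_deformation_gradients(fx$state, "all", "centroid")
  mesh <- fx$state$mesh
  for (r in seq_along(tbl$element)) {
    ctr <- colMeans(element_coords(mesh, tbl$element[r]))
    expect_lt(max(abs(defgrad_tensor(tbl, r) - fx$oracle_F(ctr))), 1e-12)
  }
})

test_that("the deformation filter matches a brute-force check and is monotone", {
  set.seed(21)
  F0 <- diag(3); F0[1, 1] <- 1.05
  fx <- synthetic_macro_solution(3, 3, 1, analytic_deformation("affine",
                                                               F0 = F0))
  mesh <- fx$state$mesh
  # mix: some elements deformed, some identity (move only right-half nodes)
  def2 <- mesh$nodes
  right <- mesh$nodes[, 1] > 5
  def2[right, 1] <- def2[right, 1] + 0.4 * (def2[right, 1] - 5)
  st <- macro_state(mesh, deformed = def2)
  tbl <- element_deformation_gradients(st, "all", "centroid")
  for (tol in c(1e-4, 1e-3, 1e-2, 0.1)) {
    kept <- filter_deforming_elements(tbl, tol)
    brute <- sum(vapply(seq_along(tbl$element), function(r)
      max(abs(defgrad_tensor(tbl, r) - diag(3))) > tol, TRUE))
    expect_length(kept$element, brute)
  }
  # monotone: larger tol never keeps more
  tols <- sort(stats::runif(10, 1e-5, 0.5))
  counts <- vapply(tols, function(t)
    length(filter_deforming_elements(tbl, t)$element), 1L)
  expect_true(all(diff(counts) <= 0))
  # a single component 2*tol above identity is kept
  tbl1 <- tbl
  tbl1$F[1, 1, , ] <- diag(3); tbl1$F[1, 1, 1, 1] <- 1 + 2e-3
  tbl1$deviation[1] <- 2e-3
  expect_true(tbl1$element[1] %in% filter_deforming_elements(tbl1, 1e-3)$element)
})

test_that("variation residual over Gauss-point tensors matches brute force", {
  F0 <- diag(c(0.95, 1, 1.02))
  fx <- synthetic_macro_solution(2, 1, 1, analytic_deformation("affine",
                                                               F0 = F0))
  tbl <- element_deformation_gradients(fx$state, "all", "gauss8")
  # affine field: eight identical tensors, zero residual
  expect_equal(max(variation_residual(tbl)), 0)
  # seven identity + one with F11 = 1.1: residual is exactly 0.1
  tbl2 <- tbl
  for (k in 1:8) tbl2$F[1, k, , ] <- diag(3)
  tbl2$F[1, 1, 1, 1] <- 1.1
  expect_equal(variation_residual(tbl2)[1], 0.1)
  # random tensors vs brute-force double loop
  set.seed(22)
  tbl2$F[2, , , ] <- array(stats::rnorm(8 * 9), c(8, 3, 3))
  brute <- 0
  for (a in 1:7) for (b in (a + 1):8)
    brute <- max(brute, sum(abs(tbl2$F[2, a, , ] - tbl2$F[2, b, , ])))
  expect_equal(variation_residual(tbl2)[2], brute)
  # centroid-sampled tables are refused
  tblc <- element_deformation_gradients(fx$state, "all", "centroid")
  expect_error(variation_residual(tblc), "gauss8")
})

test_that("deformation-gradient tables export to CSV with 9 components", {
  dir <- withr::local_tempdir()
  F0 <- diag(c(0.9, 1, 1.1))
  fx <- synthetic_macro_solution(2, 1, 1, analytic_deformation("affine",
                                                               F0 = F0))
  tbl <- element_deformation_gradients(fx$state, "all", "centroid")
  f <- file.path(dir, "F.csv")
  write_defgrad_csv(tbl, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$F11, c(0.9, 0.9))
  expect_equal(back$F33, c(1.1, 1.1))
})
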