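# Independent oracles and small fixture builders used across the suite.

# 8 x 3 corner coordinates of the box [0,a]x[0,b]x[0,c], standard ordering.
box_coords <- function(a = 1, b = 1, c = 1) {
  signs <- (cellscale:::HEX_CORNERS + 1) / 2
  cbind(a * signs[, 1], b * signs[, 2], c * signs[, 3])
}

# 5-tetrahedron decomposition volume of a planar-faced hexahedron.
tet_decomposition_volume <- function(coords) {
  tets <- rbind(c(1, 2, 4, 5), c(2, 3, 4, 7), c(2, 6, 7, 5),
                c(4, 7, 8, 5), c(2, 4, 7, 5))
  v <- 0
  for (r in seq_len(nrow(tets))) {
    p <- coords[tets[r, ], ]
    v <- v + abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ],
                           p[4, ] - p[1, ]))) / 6
  }
  v
}

# central finite differences of the shape functions at a natural point
fd_shape_gradients <- function(p, h = 1e-6) {
  g <- matrix(0, 8, 3)
  for (j in 1:3) {
    pp <- p; pm <- p
    pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    g[, j] <- (hex_shape_values(pp) - hex_shape_values(pm)) / (2 * h)
  }
  g
}

# uniform random rotation matrix (QR with positive diagonal, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Mooney-Rivlin strain energy (uncoupled, U = K/2 ln^2 J)
mr_energy <- function(F, c1, c2, K) {
  J <- det(F)
  C <- t(F) %*% F
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(diag(C %*% C)))
  c1 * (J^(-2 / 3) * I1 - 3) + c2 * (J^(-4 / 3) * I2 - 3) + K / 2 * log(J)^2
}

# Cauchy stress by numerical differentiation of the energy:
# P = dW/dF (central differences), sigma = P F' / J
fd_cauchy_stress <- function(F, c1, c2, K, h = 1e-7) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fm <- F
    Fp[i, j] <- Fp[i, j] + h; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (mr_energy(Fp, c1, c2, K) - mr_energy(Fm, c1, c2, K)) / (2 * h)
  }
  P %*% t(F) / det(F)
}

# Homogeneous uniaxial-stress state of the compressible model: minimize the
# energy over the lateral stretch and differentiate for the axial Cauchy
# stress. Mesh-free oracle for the unconfined FE solution.
uniaxial_1d_oracle <- function(lam, c1, c2, K) {
  W <- function(ll) mr_energy(diag(c(ll, ll, lam)), c1, c2, K)
  ll <- stats::optimize(W, c(0.4, 2.5), tol = 1e-12)$minimum
  h <- 1e-6
  Wl <- function(l3) mr_energy(diag(c(ll, ll, l3)), c1, c2, K)
  dWdlam <- (Wl(lam + h) - Wl(lam - h)) / (2 * h)
  J <- ll^2 * lam
  list(sigma_zz = lam / J * dWdlam, lateral = ll, J = J)
}

# voxel sphere mesh: structured grid over [-half, half]^3 with the element
# set "sphere" = elements whose centroid lies inside radius R
voxel_sphere_mesh <- function(r, R = 1, half = 1.02) {
  mesh <- structured_hex_mesh(r, r, r, lower = rep(-half, 3),
                              upper = rep(half, 3))
  h <- 2 * half / r
  ctr <- as.matrix(expand.grid(x = (seq_len(r) - 0.5) * h - half,
                               y = (seq_len(r) - 0.5) * h - half,
                               z = (seq_len(r) - 0.5) * h - half))
  mesh$sets$sphere <- which(rowSums(ctr^2) <= R^2)
  mesh
}

# quick solver settings for warm-started single-increment solves in tests
fast_settings <- function(n_steps = 1L) {
  solver_settings(n_steps = n_steps, max_iter = 80L, refactor_ratio = 0.95)
}

# homogeneous block micro model with a single-material table
homogeneous_block <- function(r = 10L, mat = c(c1 = 1.6892, c2 = 0,
                                               K = 83.3333)) {
  g <- place_chondrons(0)
  tb <- material_table(ecm = mat, pcm = mat, cell = mat)
  assign_materials(build_micro_mesh(g, r), tb)
}

# 5-point Gauss-Legendre rule on [-1, 1] (classical values), used as a
# dense quadrature oracle for the isoparametric volume integral
gauss_legendre5 <- function() {
  list(nodes = c(-0.906179845938664, -0.538469310105683, 0,
                 0.538469310105683, 0.906179845938664),
       weights = c(0.236926885056189, 0.478628670499366, 0.568888888888889,
                   0.478628670499366, 0.236926885056189))
}
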