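# Element matrices for the prestressed network model.
#
# Units: length nm, force nN, hence moduli and stresses in nN/nm^2 (= GPa).
# Node DOF order: [ux, uy, uz, rx, ry, rz], 6 per node.

# 12x12 local stiffness of a 3D Euler-Bernoulli beam (circular section).
beam_local_stiffness <- function(E, G, A, I, J, L) {
  K <- matrix(0, 12, 12)
  add <- function(K, rows, m) { K[rows, rows] <- K[rows, rows] + m; K }
  # axial
  ka <- E * A / L
  K[c(1, 7), c(1, 7)] <- K[c(1, 7), c(1, 7)] + ka * matrix(c(1, -1, -1, 1), 2)
  # torsion
  kt <- G * J / L
  K[c(4, 10), c(4, 10)] <- K[c(4, 10), c(4, 10)] +
    kt * matrix(c(1, -1, -1, 1), 2)
  # bending in local x-y plane (v, theta_z)
  kb <- E * I / L^3
  Bz <- kb * matrix(c(
    12,    6 * L, -12,    6 * L,
    6 * L, 4 * L^2, -6 * L, 2 * L^2,
    -12,  -6 * L,  12,   -6 * L,
    6 * L, 2 * L^2, -6 * L, 4 * L^2), 4, 4, byrow = TRUE)
  K <- add(K, c(2, 6, 8, 12), Bz)
  # bending in local x-z plane (w, theta_y); L-term signs flip
  By <- kb * matrix(c(
    12,   -6 * L, -12,   -6 * L,
    -6 * L, 4 * L^2, 6 * L, 2 * L^2,
    -12,   6 * L,  12,    6 * L,
    -6 * L, 2 * L^2, 6 * L, 4 * L^2), 4, 4, byrow = TRUE)
  K <- add(K, c(3, 5, 9, 11), By)
  K
}

# Consistent geometric stiffness of a beam carrying axial force N (tension
# positive); stiffens both transverse bending planes.
beam_geometric_stiffness <- function(N, L) {
  K <- matrix(0, 12, 12)
  if (N == 0) return(K)
  g <- N / L
  Gz <- g * matrix(c(
    6 / 5,   L / 10, -6 / 5,   L / 10,
    L / 10,  2 * L^2 / 15, -L / 10, -L^2 / 30,
    -6 / 5, -L / 10,  6 / 5,  -L / 10,
    L / 10, -L^2 / 30, -L / 10, 2 * L^2 / 15), 4, 4, byrow = TRUE)
  K[c(2, 6, 8, 12), c(2, 6, 8, 12)] <- Gz
  Gy <- g * matrix(c(
    6 / 5,  -L / 10, -6 / 5,  -L / 10,
    -L / 10, 2 * L^2 / 15, L / 10, -L^2 / 30,
    -6 / 5,  L / 10,  6 / 5,   L / 10,
    -L / 10, -L^2 / 30, L / 10, 2 * L^2 / 15), 4, 4, byrow = TRUE)
  K[c(3, 5, 9, 11), c(3, 5, 9, 11)] <- Gy
  K
}

# Rotation of a 12-DOF beam matrix from local to global axes.
beam_rotation <- function(p1, p2) {
  ex <- p2 - p1
  L <- sqrt(sum(ex^2))
  ex <- ex / L
  ref <- if (abs(ex[3]) < 0.99) c(0, 0, 1) else c(1, 0, 0)
  ey <- c(ref[2] * ex[3] - ref[3] * ex[2],
          ref[3] * ex[1] - ref[1] * ex[3],
          ref[1] * ex[2] - ref[2] * ex[1])
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- rbind(ex, ey, ez)
  T <- matrix(0, 12, 12)
  for (b in 0:3) T[b * 3 + 1:3, b * 3 + 1:3] <- R
  list(T = T, L = L)
}

# Assembled (global) material + geometric stiffness of one beam element.
beam_element <- function(p1, p2, E, G, A, I, J, N_axial) {
  rt <- beam_rotation(p1, p2)
  Kl <- beam_local_stiffness(E, G, A, I, J, rt$L) +
    beam_geometric_stiffness(N_axial, rt$L)
  t(rt$T) %*% Kl %*% rt$T
}

# Constant-strain triangle geometry: area and shape-function gradients.
cst_geometry <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
  c_ <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
  A2 <- x[1] * b[1] + x[2] * b[2] + x[3] * b[3]   # 2*area (signed)
  if (abs(A2) < 1e-12)
    afm_error("afm_mesh_error", "degenerate membrane triangle")
  list(area = abs(A2) / 2,
       G = rbind(b, c_) / A2)   # 2x3 gradient operator dN/dx, dN/dy
}

# 6x6 plane-stress CST membrane stiffness (dofs u1 v1 u2 v2 u3 v3).
cst_membrane_stiffness <- function(xy, E, nu, t) {
  g <- cst_geometry(xy)
  B <- matrix(0, 3, 6)
  B[1, c(1, 3, 5)] <- g$G[1, ]
  B[2, c(2, 4, 6)] <- g$G[2, ]
  B[3, c(1, 3, 5)] <- g$G[2, ]
  B[3, c(2, 4, 6)] <- g$G[1, ]
  D <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3)
  t * g$area * t(B) %*% D %*% B
}

# 3x3 per-displacement-component geometric stiffness of a prestressed
# membrane triangle under isotropic tension sigma0 * t (nN/nm).
cst_geometric_stiffness <- function(xy, tension) {
  g <- cst_geometry(xy)
  tension * g$area * t(g$G) %*% g$G
}
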