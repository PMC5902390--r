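# Internal-coordinate geometry: atom placement and rigid-body transforms.

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector", call. = FALSE)
  v / n
}

# Position of a new atom D given three placed atoms A-B-C, the bond length
# C-D, the bond angle B-C-D (degrees) and the dihedral A-B-C-D (degrees).
# Standard natural-extension-reference-frame construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# angle at b (degrees) of the triangle a-b-c
atom_angle <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Rotation matrix taking unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  u <- unitv(u); v <- unitv(v)
  w <- pracma_cross(u, v)
  s <- vnorm(w)
  cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to u
    axis <- if (abs(u[1]) < 0.9) unitv(pracma_cross(u, c(1, 0, 0)))
            else unitv(pracma_cross(u, c(0, 1, 0)))
    K <- matrix(c(0, -axis[3], axis[2],
                  axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  axis <- w / s
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(acos(max(-1, min(1, cth)))) * K +
    (1 - cth) * K %*% K
}

rotation_about_axis <- function(axis, theta_deg) {
  axis <- unitv(axis)
  th <- theta_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Apply rotation R (about the origin) then translation t to an n x 3 matrix.
transform_xyz <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, t, `+`)
}
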