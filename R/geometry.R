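# Small 3D geometry toolkit shared by the builders and descriptors.
# All coordinates are orthonormal angstroms; angles are degrees.

DEG <- pi / 180

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize zero vector")
  a / n
}

#' Angle at b formed by points a-b-c, in degrees
#' @noRd
bond_angle <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

#' Signed dihedral a-b-c-d in degrees, in (-180, 180]
#' @noRd
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  x <- sum(n1 * n2); y <- sum(vcross(n1, n2) * unitv(b2))
  ang <- atan2(y, x) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# Natural-extension (NeRF) placement: position of atom d bonded to c, given
# bond length |cd|, angle b-c-d and dihedral a-b-c-d.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  ang <- angle * DEG; dih <- dihedral * DEG
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rotation matrix about an axis through the origin
#' @noRd
rotation_matrix <- function(axis, angle) {
  u <- unitv(axis)
  th <- angle * DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Apply R then translate, to an n x 3 coordinate matrix.
transform_coords <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}

coords_of <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

set_coords <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# Orthogonalization matrix of a unit cell (a along x, b in the xy plane):
# cartesian = M %*% fractional.
cell_orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * DEG; be <- cell[5] * DEG; ga <- cell[6] * DEG
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    a, b * cos(ga), cc * cos(be),
    0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0,           cc * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

cell_volume <- function(cell) {
  det(cell_orth_matrix(cell))
}

# Deterministic quasi-uniform unit-sphere point set (spherical Fibonacci
# lattice); used by the SASA and surface-dot kernels.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
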