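# Small 3D geometry helpers used across the package. Coordinates are plain
# numeric length-3 vectors or n x 3 matrices, always in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle between four points
#'
#' Standard signed torsion p1-p2-p3-p4 in degrees, in (-180, 180].
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return angle in degrees.
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

angle_deg <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Best-fit plane through a point cloud; returns list(center, normal).
fit_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(center = ctr, normal = sv$v[, 3])
}

# Rotation matrix for angle theta (radians) about unit axis.
rotation_about_axis <- function(axis, theta) {
  u <- unitv(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Angle between two planes' normals folded into [0, 90] degrees.
interplane_angle <- function(n1, n2) {
  a <- angle_deg(n1, c(0, 0, 0), n2)
  if (a > 90) a <- 180 - a
  a
}
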