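# Low-level 3D geometry helpers (internal).

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

# NeRF atom placement: position D given A, B, C with bond |C-D|,
# angle B-C-D and dihedral A-B-C-D.
.nerf <- function(A, B, C, bond, angle, dihedral) {
  th <- .deg2rad(angle)
  ph <- .deg2rad(dihedral)
  bc <- .unit(C - B)
  n <- .unit(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  d <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Rotation matrix for angle deg about unit axis (Rodrigues).
.rotmat <- function(axis, deg) {
  u <- .unit(axis)
  th <- .deg2rad(deg)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation matrix taking unit vector a onto unit vector b.
.rot_between <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- .cross3(a, b)
  s <- sqrt(sum(v^2))
  co <- sum(a * b)
  if (s < 1e-12) {
    if (co > 0) return(diag(3))
    # 180 degrees: rotate about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(.rotmat(.cross3(a, p), 180))
  }
  .rotmat(v, .rad2deg(atan2(s, co)))
}

# Unsigned angle (degrees, in [0, 180]) between two vectors.
.vec_angle <- function(a, b) {
  co <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  .rad2deg(acos(max(-1, min(1, co))))
}

# Apply rotation R (about `center`) then translation t to an n x 3 matrix.
.transform_xyz <- function(xyz, R = diag(3), t = c(0, 0, 0), center = c(0, 0, 0)) {
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center + t, "+")
}

# Squared-distance matrix between two n x 3 coordinate blocks.
.dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
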