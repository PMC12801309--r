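# Small geometry kernel: rotations, dihedrals, plane fitting.

.norm3 <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .norm3(v)
  if (n < 1e-12) stop("cannot normalize near-zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#' @param axis 3-vector (normalized internally).
#' @param theta angle in radians.
#' @return 3x3 rotation matrix (Rodrigues form).
#' @keywords internal
rot_axis <- function(axis, theta) {
  u <- .unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

.rot_z <- function(theta) rot_axis(c(0, 0, 1), theta)

# signed angle from a to b about axis n (radians)
.signed_angle <- function(a, b, n) {
  a <- .unit(a); b <- .unit(b); n <- .unit(n)
  atan2(sum(.cross3(a, b) * n), sum(a * b))
}

#' Dihedral (torsion) angle of four points
#'
#' Standard IUPAC sign convention: looking from b to c, the angle from the
#' plane (a,b,c) to (b,c,d); cis = 0, trans = 180.
#'
#' @param a,b,c,d 3-vectors (nm).
#' @return angle in degrees in (-180, 180].
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Least-squares plane through a point set
#'
#' Fits the best plane by SVD of the centred coordinates; the plane normal
#' is the singular vector of the smallest singular value.
#'
#' @param xyz n x 3 matrix (n >= 3).
#' @return list with `centroid`, unit `normal`, and `rms` out-of-plane
#'   residual (nm).
#' @export
fit_plane <- function(xyz) {
  stopifnot(nrow(xyz) >= 3)
  cen <- colMeans(xyz)
  m <- sweep(xyz, 2, cen)
  sv <- svd(m)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("points are (near-)collinear; no unique plane")
  normal <- sv$v[, 3]
  resid <- m %*% normal
  list(centroid = cen, normal = as.numeric(normal),
       rms = sqrt(mean(resid^2)))
}

# wrap degrees into (-180, 180]
.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}
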