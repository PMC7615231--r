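#' Quaternion geometry for probe-orientation tracking
#'
#' Probe orientation is carried as a unit quaternion q = (q_w, q_x, q_y, q_z)
#' in the Hamilton (right-handed) convention, scalar component first. A
#' quaternion is a plain numeric vector of length 4; most functions also
#' accept an N x 4 matrix of quaternions (one per row) and vectorize over
#' rows. q and -q encode the same 3-D rotation (double cover);
#' [quat_canonicalize()] resolves the ambiguity by forcing q_w >= 0.
#'
#' @name quat
NULL

.quat_mat <- function(q) {
  if (is.null(dim(q))) {
    stopifnot(length(q) == 4L)
    q <- matrix(q, nrow = 1L)
  }
  if (ncol(q) != 4L) stop("quaternions must have 4 components (w, x, y, z)")
  if (!all(is.finite(q))) stop("invalid quaternion: non-finite components")
  q
}

.quat_out <- function(m, vec) if (vec) drop(m[1L, ]) else m

#' Construct a unit quaternion
#'
#' Normalizes the components to unit 2-norm. Use `canonical = TRUE` to also
#' apply the sign convention q_w >= 0.
#'
#' @param w,x,y,z scalar components (or vectors of equal length).
#' @param canonical apply sign canonicalization (default `TRUE`).
#' @return numeric vector of length 4 (or N x 4 matrix for vector input).
#' @export
quat <- function(w, x = 0, y = 0, z = 0, canonical = TRUE) {
  m <- cbind(w, x, y, z)
  n <- sqrt(rowSums(m^2))
  if (any(n < 1e-12)) stop("cannot normalize a zero quaternion")
  m <- m / n
  if (canonical) m <- .quat_mat_canonicalize(m)
  colnames(m) <- NULL
  .quat_out(m, length(w) == 1L)
}

#' Identity quaternion
#' @return the quaternion (1, 0, 0, 0).
#' @export
quat_identity <- function() c(1, 0, 0, 0)

.quat_mat_canonicalize <- function(m) {
  # sign rule: w >= 0; ties broken by the first nonzero component
  flip <- m[, 1L] < 0
  zw <- abs(m[, 1L]) < 1e-12
  if (any(zw)) {
    for (j in 2L:4L) {
      sel <- zw & abs(m[, j]) >= 1e-12
      flip[sel] <- m[sel, j] < 0
      zw <- zw & !sel
    }
  }
  m[flip, ] <- -m[flip, , drop = FALSE]
  m
}

#' Canonicalize quaternion sign
#'
#' q and -q encode the same rotation; this picks the representative with
#' q_w >= 0 (if q_w is zero, the first nonzero component is made positive),
#' so regression targets never flip sign mid-sequence.
#'
#' @param q quaternion or N x 4 matrix.
#' @return same shape as input.
#' @export
quat_canonicalize <- function(q) {
  vec <- is.null(dim(q))
  .quat_out(.quat_mat_canonicalize(.quat_mat(q)), vec)
}

#' Quaternion conjugate
#'
#' Returns (w, -x, -y, -z); for a unit quaternion this is the inverse
#' rotation. The operation is an involution.
#'
#' @param q quaternion or N x 4 matrix.
#' @return same shape as input.
#' @export
quat_conjugate <- function(q) {
  vec <- is.null(dim(q))
  m <- .quat_mat(q)
  m[, 2L:4L] <- -m[, 2L:4L]
  .quat_out(m, vec)
}

#' Hamilton product of two quaternions
#'
#' `quat_multiply(q1, q2)` composes rotations so that q2 is applied after q1
#' in the relative-rotation convention r_t = conj(q_{t-1}) * q_t. The result
#' is renormalized to unit norm.
#'
#' @param q1,q2 quaternions (vectors or N x 4 matrices; rows recycled if one
#'   input is a single quaternion).
#' @return quaternion product, unit-normalized.
#' @export
quat_multiply <- function(q1, q2) {
  vec <- is.null(dim(q1)) && is.null(dim(q2))
  a <- .quat_mat(q1); b <- .quat_mat(q2)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  w <- a[,1]*b[,1] - a[,2]*b[,2] - a[,3]*b[,3] - a[,4]*b[,4]
  x <- a[,1]*b[,2] + a[,2]*b[,1] + a[,3]*b[,4] - a[,4]*b[,3]
  y <- a[,1]*b[,3] - a[,2]*b[,4] + a[,3]*b[,1] + a[,4]*b[,2]
  z <- a[,1]*b[,4] + a[,2]*b[,3] - a[,3]*b[,2] + a[,4]*b[,1]
  m <- cbind(w, x, y, z)
  m <- m / sqrt(rowSums(m^2))
  colnames(m) <- NULL
  .quat_out(m, vec)
}

#' Angular distance between two orientations
#'
#' The geodesic rotation angle 2 * acos(|<q1, q2>|) in degrees. Symmetric and
#' invariant to the sign of either quaternion; the dot product is clamped to
#' \[-1, 1\] before acos to absorb floating-point drift.
#'
#' @param q1,q2 unit quaternions (vectors or N x 4 matrices).
#' @return angle in degrees in \[0, 180\].
#' @export
quat_angle <- function(q1, q2) {
  a <- .quat_mat(q1); b <- .quat_mat(q2)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  d <- pmin(1, pmax(-1, abs(rowSums(a * b))))
  ang <- 2 * acos(d) * 180 / pi
  if (is.null(dim(q1)) && is.null(dim(q2))) ang[1L] else ang
}

#' Relative rotation between consecutive probe orientations
#'
#' Returns the rotation step r with q_prev * r = q_curr (up to the double
#' cover), i.e. r = conj(q_prev) * q_curr, sign-canonicalized, together with
#' its rotation magnitude in degrees.
#'
#' @param q_prev,q_curr unit quaternions.
#' @return a `rotation_step`: list with elements `r` (unit quaternion) and
#'   `angle_deg` (in \[0, 180\]).
#' @export
quat_relative <- function(q_prev, q_curr) {
  r <- quat_canonicalize(quat_multiply(quat_conjugate(q_prev), q_curr))
  structure(list(r = r, angle_deg = quat_angle(q_prev, q_curr)),
            class = "rotation_step")
}

#' @export
print.rotation_step <- function(x, ...) {
  cat(sprintf("rotation step: %.3f deg about axis (%.3f, %.3f, %.3f)\n",
              x$angle_deg,
              x$r[2], x$r[3], x$r[4]))
  invisible(x)
}

#' Rotation from axis and angle
#'
#' @param axis length-3 numeric axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) return(quat_identity())
  axis <- axis / n
  h <- angle_deg * pi / 360
  c(cos(h), sin(h) * axis)
}

#' Does a predicted rotation step move the probe toward the target plane?
#'
#' A predicted step `r_hat` applied at `q_prev` counts as correct guidance if
#' it does not increase the angular distance to the target orientation
#' (non-strict inequality, so the identity step counts as toward).
#'
#' @param q_prev current probe orientation (unit quaternion).
#' @param r_hat predicted rotation step: a `rotation_step`, or a unit
#'   quaternion.
#' @param q_target target orientation (unit quaternion).
#' @return logical flag.
#' @export
is_toward_target <- function(q_prev, r_hat, q_target) {
  if (inherits(r_hat, "rotation_step")) r_hat <- r_hat$r
  quat_angle(quat_multiply(q_prev, r_hat), q_target) <=
    quat_angle(q_prev, q_target)
}

#' Spherical linear interpolation between orientations
#'
#' Interpolates along the shorter great-circle arc so that the angular
#' distance from `q1` grows linearly in `fraction`. Fractions outside
#' \[0, 1\] extrapolate along the same geodesic (used to construct
#' away-from-target steps). Near-antipodal inputs (angle > 179.9 deg) have no
#' unique shortest arc; a fixed orthogonal intermediate axis is used there.
#'
#' @param q1,q2 unit quaternions.
#' @param fraction interpolation parameter (0 gives `q1`, 1 gives `q2`).
#' @return unit quaternion.
#' @export
quat_slerp <- function(q1, q2, fraction) {
  a <- as.numeric(.quat_mat(q1)[1L, ]); b <- as.numeric(.quat_mat(q2)[1L, ])
  d <- sum(a * b)
  if (d < 0) { b <- -b; d <- -d }  # shorter arc
  d <- min(1, d)
  ang <- acos(d)
  if (ang > 179.9 * pi / 180) {
    # antipodal: route through a fixed orthogonal waypoint
    ortho <- c(-a[2], a[1], -a[4], a[3])
    ortho <- ortho / sqrt(sum(ortho^2))
    if (fraction <= 0.5) return(quat_slerp(a, ortho, 2 * fraction))
    return(quat_slerp(ortho, b, 2 * fraction - 1))
  }
  if (ang < 1e-8) {
    out <- (1 - fraction) * a + fraction * b
    return(out / sqrt(sum(out^2)))
  }
  s <- sin(ang)
  out <- sin((1 - fraction) * ang) / s * a + sin(fraction * ang) / s * b
  out / sqrt(sum(out^2))
}

#' Uniform random unit quaternions
#'
#' Draws from the uniform (Haar) distribution on SO(3) via normalized 4-D
#' Gaussians, sign-canonicalized.
#'
#' @param n number of quaternions.
#' @return N x 4 matrix (a plain vector if `n = 1`).
#' @export
quat_random <- function(n = 1L) {
  m <- matrix(stats::rnorm(4L * n), ncol = 4L)
  m <- m / sqrt(rowSums(m^2))
  m <- .quat_mat_canonicalize(m)
  .quat_out(m, n == 1L)
}

#' Rotation matrix of a unit quaternion
#'
#' The standard 3 x 3 rotation matrix of q in the Hamilton convention.
#' Mainly useful for cross-checking quaternion algebra against matrix
#' algebra.
#'
#' @param q unit quaternion.
#' @return 3 x 3 orthogonal matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- as.numeric(.quat_mat(q)[1L, ])
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
    2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
    2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}
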