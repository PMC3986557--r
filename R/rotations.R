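# Coordinate conventions used throughout the package
# --------------------------------------------------
# World frame: right-handed, origin at the screen center.
#   x : the rest gaze direction, pointing from the viewer toward the screen
#   y : the viewer's left
#   z : up
# The screen is the plane x = 0; a viewer at the chin-rest stands near
# (-140, 0, 0) cm and a screen-facing head has all Euler angles equal to 0.
#
# Euler convention: intrinsic Z-Y-X. psi (yaw) about z/up, theta (pitch)
# about y, phi (roll) about the forward axis x, i.e.
#   R = Rz(psi) %*% Ry(theta) %*% Rx(phi).
# Positive theta pitches the forward axis downward (toward -z); positive psi
# yaws it toward +y (the viewer's left). Gimbal lock sits at theta = +/-90
# (looking straight up or down), which realistic head poses never reach.
#
# All public interfaces use degrees; internals use radians.

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

#' Normalize angles to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector with each element reduced modulo 360 into
#'   `(-180, 180]`.
#' @export
normalize_angle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

#' Rotation matrix from Euler angles
#'
#' Builds the intrinsic Z-Y-X rotation `Rz(psi) Ry(theta) Rx(phi)` used for
#' head and eye orientations. `psi` is yaw about the world up axis, `theta`
#' pitch, `phi` roll about the forward axis.
#'
#' @param phi,theta,psi angles in degrees (roll, pitch, yaw).
#' @return a 3x3 orthonormal rotation matrix with determinant 1.
#' @export
#' @examples
#' rotation_from_euler(0, 0, 0)      # identity
#' rotation_from_euler(0, 0, 90)     # forward axis mapped to +y
rotation_from_euler <- function(phi, theta, psi) {
  stopifnot(length(phi) == 1, length(theta) == 1, length(psi) == 1)
  if (!all(is.finite(c(phi, theta, psi)))) {
    stop("Euler angles must be finite")
  }
  matrix(rot_batch(phi, theta, psi), nrow = 3, ncol = 3)
}

# Vectorized rotation construction. Angles in degrees, vectors of common
# length n; returns an n x 9 matrix with columns r11, r21, r31, r12, ...,
# r33 (column-major order of the 3x3 matrix), so row i reshapes to the
# rotation of sample i via matrix(x[i, ], 3, 3).
rot_batch <- function(phi, theta, psi) {
  cf <- cos(deg2rad(phi));   sf <- sin(deg2rad(phi))
  ct <- cos(deg2rad(theta)); st <- sin(deg2rad(theta))
  cp <- cos(deg2rad(psi));   sp <- sin(deg2rad(psi))
  cbind(
    r11 = cp * ct,
    r21 = sp * ct,
    r31 = -st,
    r12 = cp * st * sf - sp * cf,
    r22 = sp * st * sf + cp * cf,
    r32 = ct * sf,
    r13 = cp * st * cf + sp * sf,
    r23 = sp * st * cf - cp * sf,
    r33 = ct * cf
  )
}

# Batched rotation composition: row-wise A %*% B for n x 9 rotation sets.
# Either argument may have one row (recycled).
rot_mult <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), , drop = FALSE]
  out <- matrix(0, n, 9)
  for (i in 1:3) {       # output column block i (columns of B)
    for (r in 1:3) {     # output row r
      # (AB)[r,i] = sum_k A[r,k] B[k,i]
      out[, (i - 1) * 3 + r] <-
        a[, r] * b[, (i - 1) * 3 + 1] +
        a[, 3 + r] * b[, (i - 1) * 3 + 2] +
        a[, 6 + r] * b[, (i - 1) * 3 + 3]
    }
  }
  colnames(out) <- colnames(rot_batch(0, 0, 0))
  out
}

# Row-wise R %*% v for an n x 9 rotation set and n x 3 (or 1 x 3) vectors.
rot_apply <- function(r, v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  n <- max(nrow(r), nrow(v))
  if (nrow(v) == 1 && n > 1) v <- v[rep(1, n), , drop = FALSE]
  if (nrow(r) == 1 && n > 1) r <- r[rep(1, n), , drop = FALSE]
  cbind(
    r[, 1] * v[, 1] + r[, 4] * v[, 2] + r[, 7] * v[, 3],
    r[, 2] * v[, 1] + r[, 5] * v[, 2] + r[, 8] * v[, 3],
    r[, 3] * v[, 1] + r[, 6] * v[, 2] + r[, 9] * v[, 3]
  )
}

# Row-wise t(R) %*% v (world -> body frame).
rot_tapply <- function(r, v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  n <- max(nrow(r), nrow(v))
  if (nrow(v) == 1 && n > 1) v <- v[rep(1, n), , drop = FALSE]
  if (nrow(r) == 1 && n > 1) r <- r[rep(1, n), , drop = FALSE]
  cbind(
    r[, 1] * v[, 1] + r[, 2] * v[, 2] + r[, 3] * v[, 3],
    r[, 4] * v[, 1] + r[, 5] * v[, 2] + r[, 6] * v[, 3],
    r[, 7] * v[, 1] + r[, 8] * v[, 2] + r[, 9] * v[, 3]
  )
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [rotation_from_euler()]. At gimbal lock (pitch exactly
#' +/-90 degrees) yaw and roll are not separable; the canonical branch
#' `psi = 0` is returned, never an error.
#'
#' @param R a 3x3 orthonormal rotation matrix.
#' @return named numeric vector `c(phi, theta, psi)` in degrees, each in
#'   `(-180, 180]`.
#' @export
euler_from_rotation <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  if (max(abs(R %*% t(R) - diag(3))) > 1e-6) {
    stop("R is not orthonormal")
  }
  r31 <- max(-1, min(1, R[3, 1]))
  if (abs(r31) >= 1 - 1e-10) {
    theta <- if (r31 < 0) 90 else -90
    psi <- 0
    # at theta = +90: R[1,2] = sin(phi - psi), R[2,2] = cos(phi - psi)
    # at theta = -90: R[1,2] = -sin(phi + psi), R[2,2] = cos(phi + psi)
    phi <- if (r31 < 0) rad2deg(atan2(R[1, 2], R[2, 2]))
           else         rad2deg(atan2(-R[1, 2], R[2, 2]))
  } else {
    theta <- rad2deg(asin(-r31))
    psi <- rad2deg(atan2(R[2, 1], R[1, 1]))
    phi <- rad2deg(atan2(R[3, 2], R[3, 3]))
  }
  c(phi = normalize_angle(phi), theta = normalize_angle(theta),
    psi = normalize_angle(psi))
}

#' Angle between two 3-vectors
#'
#' @param v1,v2 non-zero numeric 3-vectors, or n x 3 matrices for a
#'   vectorized call.
#' @return angle(s) in degrees, in `[0, 180]`.
#' @export
#' @examples
#' angle_between(c(1, 0, 0), c(0, 1, 0))  # 90
angle_between <- function(v1, v2) {
  if (is.null(dim(v1))) v1 <- matrix(v1, nrow = 1)
  if (is.null(dim(v2))) v2 <- matrix(v2, nrow = 1)
  n <- max(nrow(v1), nrow(v2))
  if (nrow(v1) == 1 && n > 1) v1 <- v1[rep(1, n), , drop = FALSE]
  if (nrow(v2) == 1 && n > 1) v2 <- v2[rep(1, n), , drop = FALSE]
  n1 <- sqrt(rowSums(v1^2))
  n2 <- sqrt(rowSums(v2^2))
  if (any(n1 == 0) || any(n2 == 0)) stop("zero vector has no direction")
  dot <- rowSums(v1 * v2)
  cx <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  # atan2 form is numerically stable near 0 and 180 degrees
  out <- rad2deg(atan2(sqrt(rowSums(cx^2)), dot))
  if (nrow(v1) == 1) out[[1]] else out
}

# --- quaternion helpers (internal; used for orientation interpolation) -----

# n x 9 rotation set -> n x 4 unit quaternions (w, x, y, z), w >= 0.
rot_to_quat <- function(r) {
  n <- nrow(r)
  q <- matrix(0, n, 4)
  tr <- r[, 1] + r[, 5] + r[, 9]
  for (i in seq_len(n)) {
    m <- matrix(r[i, ], 3, 3)
    t0 <- tr[i]
    if (t0 > 0) {
      s <- sqrt(t0 + 1) * 2
      q[i, ] <- c(0.25 * s, (m[3, 2] - m[2, 3]) / s,
                  (m[1, 3] - m[3, 1]) / s, (m[2, 1] - m[1, 2]) / s)
    } else {
      d <- c(m[1, 1], m[2, 2], m[3, 3])
      k <- which.max(d)
      j1 <- k %% 3 + 1; j2 <- j1 %% 3 + 1
      s <- sqrt(1 + m[k, k] - m[j1, j1] - m[j2, j2]) * 2
      v <- numeric(4)
      v[1] <- (m[j2, j1] - m[j1, j2]) / s
      v[k + 1] <- 0.25 * s
      v[j1 + 1] <- (m[j1, k] + m[k, j1]) / s
      v[j2 + 1] <- (m[j2, k] + m[k, j2]) / s
      q[i, ] <- v
    }
    if (q[i, 1] < 0) q[i, ] <- -q[i, ]
  }
  q / sqrt(rowSums(q^2))
}

# n x 4 quaternions -> n x 9 rotation set.
quat_to_rot <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  )
}

# Spherical linear interpolation between row-paired quaternions q0, q1 at
# fractions u in [0, 1]; shortest-arc convention (sign-flip when dot < 0).
quat_slerp <- function(q0, q1, u) {
  dot <- rowSums(q0 * q1)
  flip <- dot < 0
  q1[flip, ] <- -q1[flip, , drop = FALSE]
  dot <- pmin(1, abs(dot))
  om <- acos(dot)
  so <- sin(om)
  w0 <- ifelse(so < 1e-9, 1 - u, sin((1 - u) * om) / so)
  w1 <- ifelse(so < 1e-9, u, sin(u * om) / so)
  q <- q0 * w0 + q1 * w1
  q / sqrt(rowSums(q^2))
}
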