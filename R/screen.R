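# Planar screen model: pixel <-> metric <-> world mapping, gaze-ray
# intersection, and its inverse (known POR -> eye-in-head angles).
#
# Pixel convention: origin at the top-left corner, u increases rightward
# (from the viewer's point of view), v increases downward. The center pixel
# (s_u/2, s_v/2) maps to the screen center point c.

#' Screen model parameters
#'
#' Describes a planar display by its center, orientation and size. The
#' in-plane "screen-up" direction makes the 2-D pixel frame well defined;
#' by default it is the world up axis projected into the screen plane.
#'
#' @param center 3-vector, screen center in world cm.
#' @param normal 3-vector, plane normal pointing from the screen toward the
#'   viewer; normalized internally.
#' @param up 3-vector, in-plane screen-up direction; the component along
#'   `normal` is removed and the result normalized. Default: world z (up).
#' @param width_cm,height_cm metric size in cm.
#' @param width_px,height_px resolution in pixels.
#' @return an object of class `screen_params`.
#' @export
#' @examples
#' default_screen()  # the 1024x768 px, 220x160 cm back-projection display
screen_params <- function(center = c(0, 0, 0), normal = c(-1, 0, 0),
                          up = c(0, 0, 1), width_cm = 220, height_cm = 160,
                          width_px = 1024, height_px = 768) {
  stopifnot(length(center) == 3, length(normal) == 3, length(up) == 3,
            width_cm > 0, height_cm > 0, width_px > 0, height_px > 0)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("normal must be non-zero")
  normal <- normal / nn
  up <- up - sum(up * normal) * normal
  nu <- sqrt(sum(up^2))
  if (nu < 1e-12) stop("up must not be parallel to normal")
  up <- up / nu
  out <- list(center = as.numeric(center), normal = as.numeric(normal),
              up = as.numeric(up),
              right = cross3(up, normal),   # viewer's right, in-plane
              width_cm = width_cm, height_cm = height_cm,
              width_px = as.numeric(width_px), height_px = as.numeric(height_px))
  class(out) <- "screen_params"
  out
}

#' @rdname screen_params
#' @export
default_screen <- function() screen_params()

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.screen_params <- function(x, ...) {
  cat("Planar screen model\n")
  cat(sprintf("  resolution : %g x %g px\n", x$width_px, x$height_px))
  cat(sprintf("  size       : %g x %g cm\n", x$width_cm, x$height_cm))
  cat(sprintf("  center     : (%.2f, %.2f, %.2f) cm\n",
              x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  normal     : (%.3f, %.3f, %.3f)\n",
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

as_uv_matrix <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 2)
    matrix(p, nrow = 1)
  } else {
    stopifnot(ncol(p) == 2)
    as.matrix(p)
  }
}

#' Map screen pixel coordinates to world coordinates
#'
#' Out-of-bounds pixels extrapolate on the screen plane (flagged by
#' [on_screen()]), never error.
#'
#' @param screen a [screen_params()] object.
#' @param p pixel coordinates: length-2 vector `c(u, v)` or an n x 2 matrix.
#' @return a 3-vector (or n x 3 matrix) of world points on the screen plane.
#' @export
por_to_world <- function(screen, p) {
  p <- as_uv_matrix(p)
  a <- (p[, 1] / screen$width_px - 0.5) * screen$width_cm     # along right
  b <- (0.5 - p[, 2] / screen$height_px) * screen$height_cm   # along up
  out <- outer(a, screen$right) + outer(b, screen$up) +
    matrix(screen$center, nrow(p), 3, byrow = TRUE)
  if (nrow(p) == 1) as.numeric(out) else out
}

#' Map world points on the screen plane to pixel coordinates
#'
#' @param screen a [screen_params()] object.
#' @param point 3-vector or n x 3 matrix of world points; must lie within
#'   `tol` cm of the screen plane.
#' @param tol off-plane tolerance in cm (default 1e-6).
#' @return pixel coordinates `c(u, v)` (or n x 2 matrix).
#' @export
world_to_por <- function(screen, point, tol = 1e-6) {
  if (is.null(dim(point))) point <- matrix(point, nrow = 1)
  stopifnot(ncol(point) == 3)
  d <- sweep(point, 2, screen$center)
  off <- abs(d %*% screen$normal)
  if (any(off > tol)) {
    stop(sprintf("point is %.3g cm off the screen plane", max(off)))
  }
  u <- (as.numeric(d %*% screen$right) / screen$width_cm + 0.5) * screen$width_px
  v <- (0.5 - as.numeric(d %*% screen$up) / screen$height_cm) * screen$height_px
  out <- cbind(u = u, v = v)
  if (nrow(out) == 1) c(u = out[1, 1], v = out[1, 2]) else out
}

#' Is a pixel coordinate on the physical screen?
#'
#' @param screen a [screen_params()] object.
#' @param p pixel coordinates (vector or n x 2 matrix).
#' @return logical vector.
#' @export
on_screen <- function(screen, p) {
  p <- as_uv_matrix(p)
  p[, 1] >= 0 & p[, 1] <= screen$width_px &
    p[, 2] >= 0 & p[, 2] <= screen$height_px
}

# Unit gaze direction in the eye's own frame for eye-in-head rotations
# (phi horizontal, theta vertical, degrees): Rz(phi) Ry(theta) (1,0,0)'.
# Vectorized; returns n x 3.
gaze_dir_local <- function(phi, theta) {
  cf <- cos(deg2rad(phi)); sf <- sin(deg2rad(phi))
  ct <- cos(deg2rad(theta)); st <- sin(deg2rad(theta))
  cbind(cf * ct, sf * ct, -st)
}

#' Gaze ray from an eye pose and eye-in-head rotation angles
#'
#' The gaze direction is the image of the eye-frame forward axis (1, 0, 0)
#' under the horizontal rotation `phi` (about the eye's up axis), the
#' vertical rotation `theta` (about the eye's lateral axis) and the eye
#' orientation `R_e`: `g = R_e Rz(phi) Ry(theta) (1,0,0)'`. Positive `phi`
#' rotates gaze toward the viewer's left, positive `theta` downward.
#'
#' @param eye eye pose: list with `position` (3-vector, cm) and `rotation`
#'   (3x3 matrix), as returned by [head_to_eye()].
#' @param angles eye-in-head angles: `c(phi, theta)` in degrees.
#' @return list with `origin` (3-vector) and unit `direction` (3-vector).
#' @export
gaze_vector <- function(eye, angles) {
  d <- gaze_dir_local(angles[[1]], angles[[2]])
  list(origin = as.numeric(eye$position),
       direction = as.numeric(eye$rotation %*% d[1, ]))
}

# Vectorized core of ray/plane intersection. eye_pos n x 3, dir n x 3
# (unit), returns list(uv = n x 2, t = n, miss = logical n). A ray is a
# miss when |direction . normal| < tol or the hit is behind the origin.
intersect_rays <- function(screen, eye_pos, dir, tol = 1e-9) {
  dn <- as.numeric(dir %*% screen$normal)
  co <- sweep(eye_pos, 2, screen$center)
  tnum <- -as.numeric(co %*% screen$normal)
  miss <- abs(dn) < tol
  tt <- ifelse(miss, NA_real_, tnum / dn)
  miss <- miss | (!is.na(tt) & tt <= 0)
  tt[miss] <- NA_real_
  f <- eye_pos + dir * tt
  d <- sweep(f, 2, screen$center)
  u <- (as.numeric(d %*% screen$right) / screen$width_cm + 0.5) * screen$width_px
  v <- (0.5 - as.numeric(d %*% screen$up) / screen$height_cm) * screen$height_px
  list(uv = cbind(u = u, v = v), t = tt, miss = miss)
}

#' Intersect a gaze ray with the screen
#'
#' @inheritParams gaze_vector
#' @param screen a [screen_params()] object.
#' @return list with `por` (pixel coordinates `c(u, v)`) and `on_screen`
#'   (TRUE iff the intersection lies within the physical display bounds).
#' @export
#' @examples
#' eye <- list(position = c(-140, 0, 0), rotation = diag(3))
#' intersect_gaze(default_screen(), eye, c(0, 0))  # center pixel
intersect_gaze <- function(screen, eye, angles) {
  ray <- gaze_vector(eye, angles)
  res <- intersect_rays(screen, matrix(ray$origin, 1), matrix(ray$direction, 1))
  if (res$miss[1]) {
    if (abs(sum(ray$direction * screen$normal)) < 1e-9) {
      stop("gaze ray is parallel to the screen plane")
    }
    stop("gaze ray intersects the screen plane behind the eye")
  }
  list(por = c(u = res$uv[1, 1], v = res$uv[1, 2]),
       on_screen = unname(on_screen(screen, res$uv[1, ])))
}

# Vectorized inverse screen mapping: required eye-in-head angles (degrees,
# n x 2) that point gaze from eyes (eye_pos n x 3, rotation set re n x 9)
# at pixel targets p (n x 2).
inverse_screen_angles <- function(screen, eye_pos, re, p) {
  w <- por_to_world(screen, p)
  if (is.null(dim(w))) w <- matrix(w, nrow = 1)
  d <- w - eye_pos
  nd <- sqrt(rowSums(d^2))
  if (any(nd < 1e-9)) stop("target point coincides with the eye position")
  d <- d / nd
  b <- rot_tapply(re, d)   # direction in the eye frame
  cbind(phi = rad2deg(atan2(b[, 2], b[, 1])),
        theta = rad2deg(asin(pmax(-1, pmin(1, -b[, 3])))))
}

#' Eye-in-head angles that fixate a known screen point
#'
#' Inverse of the screen model: given the eye pose and a target pixel,
#' returns the rotation angles for which [intersect_gaze()] reproduces the
#' target.
#'
#' @inheritParams intersect_gaze
#' @param p target pixel coordinates `c(u, v)`.
#' @return `c(phi, theta)` in degrees.
#' @export
inverse_screen <- function(screen, eye, p) {
  re <- matrix(as.numeric(eye$rotation), nrow = 1)
  a <- inverse_screen_angles(screen, matrix(eye$position, nrow = 1), re,
                             as_uv_matrix(p))
  c(phi = unname(a[1, 1]), theta = unname(a[1, 2]))
}
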