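# The geometric gaze model: rigid head-to-eye transform, linear
# pupil-to-eye-rotation model, and the gaze/screen intersection pipeline.

#' Head-to-eye transform parameters
#'
#' Rigid offset from the tracked head-marker frame to the eye-centered
#' frame: a translation `(x, y, z)` in head-frame cm (x forward, y left,
#' z up) and an orientation offset as Euler angles in degrees.
#'
#' @param x,y,z translation offset, cm.
#' @param phi,theta,psi rotation offset, degrees.
#' @return object of class `head_eye_params`.
#' @export
head_eye_params <- function(x = 0, y = 0, z = 0,
                            phi = 0, theta = 0, psi = 0) {
  v <- c(x = x, y = y, z = z, phi = phi, theta = theta, psi = psi)
  if (!all(is.finite(v))) stop("head-eye parameters must be finite")
  structure(as.list(v), class = "head_eye_params")
}

#' Linear eye model parameters
#'
#' Per-axis linear maps from pupil image position to eye-in-head rotation:
#' `phi = m_phi * p_x + b_phi`, `theta = m_theta * p_y + b_theta`.
#'
#' @param m_phi,m_theta slopes, degrees per image unit.
#' @param b_phi,b_theta intercepts, degrees.
#' @return object of class `eye_model_params`.
#' @export
eye_model_params <- function(m_phi = 1, b_phi = 0, m_theta = 1, b_theta = 0) {
  v <- c(m_phi = m_phi, b_phi = b_phi, m_theta = m_theta, b_theta = b_theta)
  if (!all(is.finite(v))) stop("eye model parameters must be finite")
  structure(as.list(v), class = "eye_model_params")
}

#' Assemble a full geometric gaze model
#'
#' @param head_eye a [head_eye_params()] object.
#' @param eye an [eye_model_params()] object.
#' @param screen a [screen_params()] object.
#' @return object of class `geometric_model`.
#' @export
geometric_model <- function(head_eye = head_eye_params(),
                            eye = eye_model_params(),
                            screen = default_screen()) {
  stopifnot(inherits(head_eye, "head_eye_params"),
            inherits(eye, "eye_model_params"),
            inherits(screen, "screen_params"))
  structure(list(head_eye = head_eye, eye = eye, screen = screen),
            class = "geometric_model")
}

he_vec <- function(p) unlist(p[c("x", "y", "z", "phi", "theta", "psi")])

#' Eye pose from a tracked head pose
#'
#' The eye position is the head position plus the head-rotated translation
#' offset; the eye orientation is the head orientation composed with the
#' rotation offset: `e = h + R_h d`, `R_e = R_h R_T`.
#'
#' @param head head pose: named vector/list with `h_x, h_y, h_z` (cm) and
#'   `h_phi, h_theta, h_psi` (degrees), or a one-row session data.frame.
#' @param params a [head_eye_params()] object.
#' @return list with `position` (3-vector, world cm) and `rotation`
#'   (3x3 matrix), the eye pose.
#' @export
head_to_eye <- function(head, params) {
  h <- unlist(head[c("h_x", "h_y", "h_z", "h_phi", "h_theta", "h_psi")])
  rh <- rotation_from_euler(h[["h_phi"]], h[["h_theta"]], h[["h_psi"]])
  rt <- rotation_from_euler(params$phi, params$theta, params$psi)
  list(position = as.numeric(h[1:3] + rh %*% c(params$x, params$y, params$z)),
       rotation = rh %*% rt)
}

# Vectorized eye poses for an n x 6 head matrix. Returns
# list(position = n x 3, rotation = n x 9 rotation set).
head_to_eye_batch <- function(H, params) {
  rh <- rot_batch(H[, 4], H[, 5], H[, 6])
  rt <- rot_batch(params$phi, params$theta, params$psi)
  list(position = H[, 1:3, drop = FALSE] +
         rot_apply(rh, c(params$x, params$y, params$z)),
       rotation = rot_mult(rh, rt))
}

#' Pupil image position to eye-in-head rotation angles
#'
#' @param p pupil centroid `c(p_x, p_y)` in image units, or an n x 2 matrix.
#' @param params an [eye_model_params()] object.
#' @return `c(phi, theta)` in degrees (or n x 2 matrix).
#' @export
pupil_to_angles <- function(p, params) {
  p <- as_uv_matrix(p)
  out <- cbind(phi = params$m_phi * p[, 1] + params$b_phi,
               theta = params$m_theta * p[, 2] + params$b_theta)
  if (nrow(out) == 1) c(phi = out[1, 1], theta = out[1, 2]) else out
}

#' Fit the linear eye model by per-axis simple linear regression
#'
#' Least-squares fit of `phi` on `p_x` and `theta` on `p_y`.
#'
#' @param pupil n x 2 matrix of pupil positions (`p_x`, `p_y`).
#' @param angles n x 2 matrix of eye rotation angles (`phi`, `theta`),
#'   degrees.
#' @return an [eye_model_params()] object.
#' @export
fit_eye_model <- function(pupil, angles) {
  pupil <- as_uv_matrix(pupil); angles <- as_uv_matrix(angles)
  stopifnot(nrow(pupil) == nrow(angles))
  if (nrow(pupil) < 2) stop("need at least 2 samples to fit the eye model")
  fit1 <- function(x, y) {
    vx <- stats::var(x)
    if (!is.finite(vx) || vx < 1e-12) {
      stop("degenerate (constant) pupil coordinate; eye model underdetermined")
    }
    m <- stats::cov(x, y) / vx
    c(m = m, b = mean(y) - m * mean(x))
  }
  fu <- fit1(pupil[, 1], angles[, 1])
  fv <- fit1(pupil[, 2], angles[, 2])
  eye_model_params(m_phi = fu[["m"]], b_phi = fu[["b"]],
                   m_theta = fv[["m"]], b_theta = fv[["b"]])
}

# Vectorized geometric forward pipeline: n x 6 head matrix, n x 2 pupil
# matrix -> list(uv = n x 2 predicted pixels, miss = logical).
predict_geometric_core <- function(model, H, P) {
  eyes <- head_to_eye_batch(H, model$head_eye)
  ang <- cbind(model$eye$m_phi * P[, 1] + model$eye$b_phi,
               model$eye$m_theta * P[, 2] + model$eye$b_theta)
  dirs <- rot_apply(eyes$rotation, gaze_dir_local(ang[, 1], ang[, 2]))
  # rot_apply recycles only single rows; gaze_dir_local already returns n x 3
  res <- intersect_rays(model$screen, eyes$position, dirs)
  list(uv = res$uv, miss = res$miss)
}

#' Predict points of regard with the geometric model
#'
#' Chains the head-to-eye transform, the linear eye model and the gaze-ray
#' screen intersection for every sample of a session.
#'
#' @param model a [geometric_model()] object.
#' @param session a [gaze_session()] (or any data.frame with the head and
#'   pupil columns).
#' @return data.frame with columns `u`, `v` (predicted pixels; NA when the
#'   gaze ray misses the screen plane) and `on_screen`.
#' @export
predict_geometric <- function(model, session) {
  H <- session_head_matrix(session)
  P <- session_pupil_matrix(session)
  res <- predict_geometric_core(model, H, P)
  data.frame(u = res$uv[, 1], v = res$uv[, 2],
             on_screen = !res$miss & on_screen(model$screen, res$uv))
}

#' Mean pixel error of a geometric model on a session
#'
#' Mean Euclidean distance in pixels between predicted and target points of
#' regard over all calibration rows; samples whose gaze rays miss the
#' screen plane contribute a fixed penalty of twice the screen diagonal.
#'
#' @inheritParams predict_geometric
#' @param session a [gaze_session()] with known stimulus targets.
#' @return non-negative scalar (0 iff every prediction is exact).
#' @export
geometric_cost <- function(model, session) {
  rows <- session_calib_rows(session)
  if (!length(rows)) stop("no usable calibration samples in session")
  H <- session_head_matrix(session)[rows, , drop = FALSE]
  P <- session_pupil_matrix(session)[rows, , drop = FALSE]
  Y <- session_target_matrix(session)[rows, , drop = FALSE]
  geometric_cost_core(model, H, P, Y)
}

geometric_cost_core <- function(model, H, P, Y) {
  res <- predict_geometric_core(model, H, P)
  d2 <- (res$uv[, 1] - Y[, 1])^2 + (res$uv[, 2] - Y[, 2])^2
  penalty <- 2 * sqrt(model$screen$width_px^2 + model$screen$height_px^2)
  e <- ifelse(res$miss, penalty, sqrt(d2))
  mean(e)
}
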