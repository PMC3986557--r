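# Calibration of the geometric model: outer bounded search over the six
# head-to-eye transform parameters with an exact closed-form inner fit of
# the linear eye model (the eye model is linear in the pupil coordinates,
# so regressing the geometrically required angles on the pupil positions
# realizes the inner minimization without a second nonlinear search).

#' Control parameters for geometric calibration
#'
#' @param bound_cm,bound_deg optimizer box half-widths for the translation
#'   (cm) and rotation (degrees) offsets.
#' @param maxit maximum outer optimizer iterations.
#' @param factr L-BFGS-B convergence tolerance factor (smaller = tighter).
#' @param starts matrix of starting points (rows of 6: x, y, z, phi, theta,
#'   psi); a small deterministic multistart guards against local minima.
#' @param subset_size reduced-subset size for screen calibration.
#' @return list of control settings.
#' @export
calib_control <- function(bound_cm = 30, bound_deg = 45, maxit = 200,
                          factr = 1e2,
                          starts = rbind(rep(0, 6),
                                         c(8, 0, -8, 0, 0, 0),
                                         c(-8, 0, 8, 0, 0, 0)),
                          subset_size = 500) {
  list(bound_cm = bound_cm, bound_deg = bound_deg, maxit = maxit,
       factr = factr, starts = starts, subset_size = subset_size)
}

# Inner step: given candidate head-to-eye parameters, fit the eye model in
# closed form and return the resulting pixel cost together with the fit.
inner_eye_fit <- function(delta_t, H, P, Y, screen) {
  hep <- head_eye_params(delta_t[1], delta_t[2], delta_t[3],
                         delta_t[4], delta_t[5], delta_t[6])
  eyes <- head_to_eye_batch(H, hep)
  ang <- inverse_screen_angles(screen, eyes$position, eyes$rotation, Y)
  eye <- fit_eye_model(P, ang)
  model <- geometric_model(hep, eye, screen)
  list(model = model, cost = geometric_cost_core(model, H, P, Y))
}

#' Calibrate the user-specific geometric parameters
#'
#' Estimates the head-to-eye transform and the linear eye model jointly
#' from a calibration session with known stimulus targets, by bounded
#' minimization of the mean pixel error. The outer search runs over the six
#' transform parameters; for each candidate the eye model is fitted exactly
#' by regressing the geometrically required eye rotations (from the inverse
#' screen model) onto the observed pupil positions.
#'
#' @param session a [gaze_session()] whose rows with a visible stimulus are
#'   used as calibration data.
#' @param screen a [screen_params()] object (fixed during user calibration).
#' @param control a [calib_control()] list.
#' @return list with `head_eye`, `eye` (fitted parameter objects), `cost`
#'   (mean pixel error at the optimum) and `convergence` diagnostics.
#' @export
calibrate_user <- function(session, screen = default_screen(),
                           control = calib_control()) {
  rows <- session_calib_rows(session)
  if (length(rows) < 10) stop("too few usable calibration samples (need >= 10)")
  H <- session_head_matrix(session)[rows, , drop = FALSE]
  P <- session_pupil_matrix(session)[rows, , drop = FALSE]
  Y <- session_target_matrix(session)[rows, , drop = FALSE]
  if (length(unique(round(Y[, 1]))) < 3 && length(unique(round(Y[, 2]))) < 3) {
    stop("calibration targets are degenerate: need several distinct targets")
  }
  calibrate_user_core(H, P, Y, screen, control)
}

calibrate_user_core <- function(H, P, Y, screen, control = calib_control()) {
  lower <- c(rep(-control$bound_cm, 3), rep(-control$bound_deg, 3))
  upper <- -lower
  obj <- function(par) inner_eye_fit(par, H, P, Y, screen)$cost
  best <- NULL
  conv <- list()
  for (k in seq_len(nrow(control$starts))) {
    start <- pmin(pmax(control$starts[k, ], lower), upper)
    fit <- stats::optim(start, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = control$maxit,
                                       factr = control$factr))
    conv[[k]] <- c(value = fit$value, convergence = fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value)) {
    stop("geometric calibration failed: non-finite objective; diagnostics: ",
         paste(vapply(conv, function(x) sprintf("%.3g", x[["value"]]),
                      character(1)), collapse = ", "))
  }
  sol <- inner_eye_fit(best$par, H, P, Y, screen)
  list(head_eye = sol$model$head_eye, eye = sol$model$eye,
       cost = sol$cost, convergence = best$convergence,
       n = nrow(H), starts = conv)
}

#' Calibrate the screen model from one or more user sessions
#'
#' Bounded search over the screen pose and (optionally) metric size,
#' minimizing the sum over users of the per-user minimized pixel cost: each
#' objective evaluation re-runs the user calibration on a reduced subset of
#' every session. The pixel resolution comes from the shape prior and is
#' never searched.
#'
#' @param sessions a [gaze_session()] or list of them (one per user).
#' @param screen_init starting [screen_params()]; also supplies the shape
#'   prior (pixel resolution) and the search box center.
#' @param fit_size logical; search the metric width/height too (TRUE), or
#'   keep the physical size fixed and search pose only (FALSE).
#' @param pos_bound half-width of the center search box, cm.
#' @param ang_bound half-width of the normal-direction search box, degrees.
#' @param size_rel relative half-width of the size search box.
#' @param maxit outer iterations.
#' @param control user-calibration control for the inner runs; defaults to
#'   a cheaper setting than [calib_control()] since it runs per evaluation.
#' @return the best [screen_params()] found, with attributes `objective`
#'   and `convergence`.
#' @export
calibrate_screen <- function(sessions, screen_init = default_screen(),
                             fit_size = TRUE, pos_bound = 20, ang_bound = 15,
                             size_rel = 0.2, maxit = 40,
                             control = calib_control(maxit = 40,
                                                     factr = 1e7,
                                                     starts = rbind(rep(0, 6)),
                                                     subset_size = 500)) {
  if (inherits(sessions, "gaze_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1)
  # pre-extract subsampled matrices per user
  users <- lapply(sessions, function(s) {
    rows <- session_calib_rows(s)
    if (length(rows) < 10) stop("a session has too few calibration samples")
    rows <- rows[subsample_idx(length(rows), control$subset_size)]
    list(H = session_head_matrix(s)[rows, , drop = FALSE],
         P = session_pupil_matrix(s)[rows, , drop = FALSE],
         Y = session_target_matrix(s)[rows, , drop = FALSE])
  })
  # parameterization: center (3), normal direction as yaw/pitch offsets from
  # the initial normal (2), and optionally metric size (2).
  n0 <- screen_init$normal
  base_yaw <- rad2deg(atan2(n0[2], n0[1]))
  base_pitch <- rad2deg(asin(max(-1, min(1, n0[3]))))
  make_screen <- function(par) {
    yaw <- deg2rad(base_yaw + par[4]); pitch <- deg2rad(base_pitch + par[5])
    nrm <- c(cos(pitch) * cos(yaw), cos(pitch) * sin(yaw), sin(pitch))
    screen_params(center = screen_init$center + par[1:3], normal = nrm,
                  up = screen_init$up,
                  width_cm = if (fit_size) par[6] else screen_init$width_cm,
                  height_cm = if (fit_size) par[7] else screen_init$height_cm,
                  width_px = screen_init$width_px,
                  height_px = screen_init$height_px)
  }
  obj <- function(par) {
    scr <- make_screen(par)
    sum(vapply(users, function(u) {
      calibrate_user_core(u$H, u$P, u$Y, scr, control)$cost
    }, numeric(1)))
  }
  par0 <- c(0, 0, 0, 0, 0,
            if (fit_size) c(screen_init$width_cm, screen_init$height_cm))
  lower <- c(rep(-pos_bound, 3), rep(-ang_bound, 2),
             if (fit_size) c(screen_init$width_cm * (1 - size_rel),
                             screen_init$height_cm * (1 - size_rel)))
  upper <- c(rep(pos_bound, 3), rep(ang_bound, 2),
             if (fit_size) c(screen_init$width_cm * (1 + size_rel),
                             screen_init$height_cm * (1 + size_rel)))
  # nlminb (PORT) rather than L-BFGS-B: the objective itself runs the
  # bounded user calibration, and R's L-BFGS-B is not reentrant
  fit <- stats::nlminb(par0, obj, lower = lower, upper = upper,
                       control = list(iter.max = maxit, eval.max = 50 * maxit))
  fit <- list(par = fit$par, value = fit$objective,
              convergence = fit$convergence)
  v0 <- obj(par0)
  # optimizer contract: never return something worse than the start
  if (fit$value > v0) fit <- list(par = par0, value = v0, convergence = 0)
  out <- make_screen(fit$par)
  attr(out, "objective") <- fit$value
  attr(out, "convergence") <- fit$convergence
  out
}

#' Fit a gaze calibration model to a session
#'
#' The single fitting front-end for both calibration approaches. With
#' `method = "geometric"` it estimates the head-to-eye transform and linear
#' eye model by nested cost minimization (the screen model is taken as
#' given); with `method = "gpr"` it trains two Gaussian processes mapping
#' the eight-dimensional head-pose/pupil input directly to the screen
#' coordinates.
#'
#' @param session a [gaze_session()] providing calibration data (rows with
#'   a visible stimulus).
#' @param method `"geometric"` or `"gpr"`.
#' @param screen a [screen_params()] object (used by the geometric pipeline
#'   and by angular-error summaries).
#' @param ... further arguments passed to [calibrate_user()]
#'   (`control`) or [train_gaze_gp()] (`subset_size`, `max_train`,
#'   `kernel`, ...).
#' @return an object of class `gaze_geometric` or `gaze_gpr` (both
#'   inheriting `gaze_model`), supporting `print()`, `summary()`, `coef()`,
#'   `predict()`, `residuals()`, `fitted()` and `plot()`.
#' @export
#' @examples
#' \donttest{
#' sess <- simulate_session(sim_config(seed = 1, sample_rate = 5))
#' fit <- gaze_calibrate(sess, method = "geometric")
#' head(predict(fit, sess))
#' }
gaze_calibrate <- function(session, method = c("geometric", "gpr"),
                           screen = default_screen(), ...) {
  method <- match.arg(method)
  stopifnot(inherits(screen, "screen_params"))
  if (method == "geometric") {
    fit <- calibrate_user(session, screen, ...)
    out <- list(model = geometric_model(fit$head_eye, fit$eye, screen),
                cost = fit$cost, convergence = fit$convergence,
                n = fit$n, screen = screen, session = session,
                method = "geometric", call = match.call())
    class(out) <- c("gaze_geometric", "gaze_model")
  } else {
    gps <- train_gaze_gp(session, ...)
    out <- list(gps = gps, screen = screen, session = session,
                n = nrow(gps$u$X), method = "gpr", call = match.call())
    class(out) <- c("gaze_gpr", "gaze_model")
  }
  out
}

# ---- S3 methods shared by both model classes ------------------------------

#' @export
print.gaze_geometric <- function(x, ...) {
  cat("Geometric gaze calibration\n")
  cat(sprintf("  %d calibration samples, mean pixel error %.3f px\n",
              x$n, x$cost))
  he <- he_vec(x$model$head_eye)
  cat(sprintf("  head-to-eye offset : (%.2f, %.2f, %.2f) cm, (%.2f, %.2f, %.2f) deg\n",
              he[1], he[2], he[3], he[4], he[5], he[6]))
  cat(sprintf("  eye model          : phi = %.4g px + %.4g, theta = %.4g py + %.4g\n",
              x$model$eye$m_phi, x$model$eye$b_phi,
              x$model$eye$m_theta, x$model$eye$b_theta))
  invisible(x)
}

#' @export
coef.gaze_geometric <- function(object, ...) {
  he <- he_vec(object$model$head_eye)
  names(he) <- paste0("T_", names(he))
  c(he, unlist(object$model$eye))
}

#' Predict points of regard from a fitted calibration model
#'
#' @param object a fitted `gaze_model` from [gaze_calibrate()].
#' @param newdata a [gaze_session()] (or data.frame with the input
#'   columns); defaults to the calibration session.
#' @param se logical (GPR only): also return the predictive standard
#'   deviations `sigma_u`, `sigma_v` in pixels.
#' @param ... unused.
#' @return data.frame with columns `u`, `v` (predicted pixels),
#'   `on_screen`, and for the GPR method `sigma_u`, `sigma_v` when
#'   `se = TRUE`.
#' @export
predict.gaze_geometric <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$session
  predict_geometric(object$model, newdata)
}

#' @export
fitted.gaze_model <- function(object, ...) {
  p <- predict(object, object$session)
  p[, c("u", "v")]
}

#' @export
residuals.gaze_model <- function(object, ...) {
  p <- fitted(object)
  data.frame(u = object$session$stim_u - p$u,
             v = object$session$stim_v - p$v)
}

#' @export
summary.gaze_model <- function(object, ...) {
  s <- object$session
  rows <- session_calib_rows(s)
  pred <- predict(object, s[rows, , drop = FALSE])
  err <- angular_error(s[rows, , drop = FALSE],
                       as.matrix(pred[, c("u", "v")]),
                       session_target_matrix(s[rows, , drop = FALSE]),
                       object$screen)
  px <- sqrt((pred$u - s$stim_u[rows])^2 + (pred$v - s$stim_v[rows])^2)
  out <- list(method = object$method, n = length(rows),
              mean_px = mean(px, na.rm = TRUE),
              mean_combined_deg = mean(err$combined, na.rm = TRUE),
              mean_azimuth_deg = mean(abs(err$azimuth), na.rm = TRUE),
              mean_elevation_deg = mean(abs(err$elevation), na.rm = TRUE),
              object = object)
  class(out) <- "summary.gaze_model"
  out
}

#' @export
print.summary.gaze_model <- function(x, ...) {
  cat(sprintf("Gaze calibration (%s method), %d samples\n", x$method, x$n))
  cat(sprintf("  training mean pixel error    : %.3f px\n", x$mean_px))
  cat(sprintf("  training mean combined error : %.4f deg\n",
              x$mean_combined_deg))
  cat(sprintf("  mean |azimuth| / |elevation| : %.4f / %.4f deg\n",
              x$mean_azimuth_deg, x$mean_elevation_deg))
  print(x$object)
  invisible(x)
}

#' @export
plot.gaze_model <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- x$session
  rows <- session_calib_rows(newdata)
  pred <- predict(x, newdata[rows, , drop = FALSE])
  tg <- session_target_matrix(newdata[rows, , drop = FALSE])
  graphics::plot(tg[, 1], tg[, 2], col = "grey50", pch = 3, cex = 0.5,
                 xlim = c(0, x$screen$width_px),
                 ylim = rev(c(0, x$screen$height_px)),
                 xlab = "u (px)", ylab = "v (px)",
                 main = sprintf("Predicted vs target POR (%s)", x$method), ...)
  graphics::points(pred$u, pred$v, col = grDevices::adjustcolor("red", 0.4),
                   pch = 16, cex = 0.4)
  graphics::legend("topright", legend = c("target", "predicted"),
                   col = c("grey50", "red"), pch = c(3, 16), bty = "n")
  invisible(x)
}

#' Simulate a synthetic session from a fitted geometric model
#'
#' Uses the fitted model as the simulator ground truth, so the returned
#' sessions are draws from the model's own forward process.
#'
#' @param object a fitted `gaze_geometric` model.
#' @param nsim number of sessions.
#' @param seed integer seed for the first session (incremented per session).
#' @param ... overrides passed to [sim_config()].
#' @return a [gaze_session()] if `nsim = 1`, else a list of them.
#' @export
simulate.gaze_geometric <- function(object, nsim = 1, seed = 1, ...) {
  out <- lapply(seq_len(nsim), function(i) {
    simulate_session(sim_config(seed = seed + i - 1,
                                ground_truth = object$model, ...))
  })
  if (nsim == 1) out[[1]] else out
}
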