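# Synthetic session generator: stimulus schedules (dynamic pursuit and
# static grid), head-motion models for the three mobility conditions, and
# the forward model that inverts the geometric pipeline to produce pupil
# samples for a fixating observer.

#' Default simulator ground truth
#'
#' A plausible helmet geometry: the eye sits 8 cm forward of and 9 cm below
#' the tracked marker centroid, with no rotation offset; the eye-camera map
#' is 0.02 degrees per image unit with small intercepts (so the pupil
#' travels ~1500 image units over 30 degrees, matching video eye-tracker
#' raw units).
#'
#' @return a [geometric_model()] object.
#' @export
default_truth <- function() {
  geometric_model(
    head_eye = head_eye_params(x = 8, y = 0, z = -9),
    eye = eye_model_params(m_phi = 0.02, b_phi = -2,
                           m_theta = 0.02, b_theta = 1.5),
    screen = default_screen()
  )
}

#' Simulation configuration
#'
#' Bundles the stated experimental protocol (sample rate, mobility
#' condition, stimulus phases) with the simulator-internal motion model and
#' sensor-noise settings.
#'
#' @param seed integer; every random draw of the session flows from it.
#' @param mobility `"head_fixed"`, `"head_free"` or `"walking"`.
#' @param sample_rate unified sampling rate, Hz.
#' @param noise_pupil pupil sensor noise sd, image units.
#' @param noise_head_pos head position sensor noise sd, cm.
#' @param noise_head_rot head orientation sensor noise sd, degrees.
#' @param fixation_jitter fixation instability sd in degrees of eye
#'   rotation (0 = the exact-fixation assumption of the calibration model).
#' @param ground_truth the generating [geometric_model()].
#' @param chinrest world position of the chin-rest / standing eye, cm.
#' @param walk_depth,walk_width walking area extents, cm (depth along the
#'   viewing axis, width lateral), centered on `chinrest`.
#' @param walk_sd,walk_tau Ornstein-Uhlenbeck stationary sd (cm) and time
#'   constant (s) of the walking position model.
#' @param face_sd,face_tau OU stationary sd (degrees) and time constant (s)
#'   of the head-orientation deviation from stimulus-facing.
#' @param dynamic_s,static_dot_s dynamic phase duration and per-dot static
#'   presentation time, seconds.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, mobility = c("walking", "head_free",
                                              "head_fixed"),
                       sample_rate = 60, noise_pupil = 2.5,
                       noise_head_pos = 0.05, noise_head_rot = 0.1,
                       fixation_jitter = 0,
                       ground_truth = default_truth(),
                       chinrest = c(-140, 0, 0),
                       walk_depth = 145, walk_width = 150,
                       walk_sd = 35, walk_tau = 8,
                       face_sd = 6, face_tau = 1.5,
                       dynamic_s = 180, static_dot_s = 1.5) {
  mobility <- match.arg(mobility)
  stopifnot(sample_rate > 0, noise_pupil >= 0, noise_head_pos >= 0,
            noise_head_rot >= 0, fixation_jitter >= 0,
            inherits(ground_truth, "geometric_model"))
  structure(list(seed = as.integer(seed), mobility = mobility,
                 sample_rate = sample_rate, noise_pupil = noise_pupil,
                 noise_head_pos = noise_head_pos,
                 noise_head_rot = noise_head_rot,
                 fixation_jitter = fixation_jitter,
                 ground_truth = ground_truth, chinrest = chinrest,
                 walk_depth = walk_depth, walk_width = walk_width,
                 walk_sd = walk_sd, walk_tau = walk_tau,
                 face_sd = face_sd, face_tau = face_tau,
                 dynamic_s = dynamic_s, static_dot_s = static_dot_s),
            class = "sim_config")
}

#' Dynamic pursuit stimulus path
#'
#' A dot moving horizontally or vertically at 100 px/s for at least 100 px
#' per segment, pausing 750 ms at every (random) change to one of the three
#' alternative cardinal directions; positions never leave the screen.
#'
#' @param duration_s total path duration, seconds.
#' @param seed optional integer seed (NULL = use the current RNG stream).
#' @param screen a [screen_params()] object.
#' @param speed dot speed during motion, px/s.
#' @param min_len minimum segment length, px.
#' @param pause_s pause duration at direction changes, seconds.
#' @param margin screen-edge margin, px.
#' @return list with `events` (data.frame: onset, duration, kind, u0, v0,
#'   u1, v1) and `position` (vectorized function of time returning an
#'   n x 2 pixel matrix).
#' @export
dynamic_stimulus_path <- function(duration_s, seed = NULL,
                                  screen = default_screen(), speed = 100,
                                  min_len = 100, pause_s = 0.75,
                                  margin = 20) {
  stopifnot(duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  lo <- c(margin, margin)
  hi <- c(screen$width_px - margin, screen$height_px - margin)
  pos <- lo + stats::runif(2) * (hi - lo)
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  cur <- sample(4, 1)
  t <- 0
  ev <- list()
  while (t < duration_s) {
    d <- dirs[cur, ]
    room <- if (d[1] > 0) hi[1] - pos[1] else if (d[1] < 0) pos[1] - lo[1]
            else if (d[2] > 0) hi[2] - pos[2] else pos[2] - lo[2]
    len <- stats::runif(1, min_len, min(max(room, min_len), 3 * min_len))
    len <- min(len, room)
    nxt <- pos + d * len
    ev[[length(ev) + 1]] <- data.frame(onset = t, duration = len / speed,
                                       kind = "pursuit_segment",
                                       u0 = pos[1], v0 = pos[2],
                                       u1 = nxt[1], v1 = nxt[2])
    t <- t + len / speed
    pos <- nxt
    if (t >= duration_s) break
    ev[[length(ev) + 1]] <- data.frame(onset = t, duration = pause_s,
                                       kind = "pause", u0 = pos[1],
                                       v0 = pos[2], u1 = pos[1], v1 = pos[2])
    t <- t + pause_s
    # pick among the three alternative cardinal directions with >= min_len
    # of room, so the next segment can honour the minimum length
    cand <- setdiff(1:4, cur)
    roomv <- apply(dirs[cand, , drop = FALSE], 1, function(dd) {
      if (dd[1] > 0) hi[1] - pos[1] else if (dd[1] < 0) pos[1] - lo[1]
      else if (dd[2] > 0) hi[2] - pos[2] else pos[2] - lo[2]
    })
    ok <- cand[roomv >= min_len]
    cur <- if (length(ok)) ok[sample.int(length(ok), 1)] else
      cand[which.max(roomv)]
  }
  events <- do.call(rbind, ev)
  position <- function(times) stimulus_at(events, times)
  list(events = events, position = position)
}

# Piecewise-linear stimulus position lookup for an event table. Times
# beyond the last event hold the final position.
stimulus_at <- function(events, times) {
  ends <- events$onset + events$duration
  idx <- findInterval(times, events$onset, rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  idx[idx > nrow(events)] <- nrow(events)
  frac <- (times - events$onset[idx]) / events$duration[idx]
  frac <- pmax(0, pmin(1, frac))
  cbind(u = events$u0[idx] + frac * (events$u1[idx] - events$u0[idx]),
        v = events$v0[idx] + frac * (events$v1[idx] - events$v0[idx]))
}

#' Static grid stimulus sequence
#'
#' Ten random permutations of a centered 5 x 4 grid spanning +/-32 x +/-23
#' degrees of visual angle from the chin-rest position (200 presentations of
#' 1500 ms each; every grid point appears exactly 10 times).
#'
#' @param seed optional integer seed (NULL = current RNG stream).
#' @param screen a [screen_params()] object.
#' @param distance_cm chin-rest viewing distance used to convert visual
#'   angle to pixels.
#' @param half_angle_deg grid half-extents `c(horizontal, vertical)` in
#'   degrees of visual angle.
#' @param dot_s presentation duration per dot, seconds.
#' @param repeats presentations per grid point.
#' @return data.frame of events: onset, duration, kind, u0, v0, u1, v1,
#'   grid_id.
#' @export
static_stimulus_sequence <- function(seed = NULL, screen = default_screen(),
                                     distance_cm = 140,
                                     half_angle_deg = c(32, 23),
                                     dot_s = 1.5, repeats = 10) {
  if (!is.null(seed)) set.seed(seed)
  half_u <- distance_cm * tan(deg2rad(half_angle_deg[1])) *
    screen$width_px / screen$width_cm
  half_v <- distance_cm * tan(deg2rad(half_angle_deg[2])) *
    screen$height_px / screen$height_cm
  cu <- screen$width_px / 2; cv <- screen$height_px / 2
  grid <- expand.grid(u = cu + seq(-1, 1, length.out = 5) * half_u,
                      v = cv + seq(-1, 1, length.out = 4) * half_v)
  order_ids <- unlist(lapply(seq_len(repeats),
                             function(i) sample.int(nrow(grid))))
  n <- length(order_ids)
  data.frame(onset = (seq_len(n) - 1) * dot_s, duration = dot_s,
             kind = "static_dot", u0 = grid$u[order_ids],
             v0 = grid$v[order_ids], u1 = grid$u[order_ids],
             v1 = grid$v[order_ids], grid_id = order_ids)
}

# Reflect values into [lo, hi] (keeps OU excursions inside the floor area).
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

# Discrete stationary Ornstein-Uhlenbeck (AR(1)) deviations: mean 0,
# stationary sd `sd`, correlation time `tau` seconds.
ou_series <- function(n, dt, sd, tau) {
  if (sd == 0) return(numeric(n))
  a <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - a^2))
  for (i in seq_len(n - 1)) x[i + 1] <- a * x[i] + innov[i]
  x
}

#' Simulate a head-pose stream
#'
#' Head-fixed: constant chin-rest pose plus sensor noise. Head-free: fixed
#' position, orientation tending to face the current stimulus with smooth
#' (Ornstein-Uhlenbeck) deviations. Walking: additionally a smooth
#' positional random walk confined to the floor area in front of the
#' display.
#'
#' @param config a [sim_config()].
#' @param times sample times, seconds.
#' @param target_world optional n x 3 matrix of world stimulus positions to
#'   face (defaults to the screen center).
#' @param seed optional seed (NULL = current RNG stream, as used inside
#'   [simulate_session()]).
#' @return data.frame with columns t, h_x, h_y, h_z, h_phi, h_theta, h_psi.
#' @export
simulate_head_trajectory <- function(config, times, target_world = NULL,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(times)
  dt <- if (n > 1) stats::median(diff(times)) else 1 / config$sample_rate
  cr <- config$chinrest
  if (config$mobility == "walking") {
    px <- cr[1] + ou_series(n, dt, config$walk_sd, config$walk_tau)
    py <- cr[2] + ou_series(n, dt, config$walk_sd, config$walk_tau)
    px <- reflect_into(px, cr[1] - config$walk_depth / 2,
                       cr[1] + config$walk_depth / 2)
    py <- reflect_into(py, cr[2] - config$walk_width / 2,
                       cr[2] + config$walk_width / 2)
  } else {
    px <- rep(cr[1], n); py <- rep(cr[2], n)
  }
  pz <- rep(cr[3], n)
  if (config$mobility == "head_fixed") {
    yaw <- pitch <- roll <- numeric(n)
  } else {
    if (is.null(target_world)) {
      target_world <- matrix(0, n, 3)
    }
    d <- target_world - cbind(px, py, pz)
    nd <- sqrt(rowSums(d^2))
    yaw <- rad2deg(atan2(d[, 2], d[, 1])) +
      ou_series(n, dt, config$face_sd, config$face_tau)
    pitch <- rad2deg(asin(pmax(-1, pmin(1, -d[, 3] / nd)))) +
      ou_series(n, dt, config$face_sd, config$face_tau)
    roll <- ou_series(n, dt, config$face_sd / 3, config$face_tau)
  }
  if (config$noise_head_pos > 0) {
    px <- px + stats::rnorm(n, 0, config$noise_head_pos)
    py <- py + stats::rnorm(n, 0, config$noise_head_pos)
    pz <- pz + stats::rnorm(n, 0, config$noise_head_pos)
  }
  if (config$noise_head_rot > 0) {
    roll <- roll + stats::rnorm(n, 0, config$noise_head_rot)
    pitch <- pitch + stats::rnorm(n, 0, config$noise_head_rot)
    yaw <- yaw + stats::rnorm(n, 0, config$noise_head_rot)
  }
  data.frame(t = times, h_x = px, h_y = py, h_z = pz,
             h_phi = normalize_angle(roll), h_theta = normalize_angle(pitch),
             h_psi = normalize_angle(yaw))
}

#' Forward model: pupil samples for a fixating observer
#'
#' Inverts the geometric pipeline: the eye pose follows from the head pose
#' and the ground-truth head-to-eye transform, the required eye rotations
#' from the inverse screen model, and the pupil position from the inverted
#' linear eye model `p_x = (phi - b_phi) / m_phi` (likewise for theta),
#' plus optional Gaussian noise.
#'
#' @param head data.frame of head poses (columns h_x .. h_psi).
#' @param target pixel targets: `c(u, v)` or n x 2 matrix.
#' @param truth the generating [geometric_model()].
#' @param noise_pupil pupil noise sd, image units.
#' @param fixation_jitter fixation instability sd, degrees.
#' @return data.frame with columns p_x, p_y.
#' @export
forward_model <- function(head, target, truth, noise_pupil = 0,
                          fixation_jitter = 0) {
  if (truth$eye$m_phi == 0 || truth$eye$m_theta == 0) {
    stop("eye model slope of zero cannot be inverted")
  }
  H <- as.matrix(head[, c("h_x", "h_y", "h_z", "h_phi", "h_theta", "h_psi")])
  target <- as_uv_matrix(target)
  if (nrow(target) == 1 && nrow(H) > 1) {
    target <- target[rep(1, nrow(H)), , drop = FALSE]
  }
  eyes <- head_to_eye_batch(H, truth$head_eye)
  ang <- inverse_screen_angles(truth$screen, eyes$position, eyes$rotation,
                               target)
  if (any(abs(ang) >= 90)) {
    stop("target not visible from the simulated eye position")
  }
  if (fixation_jitter > 0) {
    ang <- ang + matrix(stats::rnorm(length(ang), 0, fixation_jitter),
                        ncol = 2)
  }
  p_x <- (ang[, 1] - truth$eye$b_phi) / truth$eye$m_phi
  p_y <- (ang[, 2] - truth$eye$b_theta) / truth$eye$m_theta
  if (noise_pupil > 0) {
    p_x <- p_x + stats::rnorm(length(p_x), 0, noise_pupil)
    p_y <- p_y + stats::rnorm(length(p_y), 0, noise_pupil)
  }
  data.frame(p_x = p_x, p_y = p_y)
}

#' Simulate a full gaze-tracking session
#'
#' Generates the two-phase protocol: a 3-min dynamic pursuit phase followed
#' by a 5-min static grid phase (200 dots of 1500 ms), with head motion per
#' the configured mobility condition and pupil data from the forward model.
#' Fully deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param protocol `"both"`, `"dynamic"` or `"static"`.
#' @return a [gaze_session()] with phase labels and (for the static phase)
#'   stimulus presentation ids; the stimulus event tables are attached as
#'   attribute `"events"`.
#' @export
#' @examples
#' sess <- simulate_session(sim_config(seed = 7, sample_rate = 5))
#' table(sess$phase)
simulate_session <- function(config, protocol = c("both", "dynamic",
                                                  "static")) {
  protocol <- match.arg(protocol)
  set.seed(config$seed)
  screen <- config$ground_truth$screen
  dt <- 1 / config$sample_rate
  times <- list(); targets <- list(); phases <- list(); sids <- list()
  events <- list()
  t0 <- 0
  if (protocol %in% c("both", "dynamic")) {
    path <- dynamic_stimulus_path(config$dynamic_s, seed = NULL,
                                  screen = screen)
    tt <- seq(0, config$dynamic_s - dt / 2, by = dt)
    times[[length(times) + 1]] <- tt
    targets[[length(targets) + 1]] <- path$position(tt)
    phases[[length(phases) + 1]] <- rep("dynamic", length(tt))
    sids[[length(sids) + 1]] <- rep(NA_integer_, length(tt))
    ev <- path$events; ev$phase <- "dynamic"; ev$grid_id <- NA_integer_
    events[[length(events) + 1]] <- ev
    t0 <- config$dynamic_s
  }
  if (protocol %in% c("both", "static")) {
    sev <- static_stimulus_sequence(seed = NULL, screen = screen,
                                    dot_s = config$static_dot_s)
    dur <- sum(sev$duration)
    tt <- seq(0, dur - dt / 2, by = dt)
    idx <- pmin(nrow(sev), floor(tt / config$static_dot_s) + 1)
    times[[length(times) + 1]] <- t0 + tt
    targets[[length(targets) + 1]] <- cbind(sev$u0[idx], sev$v0[idx])
    phases[[length(phases) + 1]] <- rep("static", length(tt))
    sids[[length(sids) + 1]] <- idx
    sev$onset <- sev$onset + t0; sev$phase <- "static"
    events[[length(events) + 1]] <- sev
  }
  t_all <- do.call(c, times)
  tg <- do.call(rbind, targets)
  head_df <- simulate_head_trajectory(config, t_all,
                                      target_world = por_to_world(screen, tg))
  pupil <- forward_model(head_df, tg, config$ground_truth,
                         noise_pupil = config$noise_pupil,
                         fixation_jitter = config$fixation_jitter)
  out <- gaze_session(data.frame(
    t = t_all, head_df[, -1], p_x = pupil$p_x, p_y = pupil$p_y,
    stim_u = tg[, 1], stim_v = tg[, 2],
    phase = do.call(c, phases), stim_id = do.call(c, sids)
  ), user = sprintf("sim-seed-%d", config$seed))
  ev <- do.call(rbind, lapply(events, function(e) {
    e[setdiff(names(events[[length(events)]]), names(e))] <- NA
    e
  }))
  attr(out, "events") <- ev
  attr(out, "config") <- config
  out
}
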