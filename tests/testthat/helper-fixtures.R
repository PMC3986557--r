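# Shared fixtures: cheap noiseless configurations and hand-built sessions.
# All simulation-based tests run at reduced sample rates (5-25 Hz instead
# of the 60 Hz default) to keep the suite fast; the generators themselves
# are rate-agnostic.

noiseless_cfg <- function(seed, sample_rate = 10, ...) {
  sim_config(seed = seed, sample_rate = sample_rate, noise_pupil = 0,
             noise_head_pos = 0, noise_head_rot = 0, ...)
}

# A minimal hand-built session: head fixed at the chin rest, fixating a
# small set of targets exactly (pupil from the ground-truth forward model).
tiny_session <- function(n = 40, truth = default_truth(), seed = 42) {
  set.seed(seed)
  scr <- truth$screen
  tg <- cbind(runif(n, 100, scr$width_px - 100),
              runif(n, 100, scr$height_px - 100))
  head <- data.frame(t = seq(0, by = 0.1, length.out = n),
                     h_x = -140 + runif(n, -5, 5),
                     h_y = runif(n, -5, 5), h_z = runif(n, -5, 5),
                     h_phi = runif(n, -3, 3), h_theta = runif(n, -8, 8),
                     h_psi = runif(n, -8, 8))
  pup <- forward_model(head, tg, truth)
  gaze_session(data.frame(head, pup, stim_u = tg[, 1], stim_v = tg[, 2],
                          phase = "dynamic", stim_id = NA_integer_))
}

quick_calib_control <- function() {
  calib_control(maxit = 100, starts = rbind(rep(0, 6), c(8, 0, -8, 0, 0, 0)))
}

rand_rot <- function() {
  a <- c(runif(1, -170, 170), runif(1, -80, 80), runif(1, -170, 170))
  rotation_from_euler(a[1], a[2], a[3])
}
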