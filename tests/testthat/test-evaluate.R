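test_that("split_session divides phases at 2 minutes into disjoint parts", {
  sess <- simulate_session(noiseless_cfg(601, sample_rate = 5))
  sp <- split_session(sess)
  expect_named(sp, c("calib_dynamic", "valid_dynamic", "calib_static",
                     "valid_static"))
  # dynamic: first 2 min calib, last minute valid
  expect_lt(max(sp$calib_dynamic$t), 120)
  expect_gte(min(sp$valid_dynamic$t), 120)
  expect_equal(nrow(sp$calib_dynamic) + nrow(sp$valid_dynamic), 180 * 5)
  # static splits contain only filtered fixations
  filt <- filter_fixations(sess[sess$phase == "static", ])
  expect_equal(nrow(sp$calib_static) + nrow(sp$valid_static), nrow(filt))
  expect_true(max(sp$calib_static$t) < min(sp$valid_static$t))
  expect_error(split_session(sess[sess$t < 100, ]), "too short")
})

test_that("fixation filter keeps exactly the last 250 ms of each dot", {
  sess <- simulate_session(sim_config(seed = 602, sample_rate = 60),
                           protocol = "static")
  filt <- filter_fixations(sess)
  cnt <- table(filt$stim_id)
  expect_true(all(cnt == 15))              # 0.25 s x 60 Hz
  expect_equal(length(cnt), 200)
  # retained window starts 1250 ms after onset
  on1 <- min(sess$t[sess$stim_id == 1])
  expect_gte(min(filt$t[filt$stim_id == 1]) - on1, 1.25)
  expect_lt(max(filt$t[filt$stim_id == 1]) - on1, 1.5)
  # a presentation shorter than the settle time retains nothing
  short <- sess[sess$stim_id == 1 & sess$t - on1 < 1.2, ]
  expect_equal(nrow(filter_fixations(short)), 0)
})

test_that("angular_error matches planar geometry and is symmetric", {
  scr <- default_screen()
  head <- data.frame(h_x = -140, h_y = 0, h_z = 0)
  e0 <- angular_error(head, c(512, 384), c(512, 384), scr)
  expect_equal(unlist(e0), c(azimuth = 0, elevation = 0, combined = 0))
  # pure horizontal displacement at eye height: elevation 0, combined =
  # |azimuth| = the closed-form angle difference
  px_cm <- scr$width_cm / scr$width_px
  est <- c(512 + 100, 384)
  ex <- atan2(100 * px_cm, 140) * 180 / pi
  e1 <- angular_error(head, est, c(512, 384), scr)
  expect_equal(e1$elevation, 0, tolerance = 1e-9)
  expect_equal(abs(e1$azimuth), ex, tolerance = 1e-9)
  expect_equal(e1$combined, abs(e1$azimuth), tolerance = 1e-9)
  # combined error is symmetric in (est, true)
  set.seed(603)
  for (i in 1:10) {
    a <- c(runif(1, 0, 1024), runif(1, 0, 768))
    b <- c(runif(1, 0, 1024), runif(1, 0, 768))
    h <- data.frame(h_x = runif(1, -200, -80), h_y = runif(1, -50, 50),
                    h_z = runif(1, -30, 30))
    expect_equal(angular_error(h, a, b, scr)$combined,
                 angular_error(h, b, a, scr)$combined, tolerance = 1e-12)
  }
  # small-angle consistency: combined <= |azimuth| + |elevation| + tol
  e2 <- angular_error(head, c(600, 300), c(512, 384), scr)
  expect_lte(e2$combined, abs(e2$azimuth) + abs(e2$elevation) + 0.05)
  expect_error(angular_error(data.frame(h_x = 0, h_y = 0, h_z = 0),
                             c(512, 384), c(512, 384), scr), "plane")
})

test_that("overlap_metric counts jointly occupied 5-D bins", {
  mk <- function(hx, hy, hz, px, py) {
    n <- length(hx)
    gaze_session(data.frame(t = seq_len(n), h_x = hx, h_y = hy, h_z = hz,
                            h_phi = 0, h_theta = 0, h_psi = 0, p_x = px,
                            p_y = py, stim_u = 1, stim_v = 1,
                            phase = "none", stim_id = NA))
  }
  a <- mk(c(1, 15, 25, 99), c(0, 0, 0, 0), rep(0, 4), rep(0, 4), rep(0, 4))
  expect_equal(overlap_metric(a, a), 1)
  b <- mk(c(1, 15, 25, 99) + 1000, rep(0, 4), rep(0, 4), rep(0, 4), rep(0, 4))
  expect_equal(overlap_metric(a, b), 0)
  # validation occupies 4 h_x bins {0,1,2,9}; calibration covers exactly 2
  calib <- mk(c(5, 15), c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  expect_equal(overlap_metric(calib, a), 0.5)
  # monotone under augmenting calibration
  calib2 <- mk(c(5, 15, 25), rep(0, 3), rep(0, 3), rep(0, 3), rep(0, 3))
  expect_gte(overlap_metric(calib2, a), overlap_metric(calib, a))
  # pupil bins use the 1500-unit width
  c1 <- mk(0, 0, 0, 100, 0)
  c2 <- mk(0, 0, 0, 1400, 0)
  c3 <- mk(0, 0, 0, 1600, 0)
  expect_equal(overlap_metric(c1, c2), 1)   # same 1500-unit bin
  expect_equal(overlap_metric(c1, c3), 0)
  expect_error(overlap_metric(a[0, ], a), "empty")
  # exclusive-denominator reading exposed behind the flag
  expect_equal(overlap_metric(calib, a, denominator = "exclusive"), 1)
})

test_that("reject_by_confidence thresholds the mean predictive sigma", {
  pr <- data.frame(u = 1:5, v = 1:5, sigma_u = c(0, 10, 50, 80, 200),
                   sigma_v = c(0, 10, 60, 90, 100))
  all_kept <- reject_by_confidence(pr, Inf)
  expect_equal(all_kept$rejected_fraction, 0)
  tiny <- reject_by_confidence(pr, 1e-9)
  expect_equal(tiny$rejected_fraction, 0.8)   # only the zero-sigma row stays
  def <- reject_by_confidence(pr)             # default threshold 75 px
  expect_equal(def$rejected_fraction, 2 / 5)
  expect_equal(nrow(def$kept), 3)
  expect_error(reject_by_confidence(pr, 0), "threshold_px > 0")
})

test_that("run_evaluation reproduces gaze on a noiseless pairing", {
  sess <- simulate_session(noiseless_cfg(604, sample_rate = 5))
  sp <- split_session(sess)
  ev <- run_evaluation(eval_pairing(sp, "dynamic:dynamic"),
                       method = "geometric",
                       control = quick_calib_control())
  expect_lt(ev$combined_mean, 0.5)
  expect_equal(ev$n, nrow(sp$valid_dynamic))
  expect_true(ev$overlap > 0 && ev$overlap <= 1)
  expect_output(print(ev), "combined error")
  # the combined pairing trains on dynamic + static calibration segments
  cp <- eval_pairing(sp, "combined:combined")
  expect_equal(nrow(cp$calib), nrow(sp$calib_dynamic) + nrow(sp$calib_static))
  expect_true(!is.unsorted(cp$calib$t))
})
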