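test_that("head_to_eye applies the rigid transform correctly", {
  h0 <- c(h_x = 0, h_y = 0, h_z = 0, h_phi = 0, h_theta = 0, h_psi = 0)
  # identity transform: eye pose equals head pose
  e <- head_to_eye(h0, head_eye_params())
  expect_equal(e$position, c(0, 0, 0))
  expect_equal(e$rotation, diag(3))
  # pure translation offset
  e2 <- head_to_eye(h0, head_eye_params(z = 5))
  expect_equal(e2$position, c(0, 0, 5))
  # head yawed 90 with offset (10, 0, 0): hand-computed Rz(90) %*% (10,0,0)
  h90 <- c(h_x = 1, h_y = 2, h_z = 3, h_phi = 0, h_theta = 0, h_psi = 90)
  e3 <- head_to_eye(h90, head_eye_params(x = 10))
  expect_equal(e3$position, c(1, 2, 3) + c(0, 10, 0), tolerance = 1e-12)
  # R_e = R_h R_T
  e4 <- head_to_eye(h90, head_eye_params(theta = 30))
  expect_equal(e4$rotation,
               rotation_from_euler(0, 0, 90) %*% rotation_from_euler(0, 30, 0),
               tolerance = 1e-12)
})

test_that("pupil_to_angles is the stated linear map", {
  expect_equal(unname(pupil_to_angles(c(10, 5), eye_model_params())),
               c(10, 5))
  cst <- eye_model_params(m_phi = 0, b_phi = 3, m_theta = 0, b_theta = -2)
  expect_equal(unname(pupil_to_angles(c(99, -99), cst)), c(3, -2))
  em <- eye_model_params(m_phi = 0.02, b_phi = -2, m_theta = 0.03,
                         b_theta = 1)
  P <- rbind(c(100, 50), c(-200, 0))
  A <- pupil_to_angles(P, em)
  expect_equal(A[, 1], 0.02 * P[, 1] - 2)
  expect_equal(A[, 2], 0.03 * P[, 2] + 1)
})

test_that("fit_eye_model matches a least-squares oracle and detects degeneracy", {
  set.seed(301)
  # noiseless linear data: exact recovery
  P <- cbind(runif(30, -1000, 1000), runif(30, -800, 800))
  A <- cbind(0.021 * P[, 1] - 1.7, 0.019 * P[, 2] + 2.2)
  em <- fit_eye_model(P, A)
  expect_equal(em$m_phi, 0.021, tolerance = 1e-9)
  expect_equal(em$b_phi, -1.7, tolerance = 1e-9)
  expect_equal(em$m_theta, 0.019, tolerance = 1e-9)
  expect_equal(em$b_theta, 2.2, tolerance = 1e-9)
  # noisy data: agrees with lm() as the independent oracle
  An <- A + matrix(rnorm(60, 0, 0.5), ncol = 2)
  em2 <- fit_eye_model(P, An)
  o1 <- unname(coef(lm(An[, 1] ~ P[, 1])))
  o2 <- unname(coef(lm(An[, 2] ~ P[, 2])))
  expect_equal(c(em2$b_phi, em2$m_phi), o1, tolerance = 1e-9)
  expect_equal(c(em2$b_theta, em2$m_theta), o2, tolerance = 1e-9)
  expect_error(fit_eye_model(P[1, , drop = FALSE], A[1, , drop = FALSE]),
               "at least 2")
  Pc <- cbind(rep(5, 10), runif(10))
  expect_error(fit_eye_model(Pc, A[1:10, ]), "degenerate")
})

test_that("predict_geometric inverts the forward model at zero noise", {
  sess <- tiny_session(60)
  pred <- predict_geometric(default_truth(), sess)
  expect_lt(max(abs(pred$u - sess$stim_u)), 1e-6)
  expect_lt(max(abs(pred$v - sess$stim_v)), 1e-6)
  expect_true(all(pred$on_screen))
})

test_that("POR is unchanged when the head translates along the gaze direction", {
  truth <- default_truth()
  sess <- tiny_session(5)
  p0 <- predict_geometric(truth, sess)
  eyes <- head_to_eye(sess[1, ], truth$head_eye)
  for (i in seq_len(nrow(sess))) {
    eye <- head_to_eye(sess[i, ], truth$head_eye)
    ang <- pupil_to_angles(c(sess$p_x[i], sess$p_y[i]), truth$eye)
    g <- gaze_vector(eye, ang)
    s2 <- sess[i, , drop = FALSE]
    s2$h_x <- s2$h_x + 12 * g$direction[1]
    s2$h_y <- s2$h_y + 12 * g$direction[2]
    s2$h_z <- s2$h_z + 12 * g$direction[3]
    p2 <- predict_geometric(truth, s2)
    expect_equal(c(p2$u, p2$v), c(p0$u[i], p0$v[i]), tolerance = 1e-8)
  }
})

test_that("geometric_cost is the mean pixel distance with a miss penalty", {
  sess <- tiny_session(50)
  truth <- default_truth()
  expect_lt(geometric_cost(truth, sess), 1e-6)
  # shifting every target by exactly 10 px forces cost 10
  s10 <- sess
  s10$stim_u <- s10$stim_u + 10
  expect_equal(geometric_cost(truth, s10), 10, tolerance = 1e-6)
  # brute-force loop oracle on a perturbed model
  m2 <- geometric_model(head_eye_params(x = 2, z = -3),
                        eye_model_params(0.018, -1, 0.022, 2),
                        truth$screen)
  oracle <- mean(vapply(seq_len(nrow(sess)), function(i) {
    eye <- head_to_eye(sess[i, ], m2$head_eye)
    ang <- pupil_to_angles(c(sess$p_x[i], sess$p_y[i]), m2$eye)
    hit <- intersect_gaze(m2$screen, eye, ang)
    sqrt(sum((hit$por - c(sess$stim_u[i], sess$stim_v[i]))^2))
  }, numeric(1)))
  expect_equal(geometric_cost(m2, sess), oracle, tolerance = 1e-9)
  expect_error(geometric_cost(truth, sess[0, ]), "no usable calibration")
})

test_that("calibrate_user recovers predictions on noiseless data", {
  sess <- tiny_session(80, seed = 7)
  fit <- calibrate_user(sess, control = quick_calib_control())
  expect_lt(fit$cost, 0.05)
  model <- geometric_model(fit$head_eye, fit$eye, default_screen())
  hold <- tiny_session(40, seed = 8)
  pred <- predict_geometric(model, hold)
  err <- angular_error(hold, as.matrix(pred[, c("u", "v")]),
                       cbind(hold$stim_u, hold$stim_v))
  expect_lt(mean(err$combined), 0.1)
})

test_that("data generated with a zero head-eye transform is recovered as such", {
  truth0 <- geometric_model(head_eye_params(),
                            eye_model_params(0.02, 0, 0.02, 0))
  sess <- tiny_session(80, truth = truth0, seed = 9)
  fit <- calibrate_user(sess, control = quick_calib_control())
  model <- geometric_model(fit$head_eye, fit$eye, default_screen())
  p1 <- predict_geometric(model, sess)
  p0 <- predict_geometric(truth0, sess)
  expect_lt(max(abs(p1$u - p0$u)), 0.5)
  expect_lt(max(abs(p1$v - p0$v)), 0.5)
})

test_that("calibrate_user rejects empty or degenerate sessions", {
  sess <- tiny_session(30)
  expect_error(calibrate_user(sess[0, ]), "empty|few")
  expect_error(calibrate_user(sess[1:4, ]), "few")
})

test_that("gauge freedom: yaw offset in the transform trades against b_phi", {
  # Rz(5) after R_T commutes with the horizontal eye rotation, so shifting
  # b_phi by -5 gives the identical prediction function
  m1 <- default_truth()
  m2 <- geometric_model(
    head_eye_params(x = 8, z = -9, psi = 5),
    eye_model_params(m_phi = 0.02, b_phi = m1$eye$b_phi - 5,
                     m_theta = 0.02, b_theta = m1$eye$b_theta),
    m1$screen)
  sess <- tiny_session(40, seed = 11)
  p1 <- predict_geometric(m1, sess)
  p2 <- predict_geometric(m2, sess)
  expect_equal(p2$u, p1$u, tolerance = 1e-6)
  expect_equal(p2$v, p1$v, tolerance = 1e-6)
})
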