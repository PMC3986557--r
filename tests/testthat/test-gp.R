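# Small-instance oracles: dense multivariate-Gaussian conditioning and
# direct inverse/determinant evaluation, independent of the Cholesky path
# used by the implementation.

dense_lml <- function(theta, X, y, kernel = "abs") {
  K <- build_kernel_matrix(X, theta, kernel)
  n <- length(y)
  as.numeric(-0.5 * t(y) %*% solve(K, y) -
               0.5 * determinant(K, logarithm = TRUE)$modulus -
               0.5 * n * log(2 * pi))
}

dense_conditional <- function(theta, X, y, xs, kernel = "abs") {
  # brute-force conditioning of the joint Gaussian [f(xs), y]
  kfun <- function(a, b) ard_kernel(a, b, theta, kernel)
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- kfun(X[i, ], X[j, ])
  K <- K + diag(theta$sigma_n^2, n)
  ks <- vapply(1:n, function(i) kfun(xs, X[i, ]), numeric(1))
  Ki <- solve(K)
  list(mean = as.numeric(ks %*% Ki %*% y),
       var = kfun(xs, xs) - as.numeric(ks %*% Ki %*% ks))
}

test_that("ard_kernel matches its closed form and is symmetric", {
  th <- gp_hyper(sigma_s = 2.5, sigma_n = 0.3, l = c(1, 2, 4))
  x <- c(1, 2, 3)
  expect_equal(ard_kernel(x, x, th), 2.5)
  # single active dimension with |dx| = 2 l: sigma_s * exp(-1)
  th1 <- gp_hyper(sigma_s = 3, sigma_n = 0.1, l = 5)
  expect_equal(ard_kernel(0, 10, th1), 3 * exp(-1), tolerance = 1e-12)
  set.seed(401)
  for (i in 1:10) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(ard_kernel(a, b, th), ard_kernel(b, a, th))
    expect_gt(ard_kernel(a, b, th), 0)
    expect_lte(ard_kernel(a, b, th), th$sigma_s)
  }
  expect_error(gp_hyper(1, 1, c(1, -1)), "positive")
})

test_that("build_kernel_matrix matches a double-loop oracle", {
  th <- gp_hyper(sigma_s = 1.8, sigma_n = 0.4, l = c(0.5, 1, 2, 4))
  # n = 1
  expect_equal(build_kernel_matrix(matrix(0, 1, 4), th),
               matrix(1.8 + 0.16, 1, 1))
  # duplicated rows: off-diagonal sigma_s, diagonal sigma_s + sigma_n^2
  X2 <- matrix(1, 2, 4)
  K2 <- build_kernel_matrix(X2, th)
  expect_equal(K2[1, 2], 1.8)
  expect_equal(K2[1, 1], 1.8 + 0.16)
  set.seed(402)
  X <- matrix(rnorm(7 * 4), 7, 4)
  K <- build_kernel_matrix(X, th)
  oracle <- matrix(0, 7, 7)
  for (i in 1:7) for (j in 1:7) {
    oracle[i, j] <- ard_kernel(X[i, ], X[j, ], th) + (i == j) * th$sigma_n^2
  }
  expect_equal(K, oracle, tolerance = 1e-12)
  expect_equal(K, t(K))
})

test_that("log marginal likelihood matches closed form and dense oracle", {
  th <- gp_hyper(sigma_s = 2, sigma_n = 0.5, l = 1)
  # n = 1, y = 0: -log(sigma_s + sigma_n^2)/2 - log(2 pi)/2
  expect_equal(log_marginal_likelihood(th, matrix(0, 1, 1), 0),
               -0.5 * log(2.25) - 0.5 * log(2 * pi), tolerance = 1e-12)
  set.seed(403)
  th5 <- gp_hyper(sigma_s = 1.3, sigma_n = 0.7, l = c(1, 2, 0.5))
  X <- matrix(rnorm(15), 5, 3)
  y <- rnorm(5)
  expect_equal(log_marginal_likelihood(th5, X, y), dense_lml(th5, X, y),
               tolerance = 1e-9)
})

test_that("analytic LML gradient matches finite differences", {
  set.seed(404)
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- rnorm(12)
  for (kern in c("abs", "sq")) {
    p0 <- log(c(1.4, 0.6, 0.8, 1.5, 2.2))
    g <- gazecal:::lml_with_grad(p0, X, y, kern)
    num <- vapply(seq_along(p0), function(j) {
      h <- 1e-6
      pp <- p0; pp[j] <- pp[j] + h
      pm <- p0; pm[j] <- pm[j] - h
      (gazecal:::lml_with_grad(pp, X, y, kern)$lml -
         gazecal:::lml_with_grad(pm, X, y, kern)$lml) / (2 * h)
    }, numeric(1))
    expect_equal(g$grad, num, tolerance = 1e-5)
  }
})

test_that("gp_predict interpolates, reverts to the prior, matches the oracle", {
  # single noiseless training point: exact reproduction, zero variance
  th <- gp_hyper(sigma_s = 2, sigma_n = 0, l = c(1, 1))
  gp <- gp_fit(matrix(c(0.3, -0.2), 1, 2), 5, th)
  pr <- gp_predict(gp, c(0.3, -0.2))
  expect_equal(pr$mean, 5, tolerance = 1e-6)
  expect_equal(pr$var, 0, tolerance = 1e-6)
  # far from all training points: mean -> 0, variance -> sigma_s
  far <- gp_predict(gp, c(1e4, -1e4))
  expect_equal(far$mean, 0, tolerance = 1e-9)
  expect_equal(far$var, 2, tolerance = 1e-9)
  # 3-point brute-force conditioning oracle
  set.seed(405)
  th3 <- gp_hyper(sigma_s = 1.5, sigma_n = 0.3, l = c(0.7, 1.3))
  X <- matrix(rnorm(6), 3, 2)
  y <- rnorm(3)
  gp3 <- gp_fit(X, y, th3)
  xs <- rnorm(2)
  pr3 <- gp_predict(gp3, xs)
  oracle <- dense_conditional(th3, X, y, xs)
  expect_equal(pr3$mean, oracle$mean, tolerance = 1e-9)
  expect_equal(pr3$var, oracle$var, tolerance = 1e-9)
})

test_that("predictive variance is non-negative and grows away from the data", {
  set.seed(406)
  th <- gp_hyper(sigma_s = 1, sigma_n = 0.1, l = rep(2, 2))
  X <- matrix(runif(40, -1, 1), 20, 2)
  gp <- gp_fit(X, rnorm(20), th)
  offs <- seq(0, 20, by = 2)
  vs <- vapply(offs, function(o) gp_predict(gp, c(1 + o, 0))$var, numeric(1))
  expect_true(all(vs >= 0))
  expect_true(all(diff(vs) > -1e-12))
})

test_that("hyperparameter fit starts at all ones, improves LML, respects bounds", {
  set.seed(407)
  n <- 80
  X <- cbind(runif(n, -2, 2), runif(n, -2, 2))
  y <- 3 * X[, 1] - 2 * X[, 2]   # noise-free, smooth
  th <- optimize_hyperparameters(X, y, maxit = 60)
  expect_gte(attr(th, "lml"), attr(th, "lml0"))
  v <- c(th$sigma_s, th$sigma_n, th$l)
  expect_true(all(v > 0 & v <= exp(10) + 1e-6))
  # noise-free data drives sigma_n toward its lower bound
  expect_lt(th$sigma_n, 0.01)
  expect_error(optimize_hyperparameters(X[1:5, ], y[1:5]), "at least 10")
})

test_that("LML at generating hyperparameters is recovered from GP draws", {
  set.seed(408)
  n <- 200
  X <- cbind(runif(n, -3, 3), runif(n, -3, 3))
  th_true <- gp_hyper(sigma_s = 4, sigma_n = 0.2, l = c(1.5, 0.8))
  K <- build_kernel_matrix(X, th_true)
  y <- as.numeric(t(chol(K)) %*% rnorm(n))
  th_hat <- optimize_hyperparameters(X, y, maxit = 150)
  lml_true <- log_marginal_likelihood(th_true, X, y)
  expect_lt(abs(attr(th_hat, "lml") - lml_true) / abs(lml_true), 0.01)
  # a fitted model should never score below the generating parameters by much
  expect_gt(attr(th_hat, "lml"), lml_true - abs(lml_true) * 0.01)
})

test_that("LML decreases when sigma_n is inflated on well-fit noiseless data", {
  set.seed(409)
  X <- matrix(runif(30, -1, 1), 15, 2)
  y <- X[, 1]^2
  th_fit <- optimize_hyperparameters(X, y, maxit = 80)
  l0 <- log_marginal_likelihood(th_fit, X, y)
  th_noisy <- gp_hyper(th_fit$sigma_s, th_fit$sigma_n + 1, th_fit$l)
  expect_lt(log_marginal_likelihood(th_noisy, X, y), l0)
})

test_that("predict_por composes the per-axis GPs and supports a fast path", {
  sess <- tiny_session(60, seed = 13)
  gps <- train_gaze_gp(sess, subset_size = 60, maxit = 60)
  X <- gazecal:::session_input_matrix(sess)
  pp <- predict_por(gps, X[1:5, ])
  for (i in 1:5) {
    expect_equal(pp$u[i], gp_predict(gps$u, X[i, ])$mean)
    expect_equal(pp$v[i], gp_predict(gps$v, X[i, ])$mean)
  }
  expect_true(all(c(pp$sigma_u, pp$sigma_v) >= 0))
  fast <- predict_por(gps, X[1:5, ], se = FALSE)
  expect_identical(fast$u, pp$u)
  expect_identical(fast$v, pp$v)
  expect_null(fast$sigma_u)
  # interpolation: training targets reproduced closely at training inputs
  prt <- predict_por(gps, X, se = FALSE)
  expect_lt(mean(abs(prt$u - sess$stim_u)), 2)
  expect_lt(mean(abs(prt$v - sess$stim_v)), 2)
  # subset_size larger than the data uses all rows
  expect_equal(nrow(gps$u$X), nrow(sess))
})
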