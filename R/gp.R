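# Gaussian process regression of screen coordinates on the 8-D input
# (h_x, h_y, h_z, h_phi, h_theta, h_psi, p_x, p_y): ARD kernel, marginal
# likelihood hyperparameter fitting, predictive mean and variance.
#
# The default kernel is exponential decay in the length-scale-weighted
# absolute per-dimension distance,
#   k(xi, xj) = sigma_s * exp(-1/2 * sum_d |xi_d - xj_d| / l_d),
# as printed in the source method; a squared-exponential variant
# (sum_d (dx/l_d)^2 inside the exponent) is available via kernel = "sq".

#' GP hyperparameters
#'
#' @param sigma_s signal variance (`k(x, x) = sigma_s`).
#' @param sigma_n noise standard deviation (enters the kernel matrix
#'   diagonal as `sigma_n^2`).
#' @param l per-dimension length scales (one per input dimension).
#' @return object of class `gp_hyper`.
#' @export
gp_hyper <- function(sigma_s = 1, sigma_n = 1, l = rep(1, 8)) {
  if (!all(is.finite(c(sigma_s, sigma_n, l))) ||
      any(c(sigma_s, l) <= 0) || sigma_n < 0) {
    stop("hyperparameters must be finite and positive (sigma_n may be 0)")
  }
  if (any(c(sigma_s, sigma_n, l) > exp(10) * (1 + 1e-12))) {
    stop("hyperparameters must lie in (0, e^10]")
  }
  structure(list(sigma_s = sigma_s, sigma_n = sigma_n, l = as.numeric(l)),
            class = "gp_hyper")
}

# Weighted distance sum between rows of X1 (m x D) and X2 (n x D):
# "abs": sum_d |dx|/l_d ; "sq": sum_d (dx/l_d)^2. Returns m x n.
scaled_dist <- function(X1, X2, l, kernel) {
  m <- nrow(X1); n <- nrow(X2)
  S <- matrix(0, m, n)
  for (d in seq_len(ncol(X1))) {
    dx <- outer(X1[, d], X2[, d], "-")
    S <- S + if (kernel == "abs") abs(dx) / l[d] else (dx / l[d])^2
  }
  S
}

#' ARD kernel function
#'
#' @param x_i,x_j input vectors of common length D.
#' @param theta a [gp_hyper()] object with D length scales.
#' @param kernel `"abs"` (as-printed exponential in the absolute scaled
#'   distance, the default) or `"sq"` (squared exponential).
#' @return scalar covariance; `k(x, x) = sigma_s` and `0 < k <= sigma_s`.
#' @export
ard_kernel <- function(x_i, x_j, theta, kernel = c("abs", "sq")) {
  kernel <- match.arg(kernel)
  stopifnot(length(x_i) == length(x_j), length(theta$l) == length(x_i))
  S <- scaled_dist(matrix(x_i, 1), matrix(x_j, 1), theta$l, kernel)
  theta$sigma_s * exp(-0.5 * S[1, 1])
}

# Dense cross-covariance (no noise term): m x n.
kernel_cross <- function(X1, X2, theta, kernel) {
  theta$sigma_s * exp(-0.5 * scaled_dist(X1, X2, theta$l, kernel))
}

#' Build the kernel matrix of a training set
#'
#' `K_ij = k(x_i, x_j) + sigma_n^2 delta_ij`, with adaptive diagonal jitter
#' to guarantee a positive-definite factorization.
#'
#' @param X n x D matrix of inputs.
#' @inheritParams ard_kernel
#' @return n x n symmetric positive-definite matrix.
#' @export
build_kernel_matrix <- function(X, theta, kernel = c("abs", "sq")) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 1, length(theta$l) == ncol(X))
  kernel_cross(X, X, theta, kernel) + diag(theta$sigma_n^2, nrow(X))
}

# Cholesky with adaptive jitter 1e-10 -> 1e-4 (x10 steps). Returns
# list(L = upper-triangular chol, jitter).
chol_jitter <- function(K) {
  jit <- 0
  repeat {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    jit <- if (jit == 0) 1e-10 else jit * 10
    if (jit > 1e-4) stop("kernel matrix factorization failed even with jitter")
  }
}

#' Log marginal likelihood of a GP
#'
#' `-1/2 y' K^-1 y - 1/2 log|K| - n/2 log(2 pi)`, evaluated through a
#' Cholesky factorization of the kernel matrix.
#'
#' @param theta a [gp_hyper()] object.
#' @param X n x D input matrix.
#' @param y length-n target vector.
#' @inheritParams ard_kernel
#' @return scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(theta, X, y, kernel = c("abs", "sq")) {
  kernel <- match.arg(kernel)
  K <- build_kernel_matrix(X, theta, kernel)
  cf <- chol_jitter(K)
  alpha <- backsolve(cf$L, backsolve(cf$L, y, transpose = TRUE))
  n <- length(y)
  -0.5 * sum(y * alpha) - sum(log(diag(cf$L))) - 0.5 * n * log(2 * pi)
}

# LML and its gradient with respect to the log hyperparameters
# (log sigma_s, log sigma_n, log l_1..l_D). Shares one factorization.
lml_with_grad <- function(logpar, X, y, kernel) {
  D <- ncol(X)
  sigma_s <- exp(logpar[1]); sigma_n <- exp(logpar[2])
  l <- exp(logpar[-(1:2)])
  n <- nrow(X)
  # per-dimension distance pieces are reused by the gradient
  Dd <- vector("list", D)
  S <- matrix(0, n, n)
  for (d in seq_len(D)) {
    dx <- outer(X[, d], X[, d], "-")
    Dd[[d]] <- if (kernel == "abs") abs(dx) else dx^2
    S <- S + if (kernel == "abs") Dd[[d]] / l[d] else Dd[[d]] / l[d]^2
  }
  Kc <- sigma_s * exp(-0.5 * S)
  K <- Kc + diag(sigma_n^2, n)
  cf <- tryCatch(chol_jitter(K), error = function(e) NULL)
  if (is.null(cf)) {
    return(list(lml = -1e10, grad = rep(0, D + 2)))
  }
  alpha <- backsolve(cf$L, backsolve(cf$L, y, transpose = TRUE))
  lml <- -0.5 * sum(y * alpha) - sum(log(diag(cf$L))) - 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(cf$L)
  A <- tcrossprod(alpha) - Kinv       # d lml / dK = A / 2
  grad <- numeric(D + 2)
  grad[1] <- 0.5 * sum(A * Kc)                       # d/d log sigma_s
  grad[2] <- 0.5 * sum(diag(A)) * 2 * sigma_n^2      # d/d log sigma_n
  for (d in seq_len(D)) {
    dK <- if (kernel == "abs") Kc * (0.5 * Dd[[d]] / l[d])
          else Kc * (Dd[[d]] / l[d]^2)
    grad[d + 2] <- 0.5 * sum(A * dK)
  }
  list(lml = lml, grad = grad)
}

#' Fit GP hyperparameters by marginal-likelihood maximization
#'
#' Optimizes in log space with box bounds `[log(1e-6), 10]` (the upper
#' bound realizing the `(0, e^10]` search range), starting from all
#' parameters equal to 1, using bounded quasi-Newton steps with analytic
#' gradients. The achieved log marginal likelihood is never below the
#' starting point's.
#'
#' @param X n x D input matrix (n >= 10).
#' @param y length-n target vector.
#' @inheritParams ard_kernel
#' @param maxit maximum optimizer iterations.
#' @param extra_start logical; besides the all-ones start, also try one
#'   data-scaled start (length scales at the per-dimension spread, signal
#'   variance near the target variance) and keep the better optimum. With
#'   raw pixel/tracker units the all-ones start can sit in a flat
#'   "all-noise" basin, which the second start escapes.
#' @return a [gp_hyper()] object with attributes `lml` (achieved value) and
#'   `lml0` (value at the all-ones start).
#' @export
optimize_hyperparameters <- function(X, y, kernel = c("abs", "sq"),
                                     maxit = 200, extra_start = TRUE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (nrow(X) < 10) stop("need at least 10 samples to fit hyperparameters")
  D <- ncol(X)
  lower <- rep(log(1e-6), D + 2)
  upper <- rep(10, D + 2)
  cache <- new.env()
  evalp <- function(p) {
    key <- paste(format(p, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- lml_with_grad(p, X, y, kernel)
      cache$key <- key
    }
    cache$val
  }
  fn <- function(p) -evalp(p)$lml
  gr <- function(p) -evalp(p)$grad
  p0 <- rep(0, D + 2)   # all parameters start at 1
  lml0 <- -fn(p0)
  starts <- list(p0)
  if (extra_start) {
    sdy <- max(stats::sd(y), 1e-3)
    sdx <- pmax(apply(X, 2, stats::sd), 1e-3)
    starts[[2]] <- pmin(pmax(log(c(sdy^2, 0.1 * sdy, sdx)), lower), upper)
  }
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, fn, gr, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = maxit, factr = 1e5))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$convergence != 0) {
    warning("hyperparameter optimization did not fully converge (code ",
            best$convergence, "); returning best-so-far")
  }
  par <- if (-best$value >= lml0) best$par else p0
  out <- gp_hyper(sigma_s = exp(par[1]), sigma_n = exp(par[2]),
                  l = exp(par[-(1:2)]))
  attr(out, "lml") <- max(-best$value, lml0)
  attr(out, "lml0") <- lml0
  out
}

#' Construct a trained single-axis GP
#'
#' Factorizes the training kernel matrix and precomputes `K^-1 y` so that
#' predictions are single matrix products.
#'
#' @param X n x D input matrix.
#' @param y length-n targets.
#' @param theta a [gp_hyper()] object.
#' @inheritParams ard_kernel
#' @return object of class `gaze_gp`.
#' @export
gp_fit <- function(X, y, theta, kernel = c("abs", "sq")) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  K <- build_kernel_matrix(X, theta, kernel)
  cf <- chol_jitter(K)
  structure(list(X = X, y = as.numeric(y), theta = theta, kernel = kernel,
                 L = cf$L, jitter = cf$jitter,
                 alpha = backsolve(cf$L, backsolve(cf$L, y, transpose = TRUE))),
            class = "gaze_gp")
}

#' GP predictive mean and variance
#'
#' `mu = K* K^-1 y`; `var = K** - K* K^-1 K*'`. Far from all training
#' points the prediction reverts to the prior: mean 0, variance `sigma_s`.
#' Variances are clipped at zero (with a warning below -1e-8).
#'
#' @param gp a trained [gp_fit()] object.
#' @param x_star single input vector or m x D matrix of query points.
#' @param se logical; compute predictive variances (skipping them roughly
#'   halves the cost).
#' @return list with `mean` (length m) and `var` (length m, or NULL when
#'   `se = FALSE`).
#' @export
gp_predict <- function(gp, x_star, se = TRUE) {
  if (is.null(dim(x_star))) x_star <- matrix(x_star, nrow = 1)
  ks <- kernel_cross(as.matrix(x_star), gp$X, gp$theta, gp$kernel)  # m x n
  mu <- as.numeric(ks %*% gp$alpha)
  v <- NULL
  if (se) {
    w <- backsolve(gp$L, t(ks), transpose = TRUE)   # n x m
    v <- gp$theta$sigma_s - colSums(w^2)
    if (any(v < -1e-8)) {
      warning(sprintf("predictive variance clipped from %.3g to 0", min(v)))
    }
    v <- pmax(v, 0)
  }
  list(mean = mu, var = v)
}

#' Train the POR Gaussian-process pair
#'
#' Fits one GP per screen axis (u and v). Hyperparameters are estimated on
#' a uniformly subsampled reduced subset of the calibration rows; the
#' kernel matrices are then built on the full calibration set (capped at
#' `max_train` rows for tractability).
#'
#' @param session a [gaze_session()].
#' @param subset_size rows used for hyperparameter fitting (default 500).
#' @param max_train cap on rows entering the kernel matrices (default 2000).
#' @inheritParams ard_kernel
#' @param maxit hyperparameter optimizer iterations.
#' @return list with elements `u` and `v` (trained [gp_fit()] objects) and
#'   `kernel`.
#' @export
train_gaze_gp <- function(session, subset_size = 500, max_train = 2000,
                          kernel = c("abs", "sq"), maxit = 200) {
  kernel <- match.arg(kernel)
  rows <- session_calib_rows(session)
  if (length(rows) < 10) stop("too few usable calibration samples (need >= 10)")
  X <- session_input_matrix(session)[rows, , drop = FALSE]
  Y <- session_target_matrix(session)[rows, , drop = FALSE]
  tr <- subsample_idx(nrow(X), max_train)
  sub <- tr[subsample_idx(length(tr), min(subset_size, length(tr)))]
  th_u <- optimize_hyperparameters(X[sub, , drop = FALSE], Y[sub, 1],
                                   kernel, maxit = maxit)
  th_v <- optimize_hyperparameters(X[sub, , drop = FALSE], Y[sub, 2],
                                   kernel, maxit = maxit)
  list(u = gp_fit(X[tr, , drop = FALSE], Y[tr, 1], th_u, kernel),
       v = gp_fit(X[tr, , drop = FALSE], Y[tr, 2], th_v, kernel),
       kernel = kernel)
}

#' Predict PORs with predictive standard deviations
#'
#' @param gps a trained GP pair from [train_gaze_gp()].
#' @param x_star single 8-D input or m x 8 matrix.
#' @param se logical; include predictive standard deviations.
#' @return data.frame with `u`, `v` and (when `se`) `sigma_u`, `sigma_v`
#'   in pixels.
#' @export
predict_por <- function(gps, x_star, se = TRUE) {
  pu <- gp_predict(gps$u, x_star, se = se)
  pv <- gp_predict(gps$v, x_star, se = se)
  out <- data.frame(u = pu$mean, v = pv$mean)
  if (se) {
    out$sigma_u <- sqrt(pu$var)
    out$sigma_v <- sqrt(pv$var)
  }
  out
}

#' @rdname predict.gaze_geometric
#' @export
predict.gaze_gpr <- function(object, newdata = NULL, se = TRUE, ...) {
  if (is.null(newdata)) newdata <- object$session
  X <- session_input_matrix(newdata)
  out <- predict_por(object$gps, X, se = se)
  out$on_screen <- on_screen(object$screen, as.matrix(out[, c("u", "v")]))
  out
}

#' @export
print.gaze_gpr <- function(x, ...) {
  cat("Gaussian-process gaze calibration\n")
  cat(sprintf("  %d training samples, %s kernel\n", x$n,
              if (x$gps$kernel == "abs") "ARD exponential (as printed)"
              else "ARD squared-exponential"))
  for (ax in c("u", "v")) {
    th <- x$gps[[ax]]$theta
    cat(sprintf("  %s axis: sigma_s = %.4g, sigma_n = %.4g\n",
                ax, th$sigma_s, th$sigma_n))
    cat("    length scales:", paste(sprintf("%.3g", th$l), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
coef.gaze_gpr <- function(object, ...) {
  nm <- c("h_x", "h_y", "h_z", "h_phi", "h_theta", "h_psi", "p_x", "p_y")
  out <- sapply(c("u", "v"), function(ax) {
    th <- object$gps[[ax]]$theta
    c(sigma_s = th$sigma_s, sigma_n = th$sigma_n,
      stats::setNames(th$l, paste0("l_", nm)))
  })
  t(out)
}
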