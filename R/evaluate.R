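# The calibration/validation protocol: dataset splitting, fixation
# filtering, angular-error metrics, the coverage-overlap statistic and
# confidence-based rejection.

#' Split a session into calibration and validation datasets
#'
#' The dynamic phase yields the first 2 minutes as Calib-Dynamic and the
#' remainder (the last minute of the standard protocol) as Valid-Dynamic.
#' The static phase is reduced to stable fixations (see
#' [filter_fixations()]) and split the same way at 2 minutes into
#' Calib-Static and Valid-Static (its last 3 minutes).
#'
#' @param session a [gaze_session()] containing a dynamic and/or static
#'   phase.
#' @param calib_s split time from each phase onset, seconds (default 120).
#' @return named list of [gaze_session()] objects: `calib_dynamic`,
#'   `valid_dynamic`, `calib_static`, `valid_static` (phases absent from
#'   the input are omitted).
#' @export
split_session <- function(session, calib_s = 120) {
  out <- list()
  for (ph in c("dynamic", "static")) {
    rows <- session$phase == ph
    if (!any(rows)) next
    part <- session[rows, , drop = FALSE]
    if (ph == "static") part <- filter_fixations(part)
    t0 <- min(session$t[rows])
    dur <- max(session$t[rows]) - t0
    if (dur <= calib_s) {
      stop(sprintf("%s phase is too short (%.1f s) to split at %g s",
                   ph, dur, calib_s))
    }
    cal <- part[part$t < t0 + calib_s, , drop = FALSE]
    val <- part[part$t >= t0 + calib_s, , drop = FALSE]
    out[[paste0("calib_", ph)]] <- gaze_session(cal, attr(session, "user"))
    out[[paste0("valid_", ph)]] <- gaze_session(val, attr(session, "user"))
  }
  if (!length(out)) stop("session contains no dynamic or static phase")
  out
}

#' Keep only stable fixations of a static phase
#'
#' For each static stimulus presentation, the first 1250 ms after onset
#' (covering the saccade toward and settling on the new target) are
#' discarded; only the remaining 250 ms of the 1500 ms presentation
#' represent the POR.
#'
#' @param session a [gaze_session()] with static-phase rows carrying
#'   `stim_id` presentation indices.
#' @param settle_s discarded interval after stimulus onset, seconds.
#' @param dot_s presentation duration, seconds.
#' @return the filtered [gaze_session()].
#' @export
filter_fixations <- function(session, settle_s = 1.25, dot_s = 1.5) {
  rows <- which(session$phase == "static" & !is.na(session$stim_id))
  if (!length(rows)) return(session[0, , drop = FALSE])
  sub <- session[rows, , drop = FALSE]
  onset <- stats::ave(sub$t, sub$stim_id, FUN = min)
  keep <- (sub$t - onset) >= settle_s & (sub$t - onset) < dot_s
  out <- sub[keep, , drop = FALSE]
  other <- session[session$phase != "static", , drop = FALSE]
  res <- rbind(other, out)
  res <- res[order(res$t), , drop = FALSE]
  class(res) <- class(session)
  attr(res, "user") <- attr(session, "user")
  res
}

#' Angular gaze errors in degrees of visual angle
#'
#' Compares the direction vectors from the current head position to the
#' estimated POR and to the true stimulus position on the screen. The
#' combined error is the angle between the two vectors; azimuth and
#' elevation are the differences of their world-frame spherical coordinates
#' (azimuth in the horizontal plane, elevation against it).
#'
#' @param head head pose(s): data.frame or [gaze_session()] rows with
#'   columns h_x, h_y, h_z.
#' @param est_por estimated POR pixels: `c(u, v)` or n x 2 matrix.
#' @param true_por true POR pixels, same shape.
#' @param screen a [screen_params()] object.
#' @return data.frame with columns `azimuth`, `elevation`, `combined`
#'   (degrees; combined is in `[0, 180]`).
#' @export
angular_error <- function(head, est_por, true_por, screen = default_screen()) {
  pos <- as.matrix(head[, c("h_x", "h_y", "h_z"), drop = FALSE])
  est <- as_uv_matrix(est_por); tru <- as_uv_matrix(true_por)
  n <- max(nrow(pos), nrow(est), nrow(tru))
  if (nrow(pos) == 1 && n > 1) pos <- pos[rep(1, n), , drop = FALSE]
  if (nrow(est) == 1 && n > 1) est <- est[rep(1, n), , drop = FALSE]
  if (nrow(tru) == 1 && n > 1) tru <- tru[rep(1, n), , drop = FALSE]
  we <- por_to_world(screen, est); if (is.null(dim(we))) we <- matrix(we, 1)
  wt <- por_to_world(screen, tru); if (is.null(dim(wt))) wt <- matrix(wt, 1)
  de <- we - pos; dt_ <- wt - pos
  if (any(rowSums(de^2) < 1e-12) || any(rowSums(dt_^2) < 1e-12)) {
    stop("head position lies on the screen plane at the POR")
  }
  az <- function(d) rad2deg(atan2(d[, 2], d[, 1]))
  el <- function(d) rad2deg(asin(pmax(-1, pmin(1, d[, 3] /
                                                 sqrt(rowSums(d^2))))))
  data.frame(
    azimuth = normalize_angle(az(de) - az(dt_)),
    elevation = el(de) - el(dt_),
    combined = angle_between(de, dt_)
  )
}

#' Coverage overlap between calibration and validation datasets
#'
#' Discretizes the five-dimensional head-position/pupil-position space
#' (default bins: 10 cm for h_x, h_y, h_z; 1500 image units for p_x, p_y;
#' half-open intervals anchored at the origin) and returns the proportion
#' of bins occupied by the validation data that the calibration data also
#' occupies.
#'
#' @param calib,valid [gaze_session()] objects (or data.frames with the
#'   head and pupil columns).
#' @param bin_head head-position bin width, cm.
#' @param bin_pupil pupil-position bin width, image units.
#' @param denominator `"validation"` (all validation-occupied bins; the
#'   default, guaranteeing a value in `[0, 1]`) or `"exclusive"` (bins
#'   occupied by validation only).
#' @return overlap proportion.
#' @export
overlap_metric <- function(calib, valid, bin_head = 10, bin_pupil = 1500,
                           denominator = c("validation", "exclusive")) {
  denominator <- match.arg(denominator)
  if (nrow(calib) == 0 || nrow(valid) == 0) stop("empty dataset")
  keys <- function(s) {
    paste(floor(s$h_x / bin_head), floor(s$h_y / bin_head),
          floor(s$h_z / bin_head), floor(s$p_x / bin_pupil),
          floor(s$p_y / bin_pupil))
  }
  kc <- unique(keys(calib)); kv <- unique(keys(valid))
  joint <- length(intersect(kc, kv))
  denom <- if (denominator == "validation") length(kv)
           else max(length(setdiff(kv, kc)), 1L)
  joint / denom
}

#' Reject POR predictions by predictive confidence
#'
#' Keeps predictions whose mean predictive standard deviation
#' `(sigma_u + sigma_v) / 2` lies below the threshold. The 75 px default
#' corresponds to the saturation level of the reliability color scale used
#' to flag highly unreliable estimates.
#'
#' @param predictions data.frame with columns `sigma_u`, `sigma_v` (as
#'   returned by `predict()` on a GPR model).
#' @param threshold_px rejection threshold in pixels (> 0).
#' @return list with `kept` (the retained rows) and `rejected_fraction`.
#' @export
reject_by_confidence <- function(predictions, threshold_px = 75) {
  stopifnot(threshold_px > 0,
            all(c("sigma_u", "sigma_v") %in% names(predictions)))
  ms <- (predictions$sigma_u + predictions$sigma_v) / 2
  keep <- ms < threshold_px
  list(kept = predictions[keep, , drop = FALSE],
       rejected_fraction = mean(!keep))
}

#' Pair calibration and validation datasets
#'
#' The three standard pairings: train on the dynamic calibration segment
#' and validate on held-out dynamic or static data, or train on the
#' combined dynamic+static calibration segments and validate on the
#' combined held-out data. Training never uses the static calibration
#' segment alone (static fixations lack the head/eye variability that the
#' regression method needs).
#'
#' @param splits list from [split_session()].
#' @param pairing `"dynamic:dynamic"`, `"dynamic:static"` or
#'   `"combined:combined"`.
#' @return list of class `eval_pairing` with elements `calib`, `valid`,
#'   `label`.
#' @export
eval_pairing <- function(splits, pairing = c("dynamic:dynamic",
                                             "dynamic:static",
                                             "combined:combined")) {
  pairing <- match.arg(pairing)
  cat2 <- function(a, b) {
    out <- rbind(as.data.frame(a), as.data.frame(b))
    out <- out[order(out$t), , drop = FALSE]
    gaze_session(out, attr(a, "user"))
  }
  res <- switch(pairing,
    "dynamic:dynamic" = list(calib = splits$calib_dynamic,
                             valid = splits$valid_dynamic),
    "dynamic:static" = list(calib = splits$calib_dynamic,
                            valid = splits$valid_static),
    "combined:combined" = list(
      calib = cat2(splits$calib_dynamic, splits$calib_static),
      valid = cat2(splits$valid_dynamic, splits$valid_static))
  )
  res$label <- pairing
  class(res) <- "eval_pairing"
  res
}

#' Run one calibration/validation evaluation
#'
#' Calibrates the chosen method on the pairing's calibration dataset,
#' predicts the validation PORs, and summarizes the angular errors. For the
#' GPR method, predictions above the confidence rejection threshold are
#' reported via `rejected_fraction` (the error means include all samples;
#' the per-sample table carries the mean sigma for downstream filtering).
#'
#' @param pairing an [eval_pairing()] (or list with `calib` and `valid`
#'   sessions).
#' @param method `"geometric"` or `"gpr"`.
#' @param screen a [screen_params()] object.
#' @param reject_threshold_px confidence threshold for the rejected
#'   fraction (GPR only).
#' @param ... passed to [gaze_calibrate()].
#' @return object of class `gaze_eval`: a list with `azimuth_mean`,
#'   `elevation_mean`, `combined_mean` (degrees), `errors` (per-sample
#'   table), `rejected_fraction`, `overlap`, `method`, `label` and `fit`.
#' @export
run_evaluation <- function(pairing, method = c("geometric", "gpr"),
                           screen = default_screen(),
                           reject_threshold_px = 75, ...) {
  method <- match.arg(method)
  fit <- gaze_calibrate(pairing$calib, method = method, screen = screen, ...)
  pred <- predict(fit, pairing$valid)
  err <- angular_error(pairing$valid, as.matrix(pred[, c("u", "v")]),
                       session_target_matrix(pairing$valid), screen)
  err$t <- pairing$valid$t
  rej <- NA_real_
  if (method == "gpr" && !is.null(pred$sigma_u)) {
    err$sigma_mean <- (pred$sigma_u + pred$sigma_v) / 2
    rej <- reject_by_confidence(pred, reject_threshold_px)$rejected_fraction
  }
  out <- list(azimuth_mean = mean(abs(err$azimuth), na.rm = TRUE),
              elevation_mean = mean(abs(err$elevation), na.rm = TRUE),
              combined_mean = mean(err$combined, na.rm = TRUE),
              errors = err, rejected_fraction = rej,
              overlap = overlap_metric(pairing$calib, pairing$valid),
              method = method,
              label = if (!is.null(pairing$label)) pairing$label else NA,
              n = nrow(pairing$valid), fit = fit)
  class(out) <- "gaze_eval"
  out
}

#' @export
print.gaze_eval <- function(x, ...) {
  cat(sprintf("Evaluation (%s method%s): %d validation samples\n", x$method,
              if (!is.na(x$label)) paste0(", ", x$label) else "", x$n))
  cat(sprintf("  mean combined error  : %.3f deg\n", x$combined_mean))
  cat(sprintf("  mean |azimuth|       : %.3f deg\n", x$azimuth_mean))
  cat(sprintf("  mean |elevation|     : %.3f deg\n", x$elevation_mean))
  cat(sprintf("  calib/valid overlap  : %.3f\n", x$overlap))
  if (!is.na(x$rejected_fraction)) {
    cat(sprintf("  rejected fraction    : %.3f\n", x$rejected_fraction))
  }
  invisible(x)
}
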