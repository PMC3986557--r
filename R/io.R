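# Session CSV reading/writing, mixed-rate stream alignment, and model
# serialization. CSV: comma-separated, UTF-8, mandatory header, columns
# t_s, h_x, h_y, h_z, h_phi, h_theta, h_psi, p_x, p_y, stim_u, stim_v,
# phase, stim_id. Numeric output is fixed at 12 significant digits so two
# runs of the same config are byte-identical.

FILE_COLS <- c("t_s", "h_x", "h_y", "h_z", "h_phi", "h_theta", "h_psi",
               "p_x", "p_y", "stim_u", "stim_v", "phase", "stim_id")

fmt12 <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Write a session to CSV
#'
#' @param session a [gaze_session()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  df <- as.data.frame(session)
  out <- data.frame(t_s = fmt12(df$t))
  for (cc in c("h_x", "h_y", "h_z", "h_phi", "h_theta", "h_psi",
               "p_x", "p_y", "stim_u", "stim_v")) {
    out[[cc]] <- fmt12(df[[cc]])
  }
  out$phase <- df$phase
  out$stim_id <- ifelse(is.na(df$stim_id), "", as.character(df$stim_id))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a session from CSV
#'
#' Validates the schema and time ordering; malformed rows are reported
#' with their line numbers.
#'
#' @param path CSV file path (schema of [write_session()]).
#' @param user optional user id to attach.
#' @return a [gaze_session()].
#' @export
read_session <- function(path, user = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA")),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(df) == 0) stop("empty session file: ", path)
  missing_cols <- setdiff(FILE_COLS, names(df))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(FILE_COLS, c("phase", "stim_id"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "")
    if (length(bad)) {
      stop(sprintf("non-numeric value in column %s at line %d of %s",
                   cc, bad[1] + 1, path))
    }
    df[[cc]] <- v
  }
  bad <- which(diff(df$t_s) < 0)
  if (length(bad)) {
    stop(sprintf("time column not monotone at line %d of %s", bad[1] + 2,
                 path))
  }
  df$phase[is.na(df$phase)] <- "none"
  names(df)[names(df) == "t_s"] <- "t"
  df$stim_id <- suppressWarnings(as.integer(df$stim_id))
  gaze_session(df[, SESSION_COLS], user = user)
}

#' Align head and pupil streams recorded at different rates
#'
#' Resamples onto the faster stream's timestamps within the overlapping
#' time window: positions and pupil coordinates by linear interpolation,
#' orientations by quaternion spherical interpolation with the
#' shortest-arc convention.
#'
#' @param head data.frame with columns `t, h_x, h_y, h_z, h_phi, h_theta,
#'   h_psi`.
#' @param pupil data.frame with columns `t, p_x, p_y`.
#' @return data.frame of aligned samples with all input columns.
#' @export
align_streams <- function(head, pupil) {
  lo <- max(min(head$t), min(pupil$t))
  hi <- min(max(head$t), max(pupil$t))
  if (lo > hi) stop("head and pupil streams do not overlap in time")
  rate <- function(t) (length(t) - 1) / max(diff(range(t)), 1e-12)
  t_out <- if (rate(head$t) >= rate(pupil$t)) head$t else pupil$t
  t_out <- t_out[t_out >= lo & t_out <= hi]
  lin <- function(t, y) stats::approx(t, y, xout = t_out, ties = "ordered")$y
  out <- data.frame(t = t_out,
                    h_x = lin(head$t, head$h_x),
                    h_y = lin(head$t, head$h_y),
                    h_z = lin(head$t, head$h_z))
  # orientation: slerp between the bracketing head samples
  q <- rot_to_quat(rot_batch(head$h_phi, head$h_theta, head$h_psi))
  i0 <- findInterval(t_out, head$t, rightmost.closed = TRUE)
  i0 <- pmax(1, pmin(i0, nrow(q) - 1))
  i1 <- i0 + 1
  u <- (t_out - head$t[i0]) / pmax(head$t[i1] - head$t[i0], 1e-12)
  u <- pmax(0, pmin(1, u))
  qi <- quat_slerp(q[i0, , drop = FALSE], q[i1, , drop = FALSE], u)
  ang <- t(apply(quat_to_rot(qi), 1, function(r) {
    euler_from_rotation(matrix(r, 3, 3))
  }))
  out$h_phi <- ang[, 1]; out$h_theta <- ang[, 2]; out$h_psi <- ang[, 3]
  out$p_x <- lin(pupil$t, pupil$p_x)
  out$p_y <- lin(pupil$t, pupil$p_y)
  out
}

# ---- model serialization --------------------------------------------------

GAZECAL_MODEL_VERSION <- "1.0"

screen_to_list <- function(s) {
  list(center = s$center, normal = s$normal, up = s$up,
       width_cm = s$width_cm, height_cm = s$height_cm,
       width_px = s$width_px, height_px = s$height_px)
}

screen_from_list <- function(x) {
  screen_params(center = x$center, normal = x$normal, up = x$up,
                width_cm = x$width_cm, height_cm = x$height_cm,
                width_px = x$width_px, height_px = x$height_px)
}

#' Serialize a fitted gaze model to JSON
#'
#' The document is self-describing: it embeds a format version, the method
#' and (for GPR) the kernel-form flag plus the full training arrays, so
#' [read_gaze_model()] reconstructs a model whose predictions match the
#' original to numerical text precision (12 significant digits).
#'
#' @param object a fitted `gaze_model` (or bare [geometric_model()]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_gaze_model <- function(object, path) {
  if (inherits(object, "geometric_model")) {
    object <- list(model = object, method = "geometric", screen = object$screen)
    class(object) <- c("gaze_geometric", "gaze_model")
  }
  doc <- list(format = "gazecal-model", version = GAZECAL_MODEL_VERSION,
              method = object$method)
  if (object$method == "geometric") {
    doc$head_eye <- unclass(object$model$head_eye)
    doc$eye <- unclass(object$model$eye)
    doc$screen <- screen_to_list(object$model$screen)
  } else {
    doc$kernel <- object$gps$kernel
    doc$screen <- screen_to_list(object$screen)
    for (ax in c("u", "v")) {
      gp <- object$gps[[ax]]
      doc[[paste0("gp_", ax)]] <- list(
        sigma_s = gp$theta$sigma_s, sigma_n = gp$theta$sigma_n,
        l = gp$theta$l, X = gp$X, y = gp$y)
    }
  }
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = FALSE), path, useBytes = TRUE)
  invisible(path)
}

#' Load a fitted gaze model from JSON
#'
#' @param path JSON path written by [write_gaze_model()].
#' @return a `gaze_geometric` or `gaze_gpr` object (without the original
#'   calibration session; `predict()` requires `newdata`).
#' @export
read_gaze_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "gazecal-model")) {
    stop("not a gazecal model file: ", path)
  }
  screen <- screen_from_list(doc$screen)
  if (doc$method == "geometric") {
    he <- do.call(head_eye_params, doc$head_eye)
    em <- do.call(eye_model_params, doc$eye)
    out <- list(model = geometric_model(he, em, screen), screen = screen,
                method = "geometric", n = NA_integer_, cost = NA_real_,
                session = NULL)
    class(out) <- c("gaze_geometric", "gaze_model")
  } else {
    gps <- list(kernel = doc$kernel)
    for (ax in c("u", "v")) {
      g <- doc[[paste0("gp_", ax)]]
      gps[[ax]] <- gp_fit(g$X, g$y,
                          gp_hyper(g$sigma_s, g$sigma_n, g$l), doc$kernel)
    }
    out <- list(gps = gps, screen = screen, method = "gpr",
                n = nrow(gps$u$X), session = NULL)
    class(out) <- c("gaze_gpr", "gaze_model")
  }
  out
}
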