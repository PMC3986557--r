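# The session container: a time-ordered data.frame of aligned motion- and
# eye-tracker samples paired with the on-screen stimulus position.

SESSION_COLS <- c("t", "h_x", "h_y", "h_z", "h_phi", "h_theta", "h_psi",
                  "p_x", "p_y", "stim_u", "stim_v", "phase", "stim_id")

#' Construct a gaze session dataset
#'
#' A `gaze_session` is a data.frame with one row per aligned sample:
#' time `t` (s), head pose `h_x, h_y, h_z` (cm) and `h_phi, h_theta, h_psi`
#' (degrees), pupil centroid `p_x, p_y` (eye-camera image units), stimulus
#' position `stim_u, stim_v` (px; NA when no stimulus was shown), a `phase`
#' label (`"dynamic"`, `"static"` or `"none"`) and a `stim_id` presentation
#' index (NA outside static presentations).
#'
#' @param df data.frame holding the columns above.
#' @param user optional user identifier, kept as an attribute.
#' @return the validated data.frame with class `gaze_session`.
#' @export
gaze_session <- function(df, user = NULL) {
  missing_cols <- setdiff(SESSION_COLS, names(df))
  if (length(missing_cols)) {
    stop("missing session columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty session")
  bad <- which(diff(df$t) < 0)
  if (length(bad)) {
    stop(sprintf("timestamps must be non-decreasing (first violation at row %d)",
                 bad[1] + 1))
  }
  ang <- c("h_phi", "h_theta", "h_psi")
  df[ang] <- lapply(df[ang], normalize_angle)
  df$phase <- as.character(df$phase)
  stopifnot(all(df$phase %in% c("dynamic", "static", "none")))
  out <- df[SESSION_COLS]
  class(out) <- c("gaze_session", "data.frame")
  attr(out, "user") <- user
  out
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf("Gaze session: %d samples, %.1f s", nrow(x), diff(range(x$t))))
  ph <- table(x$phase)
  cat(" (", paste(sprintf("%s: %d", names(ph), ph), collapse = ", "), ")\n",
      sep = "")
  if (!is.null(attr(x, "user"))) cat("  user:", attr(x, "user"), "\n")
  NextMethod()
}

# Matrix views used by the numerical code paths.
session_head_matrix <- function(s)
  as.matrix(s[, c("h_x", "h_y", "h_z", "h_phi", "h_theta", "h_psi")])
session_pupil_matrix <- function(s) as.matrix(s[, c("p_x", "p_y")])
session_target_matrix <- function(s) as.matrix(s[, c("stim_u", "stim_v")])
session_input_matrix <- function(s)
  as.matrix(s[, c("h_x", "h_y", "h_z", "h_phi", "h_theta", "h_psi",
                  "p_x", "p_y")])

# Rows usable for calibration: stimulus shown and all inputs finite.
session_calib_rows <- function(s) {
  ok <- stats::complete.cases(s[, c("h_x", "h_y", "h_z", "h_phi", "h_theta",
                                    "h_psi", "p_x", "p_y",
                                    "stim_u", "stim_v")])
  which(ok)
}

# Uniform temporal subsampling to at most n rows (the reduced subset D').
subsample_idx <- function(n_total, n_keep) {
  if (n_total <= n_keep) return(seq_len(n_total))
  unique(round(seq(1, n_total, length.out = n_keep)))
}
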