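#' Interpolate low-likelihood pose frames
#'
#' Frames whose tracking likelihood falls below `threshold` are replaced by
#' linear interpolation of the neck coordinates between the nearest valid
#' neighbors; leading/trailing gaps are held at the nearest valid value.
#'
#' @param pose A `pose_track` data.frame (`frame`, `time_s`, `neck_x`,
#'   `neck_y`, `likelihood`).
#' @param threshold Likelihood threshold (default 0.9).
#' @return The pose track with interpolated coordinates; interpolated frames
#'   keep their original likelihood.
#' @export
interpolate_low_likelihood <- function(pose, threshold = 0.9) {
  ok <- pose$likelihood >= threshold
  if (sum(ok) < 2L) stopf("fewer than 2 frames above the likelihood threshold")
  if (all(ok)) return(pose)
  fill <- function(v) {
    stats::approx(x = which(ok), y = v[ok], xout = seq_along(v),
                  method = "linear", rule = 2)$y
  }
  pose$neck_x <- fill(pose$neck_x)
  pose$neck_y <- fill(pose$neck_y)
  pose
}

#' Allocentric neck movement speed from a pose track
#'
#' `speed(i) = ||r(i) - r(i-1)|| * frame_rate`, with the first frame copying
#' the second. Populates the log2 speed (with floor `epsilon`) and the
#' stationary mask (speed below `stationary_threshold`, default 3 cm/s).
#'
#' @param pose A `pose_track` with calibrated coordinates in cm.
#' @param frame_rate Video frame rate in Hz.
#' @param epsilon Log-floor in cm/s (default 0.25).
#' @param stationary_threshold Stationary cutoff in cm/s (default 3).
#' @param median_filter If `TRUE`, applies a 3-frame running median to the
#'   coordinates before differencing (off by default).
#' @return A data.frame of class `speed_series` with columns `frame`,
#'   `time_s`, `speed`, `logspeed`, `stationary`.
#' @export
neck_speed <- function(pose, frame_rate = 30, epsilon = 0.25,
                       stationary_threshold = 3, median_filter = FALSE) {
  x <- pose$neck_x
  y <- pose$neck_y
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stopf("non-finite coordinates in pose track")
  }
  if (median_filter && length(x) >= 3L) {
    x <- stats::runmed(x, 3, endrule = "keep")
    y <- stats::runmed(y, 3, endrule = "keep")
  }
  sp <- c(NA, sqrt(diff(x)^2 + diff(y)^2) * frame_rate)
  sp[1] <- sp[2]
  out <- data.frame(frame = pose$frame, time_s = pose$time_s, speed = sp,
                    logspeed = log2_with_floor(sp, epsilon),
                    stationary = sp < stationary_threshold,
                    row.names = NULL)
  class(out) <- c("speed_series", "data.frame")
  attr(out, "epsilon") <- epsilon
  attr(out, "stationary_threshold") <- stationary_threshold
  out
}

#' Floored base-2 logarithm of speed
#'
#' `log2(max(speed, epsilon))`: strictly monotone above the floor, constant
#' below it.
#'
#' @param speed Speed values in cm/s.
#' @param epsilon Positive floor in cm/s.
#' @return `log2(pmax(speed, epsilon))`.
#' @export
log2_with_floor <- function(speed, epsilon = 0.25) {
  if (epsilon <= 0) stopf("epsilon must be positive")
  log2(pmax(speed, epsilon))
}

#' Select stationary-dominated sessions
#'
#' Keeps the sessions whose fraction of stationary frames (neck speed below
#' the stationary threshold) strictly exceeds `fraction_threshold` of the
#' recording (default two thirds).
#'
#' @param sessions A list of session objects, each containing a logical
#'   `stationary` column (e.g. aligned-session data.frames or
#'   `speed_series`), or a single data.frame with a `session_id` column.
#' @param fraction_threshold Strict lower bound on the stationary fraction.
#' @return The subset, same container type as the input.
#' @export
stationary_session_filter <- function(sessions, fraction_threshold = 2 / 3) {
  if (is.data.frame(sessions)) {
    frac <- tapply(sessions$stationary, sessions$session_id, mean)
    keep_ids <- names(frac)[frac > fraction_threshold]
    return(sessions[sessions$session_id %in% keep_ids, , drop = FALSE])
  }
  keep <- vapply(sessions, function(s) {
    st <- if (is.data.frame(s)) s$stationary else s
    mean(st) > fraction_threshold
  }, logical(1))
  sessions[keep]
}

#' Rescale pose coordinates from the observed wall extent
#'
#' Linear pixel-to-cm calibration: the observed coordinate extent (robust
#' range) is mapped onto the configured arena size.
#'
#' @param pose A `pose_track`.
#' @param arena_size Arena width and height in cm.
#' @param probs Quantiles defining the observed wall extent (default
#'   `c(0.001, 0.999)` to resist tracking outliers).
#' @return The calibrated pose track.
#' @export
calibrate_arena <- function(pose, arena_size = c(40, 40),
                            probs = c(0.001, 0.999)) {
  qx <- stats::quantile(pose$neck_x, probs, names = FALSE)
  qy <- stats::quantile(pose$neck_y, probs, names = FALSE)
  if (diff(qx) <= 0 || diff(qy) <= 0) stopf("degenerate coordinate extent")
  pose$neck_x <- (pose$neck_x - qx[1]) / diff(qx) * arena_size[1]
  pose$neck_y <- (pose$neck_y - qy[1]) / diff(qy) * arena_size[2]
  pose
}
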