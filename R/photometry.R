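#' Resample photometry channels to the video frame clock
#'
#' Each video frame receives the mean of all photometry samples whose
#' timestamps fall in `[t_i, t_{i+1})`, where `t_i` are the TTL frame times;
#' the last frame's window extends by the median inter-frame interval.
#' Averaging within the frame window acts as an anti-aliasing filter and is
#' exact with respect to the TTL clock.
#'
#' @param raw A [raw_photometry()].
#' @return A data.frame with columns `frame` (0-based), `time_s` (frame
#'   times), `s` (frame-mean 470 channel) and `c` (frame-mean 405 channel).
#' @export
resample_to_frames <- function(raw) {
  ft <- raw$ttl_frame_times
  if (min(ft) < min(raw$time_s) - 1e-9 || max(ft) > max(raw$time_s) + 1e-9) {
    stopf("TTL frame times outside the photometry time range")
  }
  edges <- c(ft, ft[length(ft)] + stats::median(diff(ft)))
  idx <- findInterval(raw$time_s, edges)
  keep <- idx >= 1L & idx <= length(ft)
  counts <- tabulate(idx[keep], nbins = length(ft))
  if (any(counts == 0L)) {
    stopf("no photometry samples in frame window(s): %s",
          paste(utils::head(which(counts == 0L) - 1L, 10), collapse = ", "))
  }
  data.frame(
    frame = seq_along(ft) - 1L,
    time_s = ft,
    s = rowsum(raw$f470[keep], idx[keep])[, 1] / counts,
    c = rowsum(raw$f405[keep], idx[keep])[, 1] / counts,
    row.names = NULL
  )
}

#' Adjust the isosbestic control for bleaching mismatch
#'
#' Fits a 2nd-degree polynomial to the difference `d = s - c_raw` against
#' time and adds the fitted curve to the raw control, yielding an adjusted
#' control whose slow trend matches the signal channel. The regressor is
#' centered and scaled for conditioning; the returned attribute
#' `poly_coeffs` holds the three coefficients on that internal scale.
#'
#' @param s Signal (470) frame series.
#' @param c_raw Raw control (405) frame series.
#' @param t Frame times in seconds.
#' @return The adjusted control series, with attribute `poly_coeffs`.
#' @export
adjust_control <- function(s, c_raw, t) {
  n <- length(s)
  if (length(c_raw) != n || length(t) != n) stopf("inputs must have equal length")
  if (n < 3L) stopf("need at least 3 frames to fit a 2nd-degree polynomial")
  d <- s - c_raw
  tc <- (t - mean(t)) / stats::sd(t)
  X <- cbind(1, tc, tc^2)
  beta <- qr.coef(qr(X), d)
  fitted <- as.numeric(X %*% beta)
  out <- c_raw + fitted
  attr(out, "poly_coeffs") <- as.numeric(beta)
  out
}

#' Least-squares scale and offset of the control onto the signal
#'
#' Closed-form minimizer of `sum((s - (c * alpha + beta))^2)`:
#' `alpha = cov(c, s) / var(c)`, `beta = mean(s) - alpha * mean(c)`.
#'
#' @param s Signal frame series.
#' @param c_adj Adjusted control frame series.
#' @return Named numeric `c(alpha = , beta = )`.
#' @export
fit_scale_offset <- function(s, c_adj) {
  vc <- stats::var(c_adj)
  if (!is.finite(vc) || vc <= 0) {
    stopf("degenerate control: var(c_adj) = 0, cannot fit scale/offset")
  }
  alpha <- stats::cov(c_adj, s) / vc
  beta <- mean(s) - alpha * mean(c_adj)
  c(alpha = alpha, beta = beta)
}

#' Compute dF/F from signal and fitted baseline
#'
#' `dff(t) = (s(t) - (c_adj(t) alpha + beta)) / (c_adj(t) alpha + beta)`.
#' The denominator must stay away from zero: frames where
#' `|c alpha + beta| <= 1e-6 * median|c alpha + beta|` raise an error.
#'
#' @param s Signal frame series.
#' @param c_adj Adjusted control frame series.
#' @param alpha,beta Scale and offset from [fit_scale_offset()].
#' @return The dF/F series.
#' @export
compute_dff <- function(s, c_adj, alpha, beta) {
  denom <- c_adj * alpha + beta
  tol <- 1e-6 * stats::median(abs(denom))
  bad <- which(abs(denom) <= tol)
  if (length(bad)) {
    stopf("baseline within tolerance of zero at frame(s): %s",
          paste(utils::head(bad - 1L, 10), collapse = ", "))
  }
  (s - denom) / denom
}

#' Z-score a session's dF/F
#'
#' Standardizes within a session (sample SD, n-1 denominator) so that signal
#' strength can be compared across sessions.
#'
#' @param dff dF/F series of one session.
#' @return The z-scored series.
#' @export
zscore_session <- function(dff) {
  s <- stats::sd(dff)
  if (!is.finite(s) || s == 0) stopf("constant input: cannot z-score")
  (dff - mean(dff)) / s
}

#' Process a raw photometry session into frame-aligned z-scored dF/F
#'
#' Runs the full correction chain: frame resampling, polynomial control
#' adjustment, least-squares scale/offset, dF/F, and per-session z-scoring.
#'
#' @param raw A [raw_photometry()].
#' @return A data.frame of class `dff_trace` with columns `frame`, `time_s`,
#'   `dff`, `zdff`; attributes `alpha`, `beta`, `poly_coeffs`.
#' @export
process_photometry <- function(raw) {
  fr <- resample_to_frames(raw)
  c_adj <- adjust_control(fr$s, fr$c, fr$time_s)
  ab <- fit_scale_offset(fr$s, c_adj)
  dff <- compute_dff(fr$s, c_adj, ab[["alpha"]], ab[["beta"]])
  out <- data.frame(frame = fr$frame, time_s = fr$time_s, dff = dff,
                    zdff = zscore_session(dff), row.names = NULL)
  class(out) <- c("dff_trace", "data.frame")
  attr(out, "alpha") <- ab[["alpha"]]
  attr(out, "beta") <- ab[["beta"]]
  attr(out, "poly_coeffs") <- attr(c_adj, "poly_coeffs")
  out
}
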