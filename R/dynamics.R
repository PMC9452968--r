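#' Centered moving average with shrinking edges
#'
#' Boxcar of width `round(window_s * frame_rate)` forced odd, centered on
#' each frame; near the edges the window truncates to the available samples
#' (shrinking mean), so the output has no NA padding.
#'
#' @param z Numeric series.
#' @param window_s Window length in seconds.
#' @param frame_rate Sampling rate in Hz.
#' @return The smoothed series, same length as `z`.
#' @export
moving_average <- function(z, window_s, frame_rate = 30) {
  n <- length(z)
  w <- max(1L, round(window_s * frame_rate))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > n) stopf("window (%d frames) longer than the series (%d frames)", w, n)
  if (w == 1L) return(z)
  h <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(z))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Scan moving-average windows for the speed correlation optimum
#'
#' For each window `w` in `grid`, computes the Pearson correlation between
#' the `w`-second moving average of the activity trace and the (unsmoothed)
#' log2 speed, and reports the window maximizing the correlation — the
#' optimal integration time window of the activity signal. Ties resolve to
#' the smallest window.
#'
#' @param z Activity series (z-scored dF/F) at frame rate.
#' @param logspeed Log2 speed series, frame-aligned with `z`.
#' @param grid Sorted vector of window lengths in seconds (default 1 frame to
#'   10 s in 1-frame steps).
#' @param frame_rate Sampling rate in Hz.
#' @param session_id Optional identifier stored in the result.
#' @return An object of class `window_scan`: list with `window_s`, `r`,
#'   `optimal_window`, `r_max`, `session_id`.
#' @export
window_scan <- function(z, logspeed, grid = NULL, frame_rate = 30,
                        session_id = NA_character_) {
  if (length(z) != length(logspeed)) stopf("series must be frame-aligned")
  if (stats::sd(z) == 0 || stats::sd(logspeed) == 0) {
    stopf("zero-variance series: correlation undefined")
  }
  if (is.null(grid)) grid <- seq(1 / frame_rate, 10, by = 1 / frame_rate)
  if (!length(grid) || is.unsorted(grid)) stopf("grid must be non-empty and sorted")
  r <- vapply(grid, function(w) {
    zs <- moving_average(z, w, frame_rate)
    if (stats::sd(zs) == 0) return(NA_real_)
    stats::cor(zs, logspeed)
  }, 0)
  structure(
    list(window_s = grid, r = r, optimal_window = grid[which.max(r)],
         r_max = max(r, na.rm = TRUE), session_id = session_id),
    class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("<window_scan> %d windows [%.3g, %.3g] s; optimum %.3g s (r = %.3f)\n",
              length(x$window_s), min(x$window_s), max(x$window_s),
              x$optimal_window, x$r_max))
  invisible(x)
}

#' Summarize window scans across sessions
#'
#' Across-session mean and SEM of the correlation-vs-window curve, and a
#' histogram of the per-session optimal windows.
#'
#' @param scans List of [window_scan()] results on a common grid.
#' @param hist_binwidth Histogram bin width in seconds (default 0.2 s).
#' @return A list: `window_s`, `mean_r`, `sem_r`, `optima`,
#'   `hist` (data.frame `bin_left`, `count`), `peak_window` (grid value
#'   maximizing the mean curve).
#' @export
cohort_window_summary <- function(scans, hist_binwidth = 0.2) {
  if (length(scans) < 2L) stopf("need at least 2 scans")
  g <- scans[[1]]$window_s
  same <- vapply(scans, function(s) {
    length(s$window_s) == length(g) && max(abs(s$window_s - g)) < 1e-9
  }, logical(1))
  if (!all(same)) stopf("window scans are on mismatched grids")
  mat <- vapply(scans, function(s) s$r, numeric(length(g)))
  mean_r <- rowMeans(mat)
  sem_r <- apply(mat, 1, stats::sd) / sqrt(ncol(mat))
  optima <- vapply(scans, function(s) s$optimal_window, 0)
  breaks <- seq(0, max(optima) + hist_binwidth, by = hist_binwidth)
  counts <- tabulate(findInterval(optima, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1L)
  list(window_s = g, mean_r = mean_r, sem_r = sem_r, optima = optima,
       hist = data.frame(bin_left = breaks[-length(breaks)], count = counts),
       peak_window = g[which.max(mean_r)])
}

#' Compare window-scan results between lighting conditions
#'
#' Two-sample pooled-variance t-test on the correlation at a reference
#' window (1.3 s, the cohort optimum), and a two-sample Kolmogorov-Smirnov
#' test on the distributions of per-session optimal windows.
#'
#' @param scans_light,scans_dark Lists of [window_scan()] results.
#' @param reference_window Window (s) at which correlations are compared.
#' @return A list `t`, `df`, `p_t`, `ks_stat`, `p_ks`, `r_light`, `r_dark`.
#' @export
compare_light_dark <- function(scans_light, scans_dark, reference_window = 1.3) {
  if (length(scans_light) < 2L || length(scans_dark) < 2L) {
    stopf("need at least 2 sessions per group")
  }
  r_at <- function(s) s$r[which.min(abs(s$window_s - reference_window))]
  rl <- vapply(scans_light, r_at, 0)
  rd <- vapply(scans_dark, r_at, 0)
  tt <- stats::t.test(rl, rd, var.equal = TRUE)
  ol <- vapply(scans_light, function(s) s$optimal_window, 0)
  od <- vapply(scans_dark, function(s) s$optimal_window, 0)
  ks <- suppressWarnings(stats::ks.test(ol, od))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_t = tt$p.value, ks_stat = unname(ks$statistic), p_ks = ks$p.value,
       r_light = rl, r_dark = rd)
}
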