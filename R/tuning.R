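#' Subsample an aligned session at fixed intervals
#'
#' Takes the single frame nearest each multiple of `interval` from session
#' start (scatter-plot decimation; not a windowed mean).
#'
#' @param session An `aligned_session` data.frame (one session).
#' @param interval Sampling interval in seconds (default 1 s).
#' @return The subsampled rows of `session`.
#' @export
sample_interval <- function(session, interval = 1) {
  t <- session$time_s - session$time_s[1]
  if (interval < min(diff(t))) stopf("interval shorter than one frame")
  targets <- seq(0, max(t), by = interval)
  idx <- vapply(targets, function(tt) which.min(abs(t - tt)), 0L)
  session[idx, , drop = FALSE]
}

#' Bin activity against speed (or log speed)
#'
#' Half-open bins `[k w, (k+1) w)`; a value lying exactly on an edge joins
#' the upper bin. Bins with fewer than `min_count` points are reported empty
#' (`NA` mean and SEM).
#'
#' @param x Binning variable (speed in cm/s or log2 speed).
#' @param z Activity values (z-scored dF/F).
#' @param bin_width Bin width (1 cm/s for speed, 0.1 for log2 speed in the
#'   study's figures).
#' @param min_count Minimum points per reported bin (default 5).
#' @return A data.frame of class `tuning_curve`: `bin_left`, `bin_center`,
#'   `bin_mean`, `bin_sem`, `bin_n`.
#' @export
bin_tuning_curve <- function(x, z, bin_width, min_count = 5) {
  if (bin_width <= 0) stopf("bin_width must be positive")
  keep <- is.finite(x) & is.finite(z)
  x <- x[keep]; z <- z[keep]
  if (!length(x)) stopf("no finite observations to bin")
  k <- floor(x / bin_width + 1e-12)
  kk <- seq(min(k), max(k))
  idx <- match(k, kk)
  n <- tabulate(idx, nbins = length(kk))
  sums <- numeric(length(kk))
  sq <- numeric(length(kk))
  rs <- rowsum(cbind(z, z^2), idx)
  present <- as.integer(rownames(rs))
  sums[present] <- rs[, 1]
  sq[present] <- rs[, 2]
  mean_z <- ifelse(n > 0, sums / pmax(n, 1), NA_real_)
  var_z <- ifelse(n > 1, (sq - n * mean_z^2) / (n - 1), NA_real_)
  var_z <- pmax(var_z, 0)
  sem <- ifelse(n > 1, sqrt(var_z / n), NA_real_)
  empty <- n < min_count
  out <- data.frame(
    bin_left = kk * bin_width,
    bin_center = (kk + 0.5) * bin_width,
    bin_mean = ifelse(empty, NA_real_, mean_z),
    bin_sem = ifelse(empty, NA_real_, sem),
    bin_n = n,
    row.names = NULL
  )
  class(out) <- c("tuning_curve", "data.frame")
  attr(out, "bin_width") <- bin_width
  attr(out, "min_count") <- min_count
  out
}

#' Ordinary least squares of activity on log speed
#'
#' Returns the slope, intercept and Pearson correlation of the log-linear
#' speed tuning relation. A zero-variance response yields slope 0 and, by
#' convention, `r = 0` with a warning.
#'
#' @param x Log2 speed values.
#' @param z Activity values.
#' @return A list `slope`, `intercept`, `r`, `n`.
#' @export
fit_linear_log <- function(x, z) {
  keep <- is.finite(x) & is.finite(z)
  x <- x[keep]; z <- z[keep]
  if (length(x) < 3L) stopf("need at least 3 points")
  vx <- stats::var(x)
  if (vx <= 0) stopf("zero variance in x: cannot fit a line")
  slope <- stats::cov(x, z) / vx
  intercept <- mean(z) - slope * mean(x)
  vz <- stats::var(z)
  if (vz <= 0) {
    warnf("zero-variance response: Pearson r reported as 0 by convention")
    r <- 0
  } else {
    r <- stats::cor(x, z)
  }
  list(slope = slope, intercept = intercept, r = r, n = length(x))
}

#' Saturating-exponential fit of the speed tuning curve
#'
#' Nonlinear least squares of `z = y_inf - A exp(-speed / tau)` with
#' multi-start optimization over `tau` (defaults 1, 5 and 20 cm/s), keeping
#' the best-SSE converged fit.
#'
#' @param speed Speed values in cm/s.
#' @param z Activity values.
#' @param tau_starts Initial `tau` values for the multi-start.
#' @return A list `y_inf`, `amplitude`, `tau`, `sse`, `r` (correlation of
#'   fitted values with `z`), `converged`.
#' @export
fit_saturating_exponential <- function(speed, z, tau_starts = c(1, 5, 20)) {
  keep <- is.finite(speed) & is.finite(z)
  speed <- speed[keep]; z <- z[keep]
  if (length(speed) < 10L) stopf("need at least 10 points")
  if (diff(range(speed)) <= 0) stopf("speed range must be positive")
  hi <- mean(z[speed >= stats::quantile(speed, 0.8)])
  lo <- mean(z[speed <= stats::quantile(speed, 0.2)])
  if (!is.finite(hi)) hi <- max(z)
  if (!is.finite(lo)) lo <- min(z)
  a0 <- if (abs(hi - lo) > 1e-12) hi - lo else max(stats::sd(z), 1e-3)
  best <- NULL
  for (tau0 in tau_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(z ~ yinf - A * exp(-speed / tau),
                        start = list(yinf = hi, A = a0, tau = tau0),
                        lower = c(-Inf, -Inf, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- stats::coef(fit)
      best <- list(y_inf = unname(cf["yinf"]), amplitude = unname(cf["A"]),
                   tau = unname(cf["tau"]), sse = sse,
                   r = if (stats::sd(stats::fitted(fit)) > 0 && stats::sd(z) > 0)
                     stats::cor(stats::fitted(fit), z) else 0,
                   converged = TRUE)
    }
  }
  if (is.null(best)) stopf("saturating-exponential fit failed from all starts")
  best
}

#' Average tuning curves across sessions
#'
#' Per-bin across-session mean and SEM of the session-level bin means,
#' optionally split by a condition (e.g. lighting). Bins are aligned on
#' `bin_left`; sessions whose bin is empty do not contribute to that bin.
#'
#' @param curves List of `tuning_curve` objects (same bin width).
#' @param conditions Optional condition label per curve; `NULL` pools all.
#' @return A data.frame `condition`, `bin_left`, `bin_mean`, `bin_sem`,
#'   `bin_n` (number of contributing sessions).
#' @export
aggregate_curves <- function(curves, conditions = NULL) {
  if (!length(curves)) stopf("no curves supplied")
  bw <- vapply(curves, function(cu) attr(cu, "bin_width"), 0)
  if (max(bw) - min(bw) > 1e-12) stopf("curves have mismatched bin widths")
  if (is.null(conditions)) conditions <- rep("all", length(curves))
  out <- list()
  for (cond in unique(conditions)) {
    sub <- curves[conditions == cond]
    lefts <- sort(unique(unlist(lapply(sub, function(cu) cu$bin_left))))
    mat <- vapply(sub, function(cu) {
      cu$bin_mean[match(lefts, cu$bin_left)]
    }, numeric(length(lefts)))
    mat <- matrix(mat, nrow = length(lefts))
    n <- rowSums(!is.na(mat))
    m <- rowMeans(mat, na.rm = TRUE)
    sdv <- apply(mat, 1, stats::sd, na.rm = TRUE)
    sem <- ifelse(n > 1, sdv / sqrt(n), ifelse(n == 1, 0, NA_real_))
    out[[cond]] <- data.frame(condition = cond, bin_left = lefts,
                              bin_mean = ifelse(n > 0, m, NA_real_),
                              bin_sem = sem, bin_n = n, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
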