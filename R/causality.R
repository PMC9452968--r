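#' Extract the Granger-analysis segment of a session
#'
#' Takes the first `minutes` of the frame-aligned (log2 speed, z-dF/F) pair
#' and removes each channel's mean (detrending), matching the convention of
#' analyzing the first 5 minutes of every session so that sessions are
#' comparable as trials. Shorter sessions are used whole with a warning.
#'
#' @param session An `aligned_session` data.frame (one session).
#' @param minutes Segment length in minutes (default 5).
#' @param frame_rate Frame rate in Hz.
#' @return An n x 2 matrix with columns `logspeed`, `zdff`, each mean zero.
#' @export
truncate_first_minutes <- function(session, minutes = 5, frame_rate = 30) {
  n_want <- round(minutes * 60 * frame_rate)
  n <- nrow(session)
  if (n < n_want) {
    warnf("session %s shorter than %g min; using all %d frames",
          session$session_id[1] %||% "?", minutes, n)
    n_want <- n
  }
  m <- cbind(logspeed = session$logspeed[seq_len(n_want)],
             zdff = session$zdff[seq_len(n_want)])
  sweep(m, 2, colMeans(m))
}

# Stacked lagged design over trials: rows are observations t = p+1..T_k of
# each trial (no lag leakage across trials); columns are an intercept, then
# lags 1..p of channel 1, then lags 1..p of channel 2.
var_design <- function(trials, p, skip = p) {
  xs <- list(); ys <- list()
  for (tr in trials) {
    T_k <- nrow(tr)
    if (T_k <= skip + 1L) stopf("trial too short for order %d", p)
    rows <- (skip + 1L):T_k
    X <- matrix(1, length(rows), 1L + 2L * p)
    for (l in seq_len(p)) {
      X[, 1L + l] <- tr[rows - l, 1L]
      X[, 1L + p + l] <- tr[rows - l, 2L]
    }
    xs[[length(xs) + 1L]] <- X
    ys[[length(ys) + 1L]] <- tr[rows, , drop = FALSE]
  }
  list(X = do.call(rbind, xs), Y = do.call(rbind, ys))
}

#' Fit a bivariate VAR by multi-trial ordinary least squares
#'
#' Stacks the lagged design across trials (excluding each trial's first `p`
#' frames, so no lags leak across trial boundaries) and solves both channel
#' equations by OLS. The residual covariance uses the per-equation
#' denominator `n_eff - 2p - 1`.
#'
#' @param trials List of n x 2 matrices (columns: channel 1, channel 2),
#'   each detrended (e.g. from [truncate_first_minutes()]).
#' @param p VAR order (>= 1).
#' @return An object of class `var_fit`: `order`, `A` (list of p 2x2 lag
#'   matrices), `coef` (full coefficient matrix incl. intercepts), `Sigma`,
#'   `rss` (per equation), `n_eff`, `se` (coefficient standard errors).
#' @export
fit_var_multitrial <- function(trials, p) {
  if (p < 1L) stopf("order p must be >= 1")
  if (!length(trials)) stopf("no trials supplied")
  short <- vapply(trials, nrow, 0L) <= p + 10L
  if (any(short)) stopf("every trial must be longer than p + 10 frames")
  d <- var_design(trials, p)
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X)) stopf("singular lagged design (rank %d < %d)",
                                  qrX$rank, ncol(d$X))
  B <- qr.coef(qrX, d$Y)
  res <- d$Y - d$X %*% B
  n_eff <- nrow(d$X)
  df <- n_eff - (2L * p + 1L)
  Sigma <- crossprod(res) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(outer(diag(XtXinv), diag(Sigma)))
  A <- lapply(seq_len(p), function(l) {
    rbind(B[1L + l, ], B[1L + p + l, ]) |> t()
  })
  structure(list(order = p, A = A, coef = B, Sigma = Sigma,
                 rss = colSums(res^2), n_eff = n_eff, se = se),
            class = "var_fit")
}

#' @export
print.var_fit <- function(x, ...) {
  cat(sprintf("<var_fit> bivariate VAR(%d), n_eff = %d\n", x$order, x$n_eff))
  cat("  residual covariance:\n")
  print(signif(x$Sigma, 4))
  invisible(x)
}

#' Select the VAR order by information criterion
#'
#' Fits orders `1..p_max` on a common effective sample (each trial's first
#' `p_max` frames excluded for every candidate order, so criteria are
#' comparable) and returns the minimizer. The criterion is computed from the
#' exact Gaussian log-likelihood with the ML residual covariance.
#'
#' @inheritParams fit_var_multitrial
#' @param p_max Largest order considered.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @return A list `p` (selected order), `criterion` (vector over orders),
#'   `logLik` (vector over orders).
#' @export
select_order <- function(trials, p_max = 30, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (p_max < 1L) stopf("p_max must be >= 1")
  vals <- numeric(p_max)
  lls <- numeric(p_max)
  for (p in seq_len(p_max)) {
    d <- var_design(trials, p, skip = p_max)
    B <- qr.coef(qr(d$X), d$Y)
    res <- d$Y - d$X %*% B
    n <- nrow(res)
    Sigma_ml <- crossprod(res) / n
    ll <- -n / 2 * (2 * log(2 * pi) + log(det(Sigma_ml)) + 2)
    k <- 2 * (2 * p + 1)
    lls[p] <- ll
    vals[p] <- if (criterion == "AIC") -2 * ll + 2 * k else -2 * ll + k * log(n)
  }
  list(p = which.min(vals), criterion = vals, logLik = lls)
}

#' Granger-causality magnitude between two channels
#'
#' Log residual-variance ratio of the reduced (own-lags only) and full
#' bivariate autoregressions, fitted by OLS on identical samples:
#' `F = ln(RSS_reduced / RSS_full)` for the target equation, in nats.
#' Negative values from numerical round-off are clipped at zero.
#'
#' @inheritParams fit_var_multitrial
#' @param direction `"1->2"` (channel 1's past helps predict channel 2) or
#'   `"2->1"`.
#' @param fit Optional pre-computed full [fit_var_multitrial()] of the same
#'   trials and order.
#' @return A list `gc` (nats), `p_value` (chi-squared likelihood-ratio test),
#'   `order`, `n_eff`.
#' @export
gc_magnitude <- function(trials, p, direction = c("1->2", "2->1"), fit = NULL) {
  direction <- match.arg(direction)
  if (is.null(fit)) fit <- fit_var_multitrial(trials, p)
  target <- if (direction == "1->2") 2L else 1L
  d <- var_design(trials, p)
  own <- c(1L, 1L + (if (target == 1L) seq_len(p) else p + seq_len(p)))
  Xr <- d$X[, own, drop = FALSE]
  y <- d$Y[, target]
  br <- qr.coef(qr(Xr), y)
  rss_red <- sum((y - Xr %*% br)^2)
  rss_full <- fit$rss[target]
  if (rss_full <= 0) stopf("non-positive full-model residual variance")
  gc <- log(rss_red / rss_full)
  if (gc < -1e-12) stopf("negative variance ratio beyond numerical tolerance")
  gc <- max(gc, 0)
  list(gc = gc, p_value = gc_significance(gc, fit$n_eff, p), order = p,
       n_eff = fit$n_eff)
}

#' Likelihood-ratio significance of a Granger-causality magnitude
#'
#' Under the null of no Granger causality, `n_eff * F` is asymptotically
#' chi-squared with `p` degrees of freedom (the number of excluded lag
#' coefficients); the p-value is the upper tail.
#'
#' @param magnitude GC magnitude in nats.
#' @param n_eff Effective number of observations.
#' @param p VAR order.
#' @return The p-value.
#' @export
gc_significance <- function(magnitude, n_eff, p) {
  if (n_eff <= p) stopf("n_eff must exceed the order")
  stats::pchisq(n_eff * magnitude, df = p, lower.tail = FALSE)
}

#' Per-animal multi-trial Granger causality between speed and activity
#'
#' Treats each animal's sessions as multi-trial data: the first minutes of
#' every session (detrended) enter a stacked VAR, and Granger-causality
#' magnitudes are computed in both directions (speed -> ACh and ACh ->
#' speed), overall and split by lighting condition. A per-session table
#' (single-trial GC at the animal-level order) is returned for mixed-model
#' analysis.
#'
#' @param cohort A stacked `aligned_session` data.frame.
#' @param p VAR order; `NULL` selects per animal (on all of that animal's
#'   sessions) by [select_order()].
#' @param p_max Largest order for selection.
#' @param minutes Segment length per session (default 5).
#' @param frame_rate Frame rate in Hz.
#' @param split_lighting Also compute per-lighting results (default TRUE).
#' @return A list with `per_animal` and `per_session` data.frames (columns
#'   `animal_id`, [`session_id`,] `lighting`, `direction`, `gc_nats`,
#'   `p_value`, `order`, `n_trials`).
#' @export
per_mouse_gc <- function(cohort, p = NULL, p_max = 30, minutes = 5,
                         frame_rate = 30, split_lighting = TRUE) {
  animals <- unique(cohort$animal_id)
  per_animal <- list()
  per_session <- list()
  for (a in animals) {
    sub <- cohort[cohort$animal_id == a, , drop = FALSE]
    sids <- unique(sub$session_id)
    trials <- lapply(sids, function(sid) {
      truncate_first_minutes(sub[sub$session_id == sid, , drop = FALSE],
                             minutes, frame_rate)
    })
    names(trials) <- sids
    lighting_of <- vapply(sids, function(sid) {
      sub$lighting[sub$session_id == sid][1]
    }, "")
    p_a <- p %||% select_order(trials, p_max)$p
    groups <- list(all = seq_along(trials))
    if (split_lighting) {
      for (lc in c("light", "dark")) {
        idx <- which(lighting_of == lc)
        if (length(idx)) groups[[lc]] <- idx
      }
    }
    for (g in names(groups)) {
      trs <- trials[groups[[g]]]
      fit <- fit_var_multitrial(trs, p_a)
      for (dir_lab in c("speed_to_ach", "ach_to_speed")) {
        gm <- gc_magnitude(trs, p_a,
                           direction = if (dir_lab == "speed_to_ach") "1->2" else "2->1",
                           fit = fit)
        per_animal[[length(per_animal) + 1L]] <- data.frame(
          animal_id = a, lighting = g, direction = dir_lab,
          gc_nats = gm$gc, p_value = gm$p_value, order = p_a,
          n_trials = length(trs), stringsAsFactors = FALSE)
      }
    }
    for (sid in sids) {
      trs <- trials[sid]
      fit <- tryCatch(fit_var_multitrial(trs, p_a), error = function(e) NULL)
      if (is.null(fit)) next
      for (dir_lab in c("speed_to_ach", "ach_to_speed")) {
        gm <- gc_magnitude(trs, p_a,
                           direction = if (dir_lab == "speed_to_ach") "1->2" else "2->1",
                           fit = fit)
        per_session[[length(per_session) + 1L]] <- data.frame(
          animal_id = a, session_id = sid, lighting = lighting_of[[sid]],
          direction = dir_lab, gc_nats = gm$gc, p_value = gm$p_value,
          order = p_a, stringsAsFactors = FALSE)
      }
    }
  }
  list(per_animal = do.call(rbind, per_animal),
       per_session = do.call(rbind, per_session))
}
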