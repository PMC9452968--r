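#' Simulate an open-field trajectory and pose track from behavior labels
#'
#' Produces the neck-point trajectory of a foraging mouse. Within locomotor
#' states (running, walking) the speed follows a bounded mean-reverting
#' (Ornstein-Uhlenbeck) process inside the state's configured speed range;
#' within stationary states (still, grooming, rearing) the planar neck speed
#' stays below 3 cm/s. Heading performs a random walk and reflects off the
#' arena walls. The written pose track adds Gaussian tracking jitter and
#' occasional low-likelihood (dropout) frames, emulating markerless tracking.
#'
#' @param labels A `behavior_labels` data.frame from [simulate_behavior()].
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return A list with `pose` (a `pose_track` data.frame: `frame`, `time_s`,
#'   `neck_x`, `neck_y`, `likelihood`), `speed_true` (cm/s per frame, the
#'   underlying process speed before tracking noise), and `path` (the true
#'   neck position per frame, always inside the arena).
#' @export
simulate_trajectory <- function(labels, config, seed = config$seed) {
  if (any(config$arena_size <= 0)) stopf("arena size must be positive")
  fr <- attr(labels, "frame_rate") %||% config$frame_rate
  dt <- 1 / fr
  n <- nrow(labels)
  short <- STATE_SHORT[labels$state]
  rng <- config$speed_ranges
  mu <- vapply(short, function(s) mean(rng[[s]]), 0)
  lo <- vapply(short, function(s) rng[[s]][1], 0)
  hi <- vapply(short, function(s) rng[[s]][2], 0)
  sig <- (hi - lo) / 4
  theta <- 1.0  # 1/s mean-reversion rate
  L <- config$arena_size

  with_seed(seed, {
    v <- numeric(n)
    x <- numeric(n)
    y <- numeric(n)
    v[1] <- mu[1]
    x[1] <- stats::runif(1, 0.25 * L[1], 0.75 * L[1])
    y[1] <- stats::runif(1, 0.25 * L[2], 0.75 * L[2])
    head_ang <- stats::runif(1, 0, 2 * pi)
    ev <- stats::rnorm(n)
    eh <- stats::rnorm(n, 0, 0.35)
    for (i in 2:n) {
      vi <- v[i - 1] + theta * (mu[i] - v[i - 1]) * dt +
        sig[i] * sqrt(dt) * ev[i]
      # reflect into the state's speed range
      for (rep_i in 1:4) {
        if (vi < lo[i]) vi <- 2 * lo[i] - vi else if (vi > hi[i]) vi <- 2 * hi[i] - vi else break
      }
      v[i] <- min(max(vi, lo[i]), hi[i])
      head_ang <- head_ang + eh[i]
      xi <- x[i - 1] + v[i] * dt * cos(head_ang)
      yi <- y[i - 1] + v[i] * dt * sin(head_ang)
      if (xi < 0 || xi > L[1]) {
        xi <- if (xi < 0) -xi else 2 * L[1] - xi
        head_ang <- pi - head_ang
      }
      if (yi < 0 || yi > L[2]) {
        yi <- if (yi < 0) -yi else 2 * L[2] - yi
        head_ang <- -head_ang
      }
      x[i] <- min(max(xi, 0), L[1])
      y[i] <- min(max(yi, 0), L[2])
    }
    nx <- x + stats::rnorm(n, 0, config$jitter_sd)
    ny <- y + stats::rnorm(n, 0, config$jitter_sd)
    bad <- stats::runif(n) < config$dropout_prob
    lik <- stats::runif(n, 0.95, 1)
    if (any(bad)) {
      lik[bad] <- stats::runif(sum(bad), 0, 0.5)
      nx[bad] <- nx[bad] + stats::rnorm(sum(bad), 0, 3)
      ny[bad] <- ny[bad] + stats::rnorm(sum(bad), 0, 3)
    }
    pose <- data.frame(frame = labels$frame, time_s = labels$time_s,
                       neck_x = nx, neck_y = ny, likelihood = lik,
                       row.names = NULL)
    class(pose) <- c("pose_track", "data.frame")
    attr(pose, "frame_rate") <- fr
    attr(pose, "arena_size") <- L
    list(pose = pose, speed_true = v,
         path = data.frame(frame = labels$frame, x = x, y = y))
  })
}
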