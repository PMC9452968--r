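#' Construct a raw two-channel photometry object
#'
#' @param time_s Sample times in seconds, strictly increasing.
#' @param f470 Calcium-dependent (473 nm excitation) channel, a.u.
#' @param f405 Isosbestic control (405 nm excitation) channel, a.u.
#' @param ttl_frame_times Video frame times in seconds (TTL rising edges).
#' @return An object of class `raw_photometry`.
#' @export
raw_photometry <- function(time_s, f470, f405, ttl_frame_times) {
  if (length(time_s) != length(f470) || length(time_s) != length(f405)) {
    stopf("channel lengths differ")
  }
  if (any(diff(time_s) <= 0)) stopf("time_s must be strictly increasing")
  if (length(ttl_frame_times) < 2L) stopf("need at least 2 TTL frames")
  structure(list(time_s = time_s, f470 = f470, f405 = f405,
                 ttl_frame_times = ttl_frame_times),
            class = "raw_photometry")
}

#' @export
print.raw_photometry <- function(x, ...) {
  cat(sprintf("<raw_photometry> %d samples over %.1f s, %d TTL frames\n",
              length(x$time_s), diff(range(x$time_s)),
              length(x$ttl_frame_times)))
  invisible(x)
}

#' Render raw two-channel photometry from a latent trace
#'
#' Converts a frame-rate latent z-trace into 500 Hz dual-channel raw
#' fluorescence with known ground truth. The true dF/F is the latent scaled
#' by `config$dff_amplitude` and carrying the indicator kernel's temporal
#' signature; the calcium-dependent channel is
#' `F470(t) = B470 exp(-t/tau) (1 + dF/F(t)) + m(t) + noise` and the control
#' `F405(t) = B405 exp(-t/tau') + gamma m(t) + noise`, where `m(t)` is a
#' shared sparse motion-artifact process (Poisson-timed exponentially decaying
#' transients). The 405 channel carries no calcium-dependent component.
#'
#' When `latent` is a `latent_trace` and `config$compensate_kernel` is `TRUE`,
#' the deterministic drive is preserved exactly at the measured dF/F level
#' (its pre-kernel form is the exact inverse filtering of the kernel) while
#' the AR(1) noise is injected before the kernel, so only the stochastic
#' component acquires the indicator's smoothing. The reported pre-kernel
#' latent (`truth$latent_pre`) always satisfies
#' `kernel_convolve(kernel, latent_pre) = true dF/F (z-units)` exactly
#' (after the first sample). When `latent` is a plain numeric vector the
#' whole trace is convolved with the kernel.
#'
#' @param latent A `latent_trace` from [simulate_latent()], or a numeric
#'   vector at frame rate (z-units).
#' @param config A [synth_config()].
#' @param seed Integer seed for artifacts and sensor noise.
#' @return A list with `raw` (a [raw_photometry()]) and `truth`, a
#'   `ground_truth` list: sample-level `time_s`, `dff_true` (dF/F units),
#'   `dff_z` (z-units), `latent_pre` (pre-kernel z-trace), `bleach470`,
#'   `bleach405`, `artifact`; frame-level `frame_time`, `dff_true_frames`,
#'   `drive_frames`; plus `coeffs` and `kernel`.
#' @export
render_photometry <- function(latent, config, seed = config$seed) {
  if (config$bleach$b470 <= 0 || config$bleach$b405 <= 0) {
    stopf("baseline intensities must be positive")
  }
  fr <- config$frame_rate
  pr <- config$photometry_rate
  is_trace <- inherits(latent, "latent_trace")
  nf <- if (is_trace) nrow(latent) else length(latent)
  if (nf < 2L) stopf("latent must span at least 2 frames")
  duration <- nf / fr
  np <- round(duration * pr)
  t500 <- (seq_len(np) - 1L) / pr
  frame_times <- (seq_len(nf) - 1L) / fr
  idx <- findInterval(t500, frame_times)
  kern <- calcium_kernel(config$kernel$rise_tau, config$kernel$half_decay,
                         dt = 1 / pr)

  if (is_trace && isTRUE(config$compensate_kernel)) {
    drive500 <- latent$drive[idx]
    noise500 <- kernel_convolve(kern, latent$noise[idx])
    # rescale the kernel-filtered noise so its frame-level SD matches the
    # configured (or auto) latent noise SD
    counts <- tabulate(idx, nbins = nf)
    noise_f <- rowsum(noise500, idx)[, 1] / counts
    sdf <- stats::sd(noise_f)
    target <- attr(latent, "noise_sd") %||% stats::sd(latent$noise)
    if (is.finite(sdf) && sdf > 0 && target > 0) {
      noise500 <- noise500 * (target / sdf)
    }
    dff_z <- drive500 + noise500
  } else {
    lat <- if (is_trace) latent$latent else as.numeric(latent)
    dff_z <- kernel_convolve(kern, lat[idx])
  }
  latent_pre <- kernel_deconvolve(kern, dff_z)
  dff_true <- config$dff_amplitude * dff_z

  bleach470 <- config$bleach$b470 * exp(-t500 / config$bleach$tau470)
  bleach405 <- config$bleach$b405 * exp(-t500 / config$bleach$tau405)

  with_seed(seed, {
    art <- config$artifact
    m <- numeric(np)
    n_ev <- stats::rpois(1, art$rate_per_min * duration / 60)
    if (n_ev > 0 && art$amplitude > 0) {
      ev_i <- sample.int(np, n_ev, replace = TRUE)
      imp <- numeric(np)
      amp <- art$amplitude * stats::rexp(n_ev)
      for (j in seq_len(n_ev)) imp[ev_i[j]] <- imp[ev_i[j]] + amp[j]
      m <- as.numeric(stats::filter(imp, exp(-1 / (pr * art$decay_s)),
                                    method = "recursive"))
    }
    f470 <- bleach470 * (1 + dff_true) + m +
      stats::rnorm(np, 0, config$sensor_noise_sd)
    f405 <- bleach405 + art$gain * m +
      stats::rnorm(np, 0, config$sensor_noise_sd)

    counts <- tabulate(idx, nbins = nf)
    truth <- structure(list(
      time_s = t500,
      dff_true = dff_true,
      dff_z = dff_z,
      latent_pre = latent_pre,
      bleach470 = bleach470,
      bleach405 = bleach405,
      artifact = m,
      frame_time = frame_times,
      dff_true_frames = rowsum(dff_true, idx)[, 1] / counts,
      drive_frames = if (is_trace) latent$drive else NULL,
      coeffs = if (is_trace) attr(latent, "coeffs") else NULL,
      kernel = kern
    ), class = "ground_truth")
    list(raw = raw_photometry(t500, f470, f405, frame_times), truth = truth)
  })
}
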