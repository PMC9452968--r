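# Short state aliases used throughout configs; community indices follow the
# labels file format.
STATE_SHORT <- c(exploratory_running = "run", exploratory_walking = "walk",
                 grooming = "groom", rearing = "rear", still = "still")
STATE_COMMUNITY <- c(run = 0L, walk = 1L, groom = 2L, rear = 3L, still = 4L)
COMMUNITY_STATE <- names(STATE_COMMUNITY)

#' Configuration for the synthetic session generator
#'
#' Bundles every parameter of the synthetic dual-channel fiber-photometry +
#' pose-tracking generator: open-field behavior (semi-Markov state sequence
#' with lognormal dwell times and target occupancies), locomotion (bounded
#' mean-reverting speed within each behavioral state), the latent cholinergic
#' signal (a log2-speed-driven linear model with behavioral offsets, random
#' animal/session effects, and AR(1) noise), indicator kinetics
#' (difference-of-exponentials kernel with a calibrated half-decay),
#' photobleaching, shared motion artifacts, and sensor noise.
#'
#' Default occupancies are the open-field time budgets reported for freely
#' foraging mice (1.4% grooming, 26.2% walking, 70.4% running, 2.1% rearing,
#' normalized to sum to one; `still` is 0 by default). Default regression
#' coefficients place the speed slope at 0.221 z-units per log2(cm/s) and the
#' rearing offset at 0.277 z-units; darkness has no effect by default.
#'
#' `noise$sd = NULL` (the default) sets the AR(1) noise standard deviation per
#' session to the complement of the realized drive variance so that the total
#' latent variance is one: the response analyzed downstream is per-session
#' z-scored dF/F, and unit total variance makes the configured coefficients
#' directly interpretable on the z scale.
#'
#' @param session_duration Session length in seconds (study sessions: 5-15 min).
#' @param photometry_rate Photometry sampling rate, Hz.
#' @param frame_rate Video frame rate, Hz.
#' @param arena_size Arena width and height in cm.
#' @param occupancy_targets Named fractions per behavioral state
#'   (`run`, `walk`, `groom`, `rear`, `still`); must sum to 1.
#' @param speed_ranges Named list of `c(lo, hi)` cm/s per state; stationary
#'   states (`still`, `groom`, `rear`) must stay below 3 cm/s.
#' @param dwell_medians Named median bout durations in seconds.
#' @param dwell_sdlog Lognormal sdlog of dwell durations.
#' @param coeffs Named list of latent-model coefficients in z-units:
#'   `beta0`, `beta_speed`, `beta_run`, `beta_rear`, `beta_groom`,
#'   `beta_dark` (main effect of darkness) and `beta_dark_slope`
#'   (darkness-by-log2(speed) interaction).
#' @param ranef_sd Named list of random-effect standard deviations:
#'   `animal_intercept`, `animal_slope`, `session_intercept`, `session_slope`.
#' @param noise List `phi` (AR(1) coefficient at frame rate) and `sd`
#'   (marginal SD; `NULL` = complement to unit session variance).
#' @param kernel List `rise_tau`, `half_decay` in seconds.
#' @param bleach List `b470`, `tau470`, `b405`, `tau405`: baseline intensities
#'   (a.u.) and single-exponential bleaching time constants (s) per channel.
#' @param artifact List `rate_per_min`, `amplitude` (a.u.), `decay_s`, and
#'   `gain` (gamma, artifact gain in the 405 channel).
#' @param sensor_noise_sd White sensor noise SD (a.u.) per 500 Hz sample.
#' @param dff_amplitude Peak-to-SD scale: dF/F units per latent z-unit.
#' @param speed_floor Epsilon (cm/s) used inside log2(max(speed, eps)).
#' @param jitter_sd Tracking jitter SD in cm per coordinate.
#' @param dropout_prob Probability a frame is written with low likelihood.
#' @param compensate_kernel If `TRUE` (default) the deterministic drive is
#'   preserved exactly at the measured dF/F level (the pre-kernel latent is
#'   the exact inverse filtering of the drive); if `FALSE` the whole latent is
#'   convolved with the kernel, attenuating measured-level coefficients.
#' @param seed Default integer seed.
#' @return A validated object of class `synth_config` (a named list).
#' @seealso [synth_config_locomotion()], [synth_config_stationary()],
#'   [synth_config_behavior()] for preset study conditions.
#' @export
synth_config <- function(session_duration = 300,
                         photometry_rate = 500,
                         frame_rate = 30,
                         arena_size = c(40, 40),
                         occupancy_targets = c(run = 0.704, walk = 0.262,
                                               groom = 0.014, rear = 0.021,
                                               still = 0) / 1.001,
                         speed_ranges = list(run = c(8, 25), walk = c(3, 8),
                                             groom = c(0, 2.5), rear = c(0, 2.5),
                                             still = c(0, 2.5)),
                         dwell_medians = c(run = 4, walk = 1.5, groom = 4,
                                           rear = 2, still = 3),
                         dwell_sdlog = 0.5,
                         coeffs = list(beta0 = -0.169, beta_speed = 0.221,
                                       beta_run = 0, beta_rear = 0.277,
                                       beta_groom = 0, beta_dark = 0,
                                       beta_dark_slope = 0),
                         ranef_sd = list(animal_intercept = 0.05,
                                         animal_slope = 0.03,
                                         session_intercept = 0.05,
                                         session_slope = 0.02),
                         noise = list(phi = 0.9, sd = NULL),
                         kernel = list(rise_tau = 0.2, half_decay = 1.69),
                         bleach = list(b470 = 2, tau470 = 1200,
                                       b405 = 1, tau405 = 1500),
                         artifact = list(rate_per_min = 2, amplitude = 0.1,
                                         decay_s = 0.3, gain = 0.8),
                         sensor_noise_sd = 0.004,
                         dff_amplitude = 0.05,
                         speed_floor = 0.25,
                         jitter_sd = 0.01,
                         dropout_prob = 0.01,
                         compensate_kernel = TRUE,
                         seed = 1L) {
  cfg <- structure(
    list(session_duration = session_duration,
         photometry_rate = photometry_rate, frame_rate = frame_rate,
         arena_size = arena_size, occupancy_targets = occupancy_targets,
         speed_ranges = speed_ranges, dwell_medians = dwell_medians,
         dwell_sdlog = dwell_sdlog, coeffs = coeffs, ranef_sd = ranef_sd,
         noise = noise, kernel = kernel, bleach = bleach, artifact = artifact,
         sensor_noise_sd = sensor_noise_sd, dff_amplitude = dff_amplitude,
         speed_floor = speed_floor, jitter_sd = jitter_sd,
         dropout_prob = dropout_prob, compensate_kernel = compensate_kernel,
         seed = as.integer(seed)),
    class = "synth_config"
  )
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  assert_scalar_num(cfg$session_duration, "session_duration", lower = 1)
  assert_scalar_num(cfg$photometry_rate, "photometry_rate", lower = 1)
  assert_scalar_num(cfg$frame_rate, "frame_rate", lower = 1)
  if (length(cfg$arena_size) != 2L || any(cfg$arena_size <= 0)) {
    stopf("arena_size must be two positive lengths in cm")
  }
  occ <- cfg$occupancy_targets
  if (is.null(names(occ)) || !all(names(occ) %in% names(STATE_COMMUNITY))) {
    stopf("occupancy_targets must be named with states %s",
          paste(names(STATE_COMMUNITY), collapse = ", "))
  }
  if (any(occ < 0)) stopf("occupancy_targets must be non-negative")
  if (abs(sum(occ) - 1) > 1e-9) {
    stopf("occupancy_targets must sum to 1 (got %.12g)", sum(occ))
  }
  active <- names(occ)[occ > 0]
  missing_rng <- setdiff(active, names(cfg$speed_ranges))
  if (length(missing_rng)) {
    stopf("states with positive occupancy lack a speed range: %s",
          paste(missing_rng, collapse = ", "))
  }
  bad_rng <- setdiff(names(cfg$speed_ranges), names(STATE_COMMUNITY))
  if (length(bad_rng)) stopf("unknown states in speed_ranges: %s",
                             paste(bad_rng, collapse = ", "))
  for (s in names(cfg$speed_ranges)) {
    r <- cfg$speed_ranges[[s]]
    if (length(r) != 2L || r[1] < 0 || r[2] < r[1]) {
      stopf("speed range for state '%s' must be c(lo, hi) with 0 <= lo <= hi", s)
    }
  }
  missing_dwell <- setdiff(active, names(cfg$dwell_medians))
  if (length(missing_dwell)) {
    stopf("states with positive occupancy lack a dwell median: %s",
          paste(missing_dwell, collapse = ", "))
  }
  if (any(cfg$dwell_medians <= 0)) stopf("dwell medians must be positive")
  assert_scalar_num(cfg$dwell_sdlog, "dwell_sdlog", lower = 0)
  need <- c("beta0", "beta_speed", "beta_run", "beta_rear", "beta_groom",
            "beta_dark", "beta_dark_slope")
  if (!all(need %in% names(cfg$coeffs))) {
    stopf("coeffs must contain %s", paste(need, collapse = ", "))
  }
  if (any(unlist(cfg$ranef_sd) < 0)) stopf("random-effect SDs must be >= 0")
  assert_scalar_num(cfg$noise$phi, "noise$phi", lower = -0.999, upper = 0.999)
  if (!is.null(cfg$noise$sd)) assert_scalar_num(cfg$noise$sd, "noise$sd", lower = 0)
  assert_scalar_num(cfg$kernel$half_decay, "kernel$half_decay", lower = 1e-6)
  assert_scalar_num(cfg$kernel$rise_tau, "kernel$rise_tau", lower = 1e-6)
  if (cfg$bleach$b470 <= 0 || cfg$bleach$b405 <= 0) {
    stopf("baseline intensities must be positive")
  }
  if (cfg$bleach$tau470 <= 0 || cfg$bleach$tau405 <= 0) {
    stopf("bleaching time constants must be positive")
  }
  if (cfg$artifact$rate_per_min < 0 || cfg$artifact$amplitude < 0 ||
      cfg$artifact$decay_s <= 0) {
    stopf("artifact parameters out of range")
  }
  assert_scalar_num(cfg$sensor_noise_sd, "sensor_noise_sd", lower = 0)
  assert_scalar_num(cfg$dff_amplitude, "dff_amplitude", lower = 1e-9)
  assert_scalar_num(cfg$speed_floor, "speed_floor", lower = 1e-9)
  assert_scalar_num(cfg$jitter_sd, "jitter_sd", lower = 0)
  assert_scalar_num(cfg$dropout_prob, "dropout_prob", lower = 0, upper = 0.5)
  cfg
}

#' Modify fields of a synthetic-data configuration
#'
#' Shallow-merges replacement values into an existing config and re-validates.
#' Nested lists (`coeffs`, `noise`, ...) are replaced element-wise.
#'
#' @param cfg A [synth_config()].
#' @param ... Named fields to replace; nested lists may be partial.
#' @return The updated, validated `synth_config`.
#' @export
update_synth_config <- function(cfg, ...) {
  mods <- list(...)
  for (nm in names(mods)) {
    if (!nm %in% names(cfg)) stopf("unknown synth_config field '%s'", nm)
    if (is.list(cfg[[nm]]) && is.list(mods[[nm]]) && !is.null(names(mods[[nm]]))) {
      for (sub in names(mods[[nm]])) cfg[[nm]][sub] <- mods[[nm]][sub]
    } else {
      cfg[[nm]] <- mods[[nm]]
    }
  }
  validate_synth_config(cfg)
}

#' Preset: locomotion cohort with speed-by-darkness truth
#'
#' Study conditions for recovering the three-fixed-effect model of z-scored
#' dF/F on log2(speed) and its darkness interaction: behavioral offsets are
#' zero, so the generative truth contains exactly the model's fixed effects
#' (intercept -0.169, log2(speed) slope 0.221, darkness interaction 0.013).
#'
#' @param ... Overrides forwarded to [update_synth_config()].
#' @return A `synth_config`.
#' @export
synth_config_locomotion <- function(...) {
  cfg <- synth_config()
  cfg <- update_synth_config(
    cfg,
    coeffs = list(beta0 = -0.169, beta_speed = 0.221, beta_run = 0,
                  beta_rear = 0, beta_groom = 0, beta_dark = 0,
                  beta_dark_slope = 0.013))
  if (...length() > 0) cfg <- update_synth_config(cfg, ...) else cfg
}

#' Preset: stationary-dominated sessions
#'
#' Sessions in which the animal is stationary (neck speed < 3 cm/s) for well
#' over two thirds of the recording: occupancy is shifted to still, grooming
#' and rearing with a modest walking share. The generative coefficients are
#' the stationary-subset model estimates (intercept 0.232, log2(speed) slope
#' 0.226, darkness interaction 0.068).
#'
#' @inheritParams synth_config_locomotion
#' @return A `synth_config`.
#' @export
synth_config_stationary <- function(...) {
  cfg <- synth_config()
  cfg <- update_synth_config(
    cfg,
    occupancy_targets = c(run = 0, walk = 0.2, groom = 0.15, rear = 0.1,
                          still = 0.55),
    speed_ranges = list(run = c(8, 25), walk = c(3, 6), groom = c(0, 2.5),
                        rear = c(0, 2.5), still = c(0, 2.5)),
    coeffs = list(beta0 = 0.232, beta_speed = 0.226, beta_run = 0,
                  beta_rear = 0, beta_groom = 0, beta_dark = 0,
                  beta_dark_slope = 0.068))
  if (...length() > 0) cfg <- update_synth_config(cfg, ...) else cfg
}

#' Preset: behavior-community cohort
#'
#' Study conditions for the six-fixed-effect behavior model: speed slope
#' 0.200, darkness main effect -0.029, exploratory-running offset -0.001,
#' rearing offset 0.277 and grooming offset -0.211 (exploratory walking is
#' the reference level).
#'
#' @inheritParams synth_config_locomotion
#' @return A `synth_config`.
#' @export
synth_config_behavior <- function(...) {
  cfg <- synth_config()
  cfg <- update_synth_config(
    cfg,
    coeffs = list(beta0 = -0.240, beta_speed = 0.200, beta_run = -0.001,
                  beta_rear = 0.277, beta_groom = -0.211, beta_dark = -0.029,
                  beta_dark_slope = 0))
  if (...length() > 0) cfg <- update_synth_config(cfg, ...) else cfg
}

#' @export
print.synth_config <- function(x, ...) {
  occ <- paste(sprintf("%s %.1f%%", names(x$occupancy_targets),
                       100 * x$occupancy_targets), collapse = ", ")
  cat(sprintf("<synth_config> %gs session, %g Hz photometry / %g Hz video\n",
              x$session_duration, x$photometry_rate, x$frame_rate))
  cat("  occupancy:", occ, "\n")
  cat(sprintf("  coeffs: b0 %.3g, speed %.3g, rear %.3g, groom %.3g, dark %.3g\n",
              x$coeffs$beta0, x$coeffs$beta_speed, x$coeffs$beta_rear,
              x$coeffs$beta_groom, x$coeffs$beta_dark))
  cat(sprintf("  kernel: rise %.3g s, half-decay %.3g s; AR(1) phi %.2f\n",
              x$kernel$rise_tau, x$kernel$half_decay, x$noise$phi))
  invisible(x)
}
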