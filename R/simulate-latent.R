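#' Simulate the latent cholinergic activity trace
#'
#' Builds the frame-rate latent signal, in z-units, as a linear function of
#' the logarithm of neck movement speed plus behavioral offsets, lighting
#' terms, random animal/session effects, and stationary AR(1) noise:
#'
#' `latent(t) = b0 + (b_speed + u_slope) * log2(max(speed(t), eps)) +
#'  b_run I\[run\] + b_rear I\[rear\] + b_groom I\[groom\] + b_dark I\[dark\] +
#'  b_dark_slope I\[dark\] log2(...) + u_int + noise(t)`
#'
#' where `u_int`/`u_slope` collect the animal- and session-level deviations.
#' With `noise$sd = NULL` the noise SD is set to the complement of the
#' realized drive variance so the session's total latent variance is 1
#' (z-scoring downstream is then close to the identity and the coefficients
#' remain interpretable on the z scale).
#'
#' @param speed Neck movement speed in cm/s per frame. The cohort simulator
#'   passes the *tracking-derived* speed here, because the regression
#'   coefficients are defined with respect to measured kinematics.
#' @param labels A `behavior_labels` data.frame, frame-aligned with `speed`.
#' @param config A [synth_config()].
#' @param lighting `"light"` or `"dark"`.
#' @param seed Integer seed (noise and, if not supplied, random effects).
#' @param animal_effects,session_effects Optional named vectors
#'   `c(intercept=, slope=)`; drawn from `config$ranef_sd` when `NULL`.
#' @param noise_sign `+1` or `-1`: multiplies the AR(1) noise. Two sessions
#'   with the same seed and opposite signs form an antithetic pair (identical
#'   drive, negated noise), a standard Monte-Carlo variance-reduction device
#'   for recovery studies.
#' @return A data.frame of class `latent_trace` with columns `frame`,
#'   `time_s`, `drive` (deterministic + random-effect part), `noise`, and
#'   `latent = drive + noise`; attributes carry the realized coefficients and
#'   noise SD.
#' @export
simulate_latent <- function(speed, labels, config, lighting = "light",
                            seed = config$seed,
                            animal_effects = NULL, session_effects = NULL,
                            noise_sign = 1) {
  n <- length(speed)
  if (nrow(labels) != n) stopf("speed and labels must be frame-aligned")
  if (!lighting %in% c("light", "dark")) stopf("lighting must be 'light' or 'dark'")
  cf <- config$coeffs
  l2s <- log2(pmax(speed, config$speed_floor))
  short <- STATE_SHORT[labels$state]
  dark <- as.numeric(lighting == "dark")

  with_seed(seed, {
    rs <- config$ranef_sd
    if (is.null(animal_effects)) {
      animal_effects <- c(intercept = stats::rnorm(1, 0, rs$animal_intercept),
                          slope = stats::rnorm(1, 0, rs$animal_slope))
    }
    if (is.null(session_effects)) {
      session_effects <- c(intercept = stats::rnorm(1, 0, rs$session_intercept),
                           slope = stats::rnorm(1, 0, rs$session_slope))
    }
    slope <- cf$beta_speed + animal_effects[["slope"]] + session_effects[["slope"]]
    intercept <- cf$beta0 + animal_effects[["intercept"]] +
      session_effects[["intercept"]]
    drive <- intercept + slope * l2s +
      cf$beta_run * (short == "run") +
      cf$beta_rear * (short == "rear") +
      cf$beta_groom * (short == "groom") +
      cf$beta_dark * dark +
      cf$beta_dark_slope * dark * l2s
    noise_sd <- config$noise$sd
    if (is.null(noise_sd)) {
      noise_sd <- sqrt(max(1 - stats::var(drive), 0.05))
    }
    noise <- noise_sign * ar1_series(n, config$noise$phi, noise_sd)
    out <- data.frame(frame = labels$frame, time_s = labels$time_s,
                      drive = drive, noise = noise, latent = drive + noise,
                      row.names = NULL)
    class(out) <- c("latent_trace", "data.frame")
    attr(out, "frame_rate") <- attr(labels, "frame_rate") %||% config$frame_rate
    attr(out, "coeffs") <- cf
    attr(out, "noise_sd") <- noise_sd
    attr(out, "lighting") <- lighting
    attr(out, "animal_effects") <- animal_effects
    attr(out, "session_effects") <- session_effects
    out
  })
}

#' Design matrix of the latent generative model
#'
#' The exact design matrix (intercept, log2 speed, behavioral indicators and
#' darkness terms) used by [simulate_latent()]; regressing a noiseless latent
#' trace on this matrix returns the configured coefficients up to numerical
#' precision.
#'
#' @inheritParams simulate_latent
#' @return A numeric matrix with named columns.
#' @export
latent_design <- function(speed, labels, config, lighting = "light") {
  l2s <- log2(pmax(speed, config$speed_floor))
  short <- STATE_SHORT[labels$state]
  dark <- as.numeric(lighting == "dark")
  cbind(intercept = 1, logspeed = l2s,
        run = as.numeric(short == "run"),
        rear = as.numeric(short == "rear"),
        groom = as.numeric(short == "groom"),
        dark = dark, dark_logspeed = dark * l2s)
}
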