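test_that("frame resampling averages within TTL windows", {
  raw <- make_raw()
  fr <- resample_to_frames(raw)
  expect_true(all(fr$s == 2))
  expect_true(all(fr$c == 1))
  expect_equal(nrow(fr), length(raw$ttl_frame_times))

  # linear ramp against a brute-force per-window mean
  raw2 <- make_raw(duration = 3, f470 = function(t) t, f405 = function(t) 2 * t)
  fr2 <- resample_to_frames(raw2)
  edges <- c(raw2$ttl_frame_times,
             max(raw2$ttl_frame_times) + median(diff(raw2$ttl_frame_times)))
  brute <- vapply(seq_along(raw2$ttl_frame_times), function(i) {
    sel <- raw2$time_s >= edges[i] & raw2$time_s < edges[i + 1]
    mean(raw2$f470[sel])
  }, 0)
  expect_equal(fr2$s, brute, tolerance = 1e-12)

  # 103 TTL frames -> 103 output rows
  t <- seq(0, 4, by = 1 / 500)
  raw3 <- raw_photometry(t, t, t, seq(0, length.out = 103, by = 1 / 30))
  expect_equal(nrow(resample_to_frames(raw3)), 103L)
})

test_that("an empty frame window raises an error naming the frame", {
  t <- c(seq(0, 0.099, by = 0.002), seq(0.2, 0.3, by = 0.002))
  raw <- raw_photometry(t, seq_along(t), seq_along(t),
                        c(0, 0.05, 0.12, 0.18))
  expect_error(resample_to_frames(raw), "frame window")
})

test_that("polynomial control adjustment absorbs the channel difference", {
  t <- seq(0, 10, by = 1 / 30)
  c_raw <- 1 + 0.1 * sin(t)
  adj <- adjust_control(c_raw, c_raw, t)
  expect_lt(max(abs(adj - c_raw)), 1e-9)

  s <- c_raw + (1 + 2 * t + 3 * t^2)
  adj2 <- adjust_control(s, c_raw, t)
  expect_lt(max(abs(s - adj2)), 1e-9)
  expect_error(adjust_control(1:2, 1:2, 1:2), "at least 3")
})

test_that("the polynomial fit matches the normal-equations oracle", {
  set.seed(2)
  t <- seq(0, 5, by = 1 / 30)
  c_raw <- rep(1, length(t))
  s <- c_raw + 0.5 - 0.2 * t + 0.05 * t^2 + rnorm(length(t), 0, 0.1)
  adj <- adjust_control(s, c_raw, t)
  d <- s - c_raw
  X <- cbind(1, t, t^2) # raw Vandermonde basis spans the same space
  fitted_oracle <- X %*% solve(crossprod(X), crossprod(X, d))
  expect_equal(adj, c_raw + as.numeric(fitted_oracle), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the scale/offset optimizer is exact and beats a grid search", {
  set.seed(3)
  c_adj <- 1 + 0.2 * sin(seq_len(500) / 20)
  expect_equal(fit_scale_offset(c_adj, c_adj), c(alpha = 1, beta = 0))
  expect_equal(fit_scale_offset(3 * c_adj + 5, c_adj), c(alpha = 3, beta = 5))

  s <- 2 * c_adj + 1 + rnorm(500, 0, 0.3)
  ab <- fit_scale_offset(s, c_adj)
  sse <- function(a, b) sum((s - (c_adj * a + b))^2)
  sse_hat <- sse(ab[["alpha"]], ab[["beta"]])
  grid_a <- seq(ab[["alpha"]] - 0.5, ab[["alpha"]] + 0.5, length.out = 201)
  grid_b <- seq(ab[["beta"]] - 0.5, ab[["beta"]] + 0.5, length.out = 201)
  grid_min <- min(outer(grid_a, grid_b,
                        Vectorize(function(a, b) sse(a, b))))
  expect_lte(sse_hat, grid_min + 1e-9)
  expect_error(fit_scale_offset(s, rep(1, 500)), "degenerate")
})

test_that("dF/F follows its closed form and guards the denominator", {
  c_adj <- 1 + 0.1 * cos(seq_len(200) / 10)
  base <- c_adj * 2 + 0.5
  expect_equal(compute_dff(base, c_adj, 2, 0.5), rep(0, 200))
  expect_equal(compute_dff(2 * base, c_adj, 2, 0.5), rep(1, 200))
  c_bad <- c(c_adj, 0.25)
  expect_error(compute_dff(rep(1, 201), c_bad, 2, -0.5), "frame")
})

test_that("z-scoring is exact, affine-invariant and idempotent", {
  expect_equal(zscore_session(c(0, 2)), c(-1, 1) / sqrt(2))
  set.seed(4)
  x <- rnorm(300, 5, 3)
  z <- zscore_session(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(zscore_session(2.5 * x + 7), z, tolerance = 1e-9)
  expect_equal(zscore_session(z), z, tolerance = 1e-9)
  expect_error(zscore_session(rep(1, 10)), "constant")
})

test_that("isosbestic correction rejects shared motion artifacts", {
  cfg <- test_config(
    coeffs = list(beta0 = 0, beta_speed = 0, beta_run = 0, beta_rear = 0,
                  beta_groom = 0, beta_dark = 0, beta_dark_slope = 0),
    ranef_sd = list(animal_intercept = 0, animal_slope = 0,
                    session_intercept = 0, session_slope = 0),
    noise = list(phi = 0.9, sd = 1e-4),
    artifact = list(rate_per_min = 6, amplitude = 0.1, decay_s = 0.3,
                    gain = 0.8))
  ratios <- vapply(1:5, function(s) {
    sess <- simulate_session(cfg, seed = 50 + s)
    fr <- resample_to_frames(sess$raw)
    c_adj <- adjust_control(fr$s, fr$c, fr$time_s)
    ab <- fit_scale_offset(fr$s, c_adj)
    corrected <- compute_dff(fr$s, c_adj, ab[["alpha"]], ab[["beta"]])
    uncorrected <- compute_dff(fr$s, fr$c, 1, 0)
    sd(uncorrected) / sd(corrected)
  }, 0)
  expect_true(all(ratios >= 4))
})

test_that("recovery degrades monotonically with sensor noise", {
  cfg0 <- test_config()
  meds <- vapply(c(0.004, 0.04, 0.2), function(ns) {
    cfg <- update_synth_config(cfg0, sensor_noise_sd = ns)
    median(vapply(1:10, function(s) {
      sess <- simulate_session(cfg, seed = 300 + s)
      cor(process_photometry(sess$raw)$dff, sess$truth$dff_true_frames)
    }, 0))
  }, 0)
  expect_true(all(diff(meds) <= 0))
})
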