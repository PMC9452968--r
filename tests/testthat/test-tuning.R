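test_that("1-s interval sampling picks the nearest frames", {
  s <- make_aligned(300 * 30)
  out <- sample_interval(s, 1)
  expect_equal(nrow(out), 300L)
  expect_true(all(abs(out$time_s - round(out$time_s)) <= 0.5 / 30 + 1e-12))
  # interval of one frame is the identity
  out2 <- sample_interval(s[1:90, ], 1 / 30)
  expect_equal(nrow(out2), 90L)
})

test_that("tuning-curve binning is exact, half-open, and respects min_count", {
  x <- c(0.2, 0.7, 1.0, 1.4, 2.5)
  tc <- bin_tuning_curve(x, rep(0.5, 5), 1, min_count = 1)
  expect_equal(tc$bin_n, c(2L, 2L, 1L))
  expect_true(all(tc$bin_mean == 0.5))
  expect_true(all(tc$bin_sem[tc$bin_n > 1] == 0))
  # a value exactly on an edge joins the upper bin
  expect_equal(tc$bin_left[which(tc$bin_n == 2L)], c(0, 1))

  tc2 <- bin_tuning_curve(x, rep(0.5, 5), 1, min_count = 2)
  expect_true(is.na(tc2$bin_mean[3]))

  set.seed(8)
  xs <- runif(20000, 0, 10)
  tc3 <- bin_tuning_curve(xs, xs, 1, min_count = 5)
  err <- abs(tc3$bin_mean - tc3$bin_center)
  sem_ref <- 1 / sqrt(12 * tc3$bin_n) # sd of U(0,1) over bin / sqrt(n)
  expect_true(all(err < 3 * pmax(sem_ref, tc3$bin_sem)))
})

test_that("binning is invariant to input permutation", {
  set.seed(2)
  x <- runif(500, 0, 5); z <- rnorm(500)
  p <- sample(500)
  expect_equal(bin_tuning_curve(x, z, 0.5), bin_tuning_curve(x[p], z[p], 0.5))
})

test_that("log-linear fit recovers exact lines and handles flat responses", {
  x <- seq(-2, 5, by = 0.01)
  f <- fit_linear_log(x, 0.2 * x - 0.1)
  expect_equal(f$slope, 0.2, tolerance = 1e-12)
  expect_equal(f$intercept, -0.1, tolerance = 1e-12)
  expect_equal(f$r, 1, tolerance = 1e-12)
  expect_warning(fz <- fit_linear_log(x, rep(1, length(x))), "zero-variance")
  expect_equal(fz$slope, 0)
  expect_equal(fz$r, 0)
  expect_error(fit_linear_log(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("session-level slope recovers the generative speed coefficient", {
  cfg <- synth_config(session_duration = 300)
  hits <- 0L
  for (s in 1:20) {
    sess <- simulate_session(cfg, seed = 400 + s)
    al <- process_session(sess, epsilon = cfg$speed_floor)
    ss <- sample_interval(al, 1)
    f <- fit_linear_log(ss$logspeed, ss$zdff)
    se <- sqrt(sum(resid(lm(ss$zdff ~ ss$logspeed))^2) / (f$n - 2) /
                 (var(ss$logspeed) * (f$n - 1)))
    # session truth includes that session's random animal/session slopes
    truth <- 0.221 + sess$truth$animal_effects[["slope"]] +
      sess$truth$session_effects[["slope"]]
    if (abs(f$slope - truth) < 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("saturating-exponential fit is exact on noiseless data and beats a grid", {
  speed <- seq(0, 30, by = 0.1)
  z <- 1 - 1.2 * exp(-speed / 8)
  f <- fit_saturating_exponential(speed, z)
  expect_equal(f$y_inf, 1, tolerance = 1e-6)
  expect_equal(f$amplitude, 1.2, tolerance = 1e-6)
  expect_equal(f$tau, 8, tolerance = 1e-6)
  expect_true(f$converged)

  set.seed(12)
  zn <- z + rnorm(length(z), 0, 0.3)
  fn <- fit_saturating_exponential(speed, zn)
  grid_sse <- min(vapply(seq(0.5, 1.5, length.out = 30), function(yinf) {
    min(vapply(seq(0.5, 2, length.out = 30), function(A) {
      min(vapply(seq(2, 20, length.out = 30), function(tau) {
        sum((zn - (yinf - A * exp(-speed / tau)))^2)
      }, 0))
    }, 0))
  }, 0))
  expect_lte(fn$sse, grid_sse + 1e-9)
})

test_that("log-linear data favor the linear fit over the exponential", {
  set.seed(31)
  wins <- 0L
  for (s in 1:20) {
    speed <- exp(runif(300, log(0.3), log(25)))
    x <- log2(pmax(speed, 0.25))
    z <- 0.25 * x + rnorm(300, 0, 0.35)
    lin <- fit_linear_log(x, z)
    ex <- fit_saturating_exponential(speed, z)
    if (lin$r > ex$r) wins <- wins + 1L
  }
  expect_gte(wins, 16L)
})

test_that("curve aggregation equals the brute-force across-session mean", {
  set.seed(6)
  curves <- lapply(1:6, function(i) {
    x <- runif(800, 0, 6)
    bin_tuning_curve(x, 0.3 * x + rnorm(800, 0, 0.5), 1)
  })
  agg1 <- aggregate_curves(curves[1])
  expect_equal(agg1$bin_mean, curves[[1]]$bin_mean)
  agg_same <- aggregate_curves(curves[c(1, 1)])
  expect_true(all(agg_same$bin_sem[agg_same$bin_n == 2] < 1e-12))

  agg <- aggregate_curves(curves, conditions = rep(c("light", "dark"), 3))
  light <- curves[c(1, 3, 5)]
  lefts <- sort(unique(unlist(lapply(light, `[[`, "bin_left"))))
  brute <- vapply(lefts, function(b) {
    mean(vapply(light, function(cu) {
      v <- cu$bin_mean[cu$bin_left == b]
      if (length(v)) v else NA_real_
    }, 0), na.rm = TRUE)
  }, 0)
  expect_equal(agg$bin_mean[agg$condition == "light"], brute)
})

test_that("log-speed tuning curves of log-linear cohorts stay linear", {
  # curves are built from 1-s samples (the latent AR(1) noise decorrelates
  # within ~0.3 s, so the bin SEMs are valid) and the quadratic term is
  # tested with inverse-variance weights
  cfg <- synth_config(session_duration = 600)
  n_nonlinear <- 0L
  for (s in 1:20) {
    co <- simulate_latent_cohort(cfg, 1, 1, seed = 600 + s)
    ss <- sample_interval(co, 1)
    tc <- bin_tuning_curve(ss$logspeed, ss$zdff, 0.4, min_count = 10)
    tc <- tc[!is.na(tc$bin_mean) & tc$bin_sem > 0, ]
    fit <- lm(bin_mean ~ bin_center + I(bin_center^2), data = tc,
              weights = 1 / tc$bin_sem^2)
    p_quad <- summary(fit)$coefficients[3, 4]
    if (p_quad < 0.05) n_nonlinear <- n_nonlinear + 1L
  }
  expect_lte(n_nonlinear, 2L)
})
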