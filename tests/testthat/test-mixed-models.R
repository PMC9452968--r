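make_lmm_cohort <- function(n_animals = 3, n_sessions = 2, n = 400,
                            beta = c(0.1, 0.25, 0.03), sd_noise = 0.5,
                            re_sd = c(0, 0), seed = 1) {
  set.seed(seed)
  parts <- list()
  for (a in seq_len(n_animals)) {
    a_int <- rnorm(1, 0, re_sd[1])
    for (j in seq_len(n_sessions)) {
      s_int <- rnorm(1, 0, re_sd[2])
      lighting <- if (j %% 2) "light" else "dark"
      speed <- exp(runif(n, log(0.3), log(25)))
      lg <- log2(pmax(speed, 0.25))
      dark <- as.numeric(lighting == "dark")
      z <- beta[1] + a_int + s_int + beta[2] * lg + beta[3] * lg * dark +
        rnorm(n, 0, sd_noise)
      parts[[length(parts) + 1L]] <- make_aligned(
        n, animal_id = sprintf("m%02d", a),
        session_id = sprintf("m%02d_s%02d", a, j), lighting = lighting,
        zdff = z, speed = speed)
    }
  }
  do.call(rbind, parts)
}

test_that("designs encode the study models' fixed effects", {
  co <- make_lmm_cohort()
  d <- build_design(co, "speed_dark")
  expect_equal(d$fixed_names, c("(Intercept)", "logspeed", "logspeed_dark"))
  expect_true(all(d$data$dark[co$lighting == "light"] == 0))

  st <- c(rep("exploratory_running", 100), rep("exploratory_walking", 100),
          rep("grooming", 50), rep("rearing", 50))
  co2 <- make_aligned(300)
  co2 <- rbind(co2, make_aligned(300, animal_id = "m02", session_id = "s2",
                                 lighting = "dark"))
  co2$state <- rep(st, length.out = 600)
  co2$community <- unname(cholspeed:::STATE_COMMUNITY[
    cholspeed:::STATE_SHORT[co2$state]])
  d2 <- build_design(co2, "behavior_speed_dark")
  expect_length(d2$fixed_names, 6L)
  expect_error(build_design(co, "not_a_model"), "unknown formula_id")
})

test_that("with no random variance the fit reduces to ordinary least squares", {
  co <- make_lmm_cohort(n_animals = 2, n_sessions = 2, re_sd = c(0, 0))
  f <- suppressWarnings(fit_lmm(build_design(co, "speed_dark")))
  d <- build_design(co, "speed_dark")$data
  ols <- lm(zdff ~ logspeed + logspeed_dark, d)
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("the REML optimum beats random perturbations of the variance parameters", {
  co <- make_lmm_cohort(n_animals = 4, n_sessions = 2, n = 60,
                        re_sd = c(0.3, 0.2), seed = 5)
  f <- suppressWarnings(fit_lmm(build_design(co, "speed_dark")))
  dd <- lme4::lmer(build_design(co, "speed_dark")$formula,
                   data = build_design(co, "speed_dark")$data, REML = TRUE,
                   devFunOnly = TRUE)
  th <- lme4::getME(f$fit, "theta")
  crit_hat <- dd(th)
  set.seed(11)
  for (i in 1:50) {
    probe <- pmax(th + rnorm(length(th), 0, 0.1), 0)
    expect_gte(dd(probe), crit_hat - 1e-6)
  }
})

test_that("information criteria are internally consistent and match lme4", {
  co <- make_lmm_cohort(n_animals = 3, n_sessions = 2, n = 100,
                        re_sd = c(0.2, 0.2), seed = 2)
  f <- suppressWarnings(fit_lmm(build_design(co, "speed_dark")))
  st <- f$stats
  expect_equal(st[["aic"]], st[["deviance"]] + 2 * st[["k"]])
  expect_equal(st[["bic"]], st[["deviance"]] + st[["k"]] * log(st[["n"]]))
  expect_equal(st[["aic"]], AIC(f$fit), tolerance = 1e-8)
  expect_equal(st[["bic"]], BIC(f$fit), tolerance = 1e-8)
})

test_that("fixed effects are invariant to relabeling of groups", {
  co <- make_lmm_cohort(n_animals = 3, n_sessions = 2, n = 80,
                        re_sd = c(0.2, 0.1), seed = 3)
  f1 <- suppressWarnings(fit_lmm(build_design(co, "speed_dark")))
  co2 <- co
  perm <- c(m01 = "zebra", m02 = "alpha", m03 = "kiwi")
  co2$animal_id <- perm[co2$animal_id]
  co2$session_id <- paste0("x_", co2$session_id)
  f2 <- suppressWarnings(fit_lmm(build_design(co2, "speed_dark")))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("a noiseless generator is recovered exactly (unscaled response)", {
  # generative truth restricted to the fitted model's own terms; any
  # behavioral offset would be an intentionally misspecified model instead
  cfg <- test_config(
    session_duration = 30,
    coeffs = list(beta0 = -0.169, beta_speed = 0.221, beta_run = 0,
                  beta_rear = 0, beta_groom = 0, beta_dark = 0,
                  beta_dark_slope = 0.013),
    ranef_sd = list(animal_intercept = 0, animal_slope = 0,
                    session_intercept = 0, session_slope = 0),
    noise = list(phi = 0.9, sd = 0), jitter_sd = 0, dropout_prob = 0)
  rep_res <- suppressWarnings(
    recovery_study(cfg, "speed_dark", n_replicates = 2, seed = 4,
                   n_animals = 2, sessions_per_animal = 2, zscore = FALSE))
  expect_lt(max(abs(rep_res$per_coefficient$bias)), 1e-6)
})

test_that("the direction effect has a calibrated rejection rate under its null", {
  set.seed(9)
  rej <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    rows <- list()
    for (a in 1:5) {
      a_int <- rnorm(1, 0, 5e-4)
      for (j in 1:10) {
        s_int <- rnorm(1, 0, 5e-4)
        base <- 0.003 + a_int + s_int
        lighting <- if (j %% 2) "light" else "dark"
        for (dir in c("speed_to_ach", "ach_to_speed")) {
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = sprintf("m%d", a),
            session_id = sprintf("m%d_s%d", a, j), lighting = lighting,
            direction = dir, gc_nats = base + rnorm(1, 0, 1e-3),
            p_value = NA_real_, order = 9L)
        }
      }
    }
    tab <- do.call(rbind, rows)
    f <- suppressWarnings(fit_lmm(build_design(tab, "gc_direction_dark")))
    pv <- f$coefficients$p[f$coefficients$name == "dir_ach_to_speed"]
    if (pv < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_rep, 0.02)
  expect_lte(rej / n_rep, 0.09)
})

test_that("doubling the cohort tightens speed-slope recovery", {
  cfg <- synth_config(session_duration = 60,
                      ranef_sd = list(animal_intercept = 0.05, animal_slope = 0,
                                      session_intercept = 0.05,
                                      session_slope = 0.02))
  r_small <- suppressWarnings(
    recovery_study(cfg, "speed_dark", n_replicates = 8, seed = 10,
                   n_animals = 3, sessions_per_animal = 2))
  r_big <- suppressWarnings(
    recovery_study(cfg, "speed_dark", n_replicates = 8, seed = 10,
                   n_animals = 3, sessions_per_animal = 8))
  rm_s <- r_small$per_coefficient
  rm_b <- r_big$per_coefficient
  expect_lt(rm_b$rmse[rm_b$name == "logspeed"],
            rm_s$rmse[rm_s$name == "logspeed"])
})
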