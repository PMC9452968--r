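LMM_FORMULAS <- c("speed_dark", "stationary_speed_dark", "gc_direction_dark",
                  "behavior_speed_dark")

#' Build a mixed-model design from frame- or session-level data
#'
#' Constructs the response, fixed-effect columns and random-effects structure
#' for the four study models:
#'
#' * `speed_dark`: z-dF/F on intercept, log2(speed) and the
#'   log2(speed) x darkness interaction, with uncorrelated random effects on
#'   all three terms for animal and for session (7 covariance parameters).
#' * `stationary_speed_dark`: the same model, intended for the
#'   stationary-session subset (apply [stationary_session_filter()] first).
#' * `gc_direction_dark`: per-session Granger-causality magnitude on
#'   intercept, direction (ACh->Speed vs the Speed->ACh reference), darkness
#'   and their interaction, with uncorrelated random effects on all four
#'   terms for animal and session.
#' * `behavior_speed_dark`: z-dF/F on intercept, log2(speed), darkness and
#'   behavior-community indicators (exploratory running, rearing, grooming;
#'   exploratory walking is the reference level), with random intercepts for
#'   animal, session, darkness level and community.
#'
#' @param data For the first two and last formulas, a stacked
#'   `aligned_session` data.frame; for `gc_direction_dark`, the `per_session`
#'   table from [per_mouse_gc()].
#' @param formula_id One of `"speed_dark"`, `"stationary_speed_dark"`,
#'   `"gc_direction_dark"`, `"behavior_speed_dark"`.
#' @return An object of class `lmm_design`: list with `data` (model frame),
#'   `formula`, `fixed_names`, `formula_id`.
#' @export
build_design <- function(data, formula_id) {
  if (!is_string(formula_id) || !formula_id %in% LMM_FORMULAS) {
    stopf("unknown formula_id '%s' (use one of %s)",
          paste(formula_id, collapse = ","), paste(LMM_FORMULAS, collapse = ", "))
  }
  if (formula_id %in% c("speed_dark", "stationary_speed_dark")) {
    need <- c("zdff", "logspeed", "lighting", "animal_id", "session_id")
    check_cols(data, need)
    df <- data.frame(
      zdff = data$zdff, logspeed = data$logspeed,
      dark = as.numeric(data$lighting == "dark"),
      animal = factor(data$animal_id), session = factor(data$session_id))
    df$logspeed_dark <- df$logspeed * df$dark
    form <- zdff ~ 1 + logspeed + logspeed_dark +
      (1 + logspeed + logspeed_dark || animal) +
      (1 + logspeed + logspeed_dark || session)
    fixed <- c("(Intercept)", "logspeed", "logspeed_dark")
  } else if (formula_id == "gc_direction_dark") {
    need <- c("gc_nats", "direction", "lighting", "animal_id", "session_id")
    check_cols(data, need)
    df <- data.frame(
      gc_nats = data$gc_nats,
      dir_ach_to_speed = as.numeric(data$direction == "ach_to_speed"),
      dark = as.numeric(data$lighting == "dark"),
      animal = factor(data$animal_id), session = factor(data$session_id))
    df$dir_dark <- df$dir_ach_to_speed * df$dark
    form <- gc_nats ~ 1 + dir_ach_to_speed + dark + dir_dark +
      (1 + dir_ach_to_speed + dark + dir_dark || animal) +
      (1 + dir_ach_to_speed + dark + dir_dark || session)
    fixed <- c("(Intercept)", "dir_ach_to_speed", "dark", "dir_dark")
  } else { # behavior_speed_dark
    need <- c("zdff", "logspeed", "lighting", "animal_id", "session_id", "state")
    check_cols(data, need)
    short <- STATE_SHORT[data$state]
    df <- data.frame(
      zdff = data$zdff, logspeed = data$logspeed,
      dark = as.numeric(data$lighting == "dark"),
      er = as.numeric(short == "run"),
      rearing = as.numeric(short == "rear"),
      grooming = as.numeric(short == "groom"),
      animal = factor(data$animal_id), session = factor(data$session_id),
      dark_f = factor(data$lighting),
      community = factor(data$community %||% STATE_COMMUNITY[short]))
    form <- zdff ~ 1 + logspeed + dark + er + rearing + grooming +
      (1 | animal) + (1 | session) + (1 | dark_f) + (1 | community)
    # the darkness/community intercepts are exactly confounded with the
    # fixed dummies; when the factorization fails, the structure is
    # simplified to the identifiable animal/session intercepts
    fallback <- zdff ~ 1 + logspeed + dark + er + rearing + grooming +
      (1 | animal) + (1 | session)
    fixed <- c("(Intercept)", "logspeed", "dark", "er", "rearing", "grooming")
  }
  X <- stats::model.matrix(stats::reformulate(setdiff(fixed, "(Intercept)")),
                           df)
  if (qr(X)$rank < ncol(X)) {
    stopf("rank-deficient fixed-effects design for '%s'", formula_id)
  }
  structure(list(data = df, formula = form,
                 fallback_formula = if (exists("fallback", inherits = FALSE))
                   fallback,
                 fixed_names = fixed, formula_id = formula_id),
            class = "lmm_design")
}

check_cols <- function(data, need) {
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("data lacks columns: %s", paste(miss, collapse = ", "))
}

#' Fit a linear mixed-effects model with residual-DF t inference
#'
#' Fits the design by (restricted) maximum likelihood and reports a
#' coefficient table with t statistics on residual degrees of freedom
#' (`n - p`, the convention matching very large frame-level DFs), 95%
#' confidence intervals, variance components, and AIC/BIC/log-likelihood/
#' deviance. Singular fits (a variance component at zero) produce a warning,
#' not an error.
#'
#' For large frame-level designs the optimizer is warm-started: the variance
#' components are first estimated on a systematically thinned subsample
#' (every k-th frame) and used as starting values for the full-data fit,
#' which typically cuts the optimization time several-fold without changing
#' the optimum.
#'
#' @param design An [build_design()] result.
#' @param method `"REML"` (default) or `"ML"`.
#' @param warm_start_rows Thin the data to about this many rows for a pilot
#'   fit whose variance components initialize the full fit; `NULL` disables,
#'   the default (`50000`) only engages when the data are at least twice
#'   that size.
#' @return An object of class `lmm_fit`: `coefficients` (data.frame `name`,
#'   `estimate`, `se`, `t`, `df`, `p`, `ci_low`, `ci_high`), `varcor`
#'   (data.frame of variance components), `stats` (named: `aic`, `bic`,
#'   `logLik`, `deviance`, `n`, `k`), `formula_id`, `fit` (the underlying
#'   lme4 object).
#' @export
fit_lmm <- function(design, method = c("REML", "ML"), warm_start_rows = 50000) {
  method <- match.arg(method)
  for (g in c("animal", "session")) {
    if (g %in% names(design$data) && nlevels(design$data[[g]]) < 2L) {
      stopf("grouping factor '%s' needs at least 2 levels", g)
    }
  }
  ctrl <- lme4::lmerControl(calc.derivs = FALSE)
  start <- NULL
  n_rows <- nrow(design$data)
  if (!is.null(warm_start_rows) && n_rows >= 2 * warm_start_rows) {
    thin <- design$data[seq(1L, n_rows, by = ceiling(n_rows / warm_start_rows)), ]
    pilot <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(design$formula, data = thin, REML = method == "REML",
                   control = ctrl))),
      error = function(e) NULL)
    if (!is.null(pilot)) start <- lme4::getME(pilot, "theta")
  }
  fit_ctrl <- ctrl
  if (!is.null(start)) {
    # warm-started large-n fit: variance components start near the optimum,
    # and the fixed effects are insensitive to theta at this resolution
    # (verified below machine noise), so looser stopping rules apply
    fit_ctrl <- lme4::lmerControl(
      calc.derivs = FALSE,
      optCtrl = list(ftol_abs = 1e-3, xtol_abs = 1e-4))
  }
  fit <- tryCatch(
    lme4::lmer(design$formula, data = design$data, REML = method == "REML",
               start = start, control = fit_ctrl),
    error = function(e) e)
  if (inherits(fit, "error") && !is.null(design$fallback_formula)) {
    warnf("random-effects structure simplified after '%s'; refitting with %s",
          conditionMessage(fit), deparse(design$fallback_formula[[3]]))
    fit <- tryCatch(
      lme4::lmer(design$fallback_formula, data = design$data,
                 REML = method == "REML", control = ctrl),
      error = function(e) e)
  }
  if (inherits(fit, "error")) {
    stopf("mixed-model fit failed: %s", conditionMessage(fit))
  }
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warnf("singular fit: one or more variance components estimated at zero")
  }
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n <- stats::nobs(fit)
  df_resid <- n - length(beta)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE)
  tcrit <- stats::qt(0.975, df_resid)
  coefs <- data.frame(
    name = names(beta), estimate = unname(beta), se = unname(se),
    t = unname(tval), df = df_resid, p = unname(pval),
    ci_low = unname(beta - tcrit * se), ci_high = unname(beta + tcrit * se),
    row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  dev <- -2 * as.numeric(ll)
  structure(list(
    coefficients = coefs,
    varcor = vc,
    stats = c(aic = dev + 2 * k, bic = dev + k * log(n),
              logLik = as.numeric(ll), deviance = dev, n = n, k = k),
    formula_id = design$formula_id,
    method = method,
    fit = fit), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<lmm_fit> %s (%s), n = %d\n", x$formula_id, x$method,
              as.integer(x$stats[["n"]])))
  cf <- x$coefficients
  cf[, c("estimate", "se", "t", "p", "ci_low", "ci_high")] <-
    lapply(cf[, c("estimate", "se", "t", "p", "ci_low", "ci_high")],
           signif, digits)
  print(cf, row.names = FALSE)
  cat(sprintf("AIC %.4g  BIC %.4g  logLik %.4g  deviance %.4g\n",
              x$stats[["aic"]], x$stats[["bic"]], x$stats[["logLik"]],
              x$stats[["deviance"]]))
  invisible(x)
}

# Truth values of the fixed effects implied by a synth_config, per formula.
lmm_truth <- function(config, formula_id) {
  cf <- config$coeffs
  switch(formula_id,
         speed_dark = ,
         stationary_speed_dark = c(
           "(Intercept)" = cf$beta0, logspeed = cf$beta_speed,
           logspeed_dark = cf$beta_dark_slope),
         behavior_speed_dark = c(
           "(Intercept)" = cf$beta0, logspeed = cf$beta_speed,
           dark = cf$beta_dark, er = cf$beta_run, rearing = cf$beta_rear,
           grooming = cf$beta_groom),
         stopf("no generator truth defined for formula '%s'", formula_id))
}

#' Parameter-recovery study for the mixed models
#'
#' Simulates replicate cohorts from a generator configuration, fits the
#' requested mixed model to each, and reports bias, RMSE, empirical coverage
#' of the 95% confidence intervals, and the Monte-Carlo standard error of
#' the mean estimate per fixed-effect coefficient.
#'
#' Replicates are simulated at the latent level by default (the latent trace
#' is z-scored directly, skipping photometry rendering and re-estimation),
#' which isolates the model-fitting stage; `use_pipeline = TRUE` runs the
#' full photometry pipeline instead.
#'
#' @param config A [synth_config()].
#' @param formula_id Model to fit (see [build_design()]).
#' @param n_replicates Number of simulated cohorts.
#' @param seed Base seed.
#' @param n_animals,sessions_per_animal,lighting_schedule Cohort layout.
#' @param use_pipeline If `TRUE`, run the full raw-photometry pipeline.
#' @param zscore Latent-level path only: z-score the response per session
#'   (the study convention; default) or fit the raw latent. With zscoring
#'   disabled and a noiseless generator, recovery is exact, which isolates
#'   defects in the fitting machinery from scaling effects.
#' @param stationary_filter Apply [stationary_session_filter()] before
#'   fitting (for the stationary model).
#' @return An object of class `recovery_report`: `per_coefficient`
#'   data.frame (`name`, `truth`, `mean_estimate`, `bias`, `rmse`,
#'   `coverage`, `mc_se`, `n_fits`), `estimates` (replicate x coefficient),
#'   and `failures` (character vector of error messages, if any).
#' @export
recovery_study <- function(config, formula_id = "speed_dark",
                           n_replicates = 10, seed = config$seed,
                           n_animals = 5, sessions_per_animal = 4,
                           lighting_schedule = "alternate",
                           use_pipeline = FALSE, zscore = TRUE,
                           stationary_filter = formula_id == "stationary_speed_dark") {
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  truth <- lmm_truth(config, formula_id)
  ests <- list(); los <- list(); his <- list()
  failures <- character(0)
  for (r in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, 7000, r)
    fit <- tryCatch({
      cohort <- if (use_pipeline) {
        simulate_aligned_cohort(config, n_animals, sessions_per_animal,
                                lighting_schedule, seed = rep_seed)
      } else {
        simulate_latent_cohort(config, n_animals, sessions_per_animal,
                               lighting_schedule, seed = rep_seed,
                               zscore = zscore)
      }
      if (stationary_filter) {
        cohort <- stationary_session_filter(cohort)
        if (!nrow(cohort)) stopf("no stationary sessions in replicate")
      }
      suppressWarnings(fit_lmm(build_design(cohort, formula_id)))
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
      next
    }
    cf <- fit$coefficients
    ests[[length(ests) + 1L]] <- stats::setNames(cf$estimate, cf$name)
    los[[length(los) + 1L]] <- stats::setNames(cf$ci_low, cf$name)
    his[[length(his) + 1L]] <- stats::setNames(cf$ci_high, cf$name)
  }
  if (!length(ests)) stopf("all replicates failed: %s", failures[1])
  E <- do.call(rbind, ests)
  L <- do.call(rbind, los)
  H <- do.call(rbind, his)
  nm <- colnames(E)
  tr <- truth[nm]
  per <- data.frame(
    name = nm, truth = unname(tr),
    mean_estimate = colMeans(E),
    bias = colMeans(E) - unname(tr),
    rmse = sqrt(colMeans(sweep(E, 2, tr)^2)),
    coverage = colMeans(L <= rep(tr, each = nrow(L)) &
                          rep(tr, each = nrow(H)) <= H),
    mc_se = apply(E, 2, stats::sd) / sqrt(nrow(E)),
    n_fits = nrow(E), row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_coefficient = per, estimates = E, failures = failures),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  cat(sprintf("<recovery_report> %d fits (%d failures)\n",
              x$per_coefficient$n_fits[1], length(x$failures)))
  pc <- x$per_coefficient
  pc[, -1] <- lapply(pc[, -1], signif, digits)
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Simulate a cohort at the latent level
#'
#' Fast path for recovery and coverage studies: behavior, trajectory and the
#' latent trace are simulated as usual, but the (optionally z-scored) latent
#' itself serves as the response — photometry rendering and re-estimation are
#' skipped. Useful when the question concerns the downstream statistics
#' rather than the optical correction.
#'
#' @inheritParams simulate_cohort
#' @param zscore Z-score the latent per session (the study convention).
#' @param noise_sign `+1`/`-1`: see [simulate_latent()]; opposite signs with
#'   the same seed yield antithetic cohort pairs.
#' @return A stacked `aligned_session` data.frame.
#' @export
simulate_latent_cohort <- function(config, n_animals = 2,
                                   sessions_per_animal = 2,
                                   lighting_schedule = "alternate",
                                   seed = config$seed, zscore = TRUE,
                                   noise_sign = 1) {
  ns <- rep_len(sessions_per_animal, n_animals)
  parts <- vector("list", sum(ns))
  k <- 0L
  for (a in seq_len(n_animals)) {
    eff <- with_seed(derive_seed(seed, a, 0), c(
      intercept = stats::rnorm(1, 0, config$ranef_sd$animal_intercept),
      slope = stats::rnorm(1, 0, config$ranef_sd$animal_slope)))
    for (j in seq_len(ns[a])) {
      sseed <- derive_seed(seed, a, j)
      labels <- simulate_behavior(config, seed = derive_seed(sseed, 1))
      traj <- simulate_trajectory(labels, config, seed = derive_seed(sseed, 2))
      pose_i <- interpolate_low_likelihood(traj$pose, 0.9)
      sp <- neck_speed(pose_i, frame_rate = config$frame_rate,
                       epsilon = config$speed_floor)
      lighting <- resolve_lighting(lighting_schedule, a, j)
      lat <- simulate_latent(sp$speed, labels, config, lighting,
                             seed = derive_seed(sseed, 3),
                             animal_effects = eff, noise_sign = noise_sign)
      k <- k + 1L
      out <- data.frame(
        animal_id = sprintf("m%02d", a),
        session_id = sprintf("m%02d_s%03d", a, j),
        lighting = lighting, frame = labels$frame, time_s = labels$time_s,
        dff = lat$latent,
        zdff = if (zscore) zscore_session(lat$latent) else lat$latent,
        speed = sp$speed, logspeed = sp$logspeed,
        stationary = sp$stationary, state = labels$state,
        community = labels$community, row.names = NULL)
      parts[[k]] <- out
    }
  }
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  class(res) <- c("aligned_session", "data.frame")
  res
}
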