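sim_var1 <- function(n, A, sd = c(1, 1), burn = 200, coupling_noise = NULL) {
  x <- matrix(0, n + burn, 2)
  e <- cbind(rnorm(n + burn, 0, sd[1]), rnorm(n + burn, 0, sd[2]))
  for (t in 2:(n + burn)) x[t, ] <- A %*% x[t - 1, ] + e[t, ]
  x[(burn + 1):(burn + n), ]
}

test_that("the Granger segment truncates, warns, and detrends", {
  s <- make_aligned(10 * 60 * 30)
  tr <- truncate_first_minutes(s, 5, 30)
  expect_equal(nrow(tr), 9000L)
  expect_lt(max(abs(colMeans(tr))), 1e-12)
  s2 <- make_aligned(4 * 60 * 30)
  expect_warning(tr2 <- truncate_first_minutes(s2, 5, 30), "shorter")
  expect_equal(nrow(tr2), 4 * 60 * 30)
})

test_that("the multi-trial VAR equals an explicitly stacked regression", {
  set.seed(1)
  A <- matrix(c(0.5, 0, 0.2, 0.4), 2)
  trials <- list(sim_var1(300, A), sim_var1(250, A), sim_var1(400, A))
  p <- 2
  f <- fit_var_multitrial(trials, p)
  # oracle: build the stacked design by hand and use lm()
  rows <- list()
  for (tr in trials) {
    for (t in (p + 1):nrow(tr)) {
      rows[[length(rows) + 1L]] <- c(tr[t, ], tr[t - 1, ], tr[t - 2, ])
    }
  }
  M <- do.call(rbind, rows)
  d <- data.frame(y1 = M[, 1], y2 = M[, 2], x1l1 = M[, 3], x2l1 = M[, 4],
                  x1l2 = M[, 5], x2l2 = M[, 6])
  o1 <- lm(y1 ~ x1l1 + x1l2 + x2l1 + x2l2, d)
  o2 <- lm(y2 ~ x1l1 + x1l2 + x2l1 + x2l2, d)
  expect_equal(unname(f$coef[, 1]),
               unname(coef(o1)[c("(Intercept)", "x1l1", "x1l2", "x2l1", "x2l2")]),
               tolerance = 1e-10)
  expect_equal(unname(f$coef[, 2]),
               unname(coef(o2)[c("(Intercept)", "x1l1", "x1l2", "x2l1", "x2l2")]),
               tolerance = 1e-10)
  expect_equal(f$rss[2], sum(resid(o2)^2), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("VAR estimates are consistent at large n", {
  set.seed(2)
  A <- matrix(c(0.5, 0, 0.2, 0.4), 2, byrow = TRUE)
  f <- fit_var_multitrial(list(sim_var1(1e5, A)), 1)
  expect_lt(max(abs(f$A[[1]] - A)), 0.02)
})

test_that("white-noise coefficients stay within 3 standard errors", {
  set.seed(3)
  ok <- 0L
  for (s in 1:100) {
    trials <- list(matrix(rnorm(1000), 500, 2), matrix(rnorm(1000), 500, 2))
    f <- fit_var_multitrial(trials, 1)
    lag_rows <- 2:3
    if (all(abs(f$coef[lag_rows, ]) < 3 * f$se[lag_rows, ])) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("order selection is exact against a log-likelihood oracle and consistent", {
  set.seed(4)
  A <- matrix(c(0.4, 0.1, 0.2, 0.3), 2, byrow = TRUE)
  trials <- list(sim_var1(800, A))
  sel <- select_order(trials, p_max = 4)
  # oracle: exact Gaussian log-density of the residuals, enumerated per row
  for (p in 1:4) {
    d <- cholspeed:::var_design(trials, p, skip = 4)
    B <- qr.coef(qr(d$X), d$Y)
    res <- d$Y - d$X %*% B
    n <- nrow(res)
    S <- crossprod(res) / n
    Sinv <- solve(S)
    ll <- -0.5 * sum(apply(res, 1, function(r)
      2 * log(2 * pi) + log(det(S)) + drop(r %*% Sinv %*% r)))
    expect_equal(sel$logLik[p], ll, tolerance = 1e-9 * abs(ll))
  }
  expect_equal(select_order(trials, p_max = 1)$p, 1L)

  # strong VAR(3) is identified at moderate n
  hit <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 10000; burn <- 300
    x <- matrix(0, n + burn, 2)
    e <- matrix(rnorm(2 * (n + burn)), ncol = 2)
    A1 <- matrix(c(0.3, 0, 0.1, 0.3), 2, byrow = TRUE)
    A3 <- matrix(c(-0.35, 0.15, 0.1, -0.3), 2, byrow = TRUE)
    for (t in 4:(n + burn)) {
      x[t, ] <- A1 %*% x[t - 1, ] + A3 %*% x[t - 3, ] + e[t, ]
    }
    sel3 <- select_order(list(x[(burn + 1):(burn + n), ]), p_max = 6)
    if (sel3$p == 3L) hit <- hit + 1L
  }
  expect_gte(hit, 16L)
})

test_that("GC magnitude matches a brute-force two-regression oracle", {
  set.seed(5)
  A <- matrix(c(0.5, 0, 0.3, 0.5), 2, byrow = TRUE) # x drives y
  x <- sim_var1(2e5, A)
  g <- gc_magnitude(list(x), 1, "1->2")
  # oracle: restricted and full regressions via lm on explicit lags
  d <- data.frame(y = x[-1, 2], yl = x[-nrow(x), 2], xl = x[-nrow(x), 1])
  rss_r <- sum(resid(lm(y ~ yl, d))^2)
  rss_f <- sum(resid(lm(y ~ yl + xl, d))^2)
  oracle <- log(rss_r / rss_f)
  expect_lt(abs(g$gc - oracle) / oracle, 0.05)
  expect_lt(g$p_value, 1e-10)
  # the uncoupled direction is near zero with a large p-value
  g0 <- gc_magnitude(list(x), 1, "2->1")
  expect_lt(g0$gc, 5e-5)
  expect_gt(g0$p_value, 1e-4)
})

test_that("GC significance follows the chi-squared likelihood-ratio form", {
  expect_equal(gc_significance(0, 1000, 5), 1)
  q <- qchisq(0.95, 9)
  expect_equal(gc_significance(q / 9000, 9000, 9), 0.05, tolerance = 1e-9)
  # agreement with an F-test variant at large n
  set.seed(6)
  x <- sim_var1(6000, matrix(c(0.5, 0, 0.12, 0.5), 2, byrow = TRUE))
  p <- 3
  f <- fit_var_multitrial(list(x), p)
  g <- gc_magnitude(list(x), p, "1->2", fit = f)
  d <- cholspeed:::var_design(list(x), p)
  own <- c(1L, 1L + p + seq_len(p))
  rss_r <- sum(resid(lm.fit(d$X[, own], d$Y[, 2]))^2)
  rss_f <- f$rss[2]
  df2 <- f$n_eff - (2 * p + 1)
  Fstat <- ((rss_r - rss_f) / p) / (rss_f / df2)
  p_f <- pf(Fstat, p, df2, lower.tail = FALSE)
  expect_lt(abs(g$p_value - p_f) / p_f, 0.1)
})

test_that("GC is invariant to affine rescaling of each channel", {
  set.seed(7)
  x <- sim_var1(3000, matrix(c(0.5, 0.1, 0.3, 0.4), 2, byrow = TRUE))
  g0 <- gc_magnitude(list(x), 2, "1->2")$gc
  y <- cbind(5 * x[, 1] - 3, -0.2 * x[, 2] + 11)
  y <- sweep(y, 2, colMeans(y))
  g1 <- gc_magnitude(list(y), 2, "1->2")$gc
  expect_equal(g0, g1, tolerance = 1e-9)
})

test_that("GC shrinks toward zero as the coupling vanishes", {
  meds <- vapply(c(0.4, 0.15, 0), function(cpl) {
    median(vapply(1:20, function(s) {
      set.seed(1000 + s + round(cpl * 1e4))
      x <- sim_var1(2000, matrix(c(0.5, 0, cpl, 0.5), 2, byrow = TRUE))
      gc_magnitude(list(x), 2, "1->2")$gc
    }, 0))
  }, 0)
  expect_true(all(diff(meds) < 0))
})

test_that("reduced-model residual variance never undercuts the full model", {
  set.seed(8)
  for (s in 1:5) {
    x <- sim_var1(1500, matrix(c(0.4, 0.1, 0.1, 0.4), 2, byrow = TRUE))
    f <- fit_var_multitrial(list(x), 3)
    for (dir in c("1->2", "2->1")) {
      expect_gte(gc_magnitude(list(x), 3, dir, fit = f)$gc, 0)
    }
  }
})

test_that("per-animal GC reduces to single-trial GC and ignores session order", {
  cfg <- synth_config(session_duration = 120)
  co <- simulate_latent_cohort(cfg, 1, 3, seed = 21)
  res <- per_mouse_gc(co, p = 4, minutes = 2, split_lighting = FALSE)
  one <- co[co$session_id == co$session_id[1], ]
  tr <- truncate_first_minutes(one, 2, 30)
  g <- gc_magnitude(list(tr), 4, "1->2")
  expect_equal(
    res$per_session$gc_nats[res$per_session$session_id == one$session_id[1] &
                              res$per_session$direction == "speed_to_ach"],
    g$gc, tolerance = 1e-12)

  co_perm <- co[order(match(co$session_id, rev(unique(co$session_id))),
                      co$frame), ]
  res2 <- per_mouse_gc(co_perm, p = 4, minutes = 2, split_lighting = FALSE)
  expect_equal(sort(res$per_animal$gc_nats), sort(res2$per_animal$gc_nats),
               tolerance = 1e-12)
})
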