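#' Simulate a semi-Markov behavioral state sequence
#'
#' Generates per-frame behavior labels (exploratory running/walking, grooming,
#' rearing, still) as a semi-Markov chain: bout states follow an embedded
#' Markov chain without self-transitions, and bout durations are lognormal
#' with state-specific medians. The embedded chain's transition law is solved
#' numerically so that the long-run fraction of *time* spent in each state
#' equals `config$occupancy_targets` while dwell distributions remain exactly
#' as configured.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A data.frame of class `behavior_labels` with columns `frame`
#'   (0-based), `time_s`, `state` (long label), and `community` (0 running,
#'   1 walking, 2 grooming, 3 rearing, 4 still).
#' @export
simulate_behavior <- function(config, seed = config$seed) {
  occ <- config$occupancy_targets
  active <- names(occ)[occ > 0]
  n_frames <- round(config$session_duration * config$frame_rate)
  fr <- config$frame_rate

  if (length(active) == 0L) stopf("no state has positive occupancy")
  if (length(active) == 1L) {
    short <- active
  } else {
    sdlog <- config$dwell_sdlog
    medians <- config$dwell_medians[active]
    mean_dwell <- medians * exp(sdlog^2 / 2)
    # embedded-chain stationary law proportional to occupancy / mean dwell
    w <- occ[active] / mean_dwell
    w <- w / sum(w)
    P <- solve_embedded_chain(w)
    short <- with_seed(seed, {
      states <- character(0)
      lens <- integer(0)
      total <- 0L
      cur <- sample(active, 1, prob = w)
      while (total < n_frames) {
        d <- stats::rlnorm(1, meanlog = log(medians[[cur]]), sdlog = sdlog)
        nf <- max(1L, as.integer(round(d * fr)))
        states <- c(states, cur)
        lens <- c(lens, nf)
        total <- total + nf
        cur <- sample(active, 1, prob = P[cur, ])
      }
      rep(states, lens)[seq_len(n_frames)]
    })
  }
  if (length(short) == 1L) short <- rep(short, n_frames)
  long <- names(STATE_SHORT)[match(short, STATE_SHORT)]
  out <- data.frame(
    frame = seq_len(n_frames) - 1L,
    time_s = (seq_len(n_frames) - 1L) / fr,
    state = long,
    community = STATE_COMMUNITY[short],
    row.names = NULL
  )
  class(out) <- c("behavior_labels", "data.frame")
  attr(out, "frame_rate") <- fr
  out
}

# Transition matrix of the embedded bout chain whose stationary distribution
# is w. Preferred form has no self-transitions (P(i -> j) = q_j / (1 - q_i),
# j != i), keeping observed bout durations exactly as configured; that form
# caps any single state's bout share at 1/2, so when w is infeasible (or for
# two-state configs, where alternation forces (1/2, 1/2)) the chain falls
# back to i.i.d. bout sampling with self-transitions allowed: occupancy is
# still exact by renewal-reward, but consecutive same-state bouts merge.
solve_embedded_chain <- function(w) {
  k <- length(w)
  nm <- names(w)
  iid_fallback <- function(msg) {
    warnf("%s; falling back to i.i.d. bout sampling (same-state bouts merge)",
          msg)
    matrix(rep(w, each = k), k, k, dimnames = list(nm, nm))
  }
  if (k == 2L) {
    if (max(abs(w - 0.5)) > 1e-9) {
      return(iid_fallback("two active states force alternating bouts"))
    }
    return(matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(nm, nm)))
  }
  if (max(w) >= 0.5 - 1e-9) {
    return(iid_fallback(sprintf(
      "bout share of state '%s' (%.2f) exceeds the 1/2 cap of a chain without self-transitions",
      nm[which.max(w)], max(w))))
  }
  q <- w
  make_P <- function(q) {
    P <- matrix(rep(q, each = k), k, k, dimnames = list(nm, nm))
    diag(P) <- 0
    P / rowSums(P)
  }
  stationary <- function(P) {
    # left eigenvector for eigenvalue 1
    A <- t(P) - diag(k)
    A[k, ] <- 1
    b <- c(rep(0, k - 1), 1)
    pi <- solve(A, b)
    pmax(pi, 1e-12) / sum(pmax(pi, 1e-12))
  }
  for (it in 1:400) {
    pi_hat <- stationary(make_P(q))
    err <- max(abs(pi_hat - w))
    if (err < 1e-10) break
    q <- q * (w / pi_hat)^0.7
    q <- pmin(pmax(q / sum(q), 1e-9), 1 - 1e-9)
  }
  if (err > 1e-6) {
    return(iid_fallback(sprintf("embedded-chain solver residual %.2g", err)))
  }
  make_P(q)
}

#' Run-length encode behavior labels into bouts
#'
#' @param labels A `behavior_labels` data.frame.
#' @return A data.frame with one row per bout: `state`, `start_frame`,
#'   `n_frames`, `duration_s`.
#' @export
behavior_bouts <- function(labels) {
  r <- rle(as.character(labels$state))
  fr <- attr(labels, "frame_rate") %||% 30
  ends <- cumsum(r$lengths)
  data.frame(
    state = r$values,
    start_frame = c(0L, ends[-length(ends)]),
    n_frames = r$lengths,
    duration_s = r$lengths / fr,
    row.names = NULL
  )
}
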