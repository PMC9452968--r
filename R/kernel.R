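#' Calcium-indicator impulse kernel
#'
#' Constructs a causal difference-of-exponentials kernel modeling the
#' fluorescence response of a slow calcium indicator (jGCaMP7s-like). The
#' kernel is parameterized by the rise time constant and the *measured*
#' half-decay time: the decay time constant is calibrated numerically so that
#' the post-peak half-time of the sampled impulse response equals
#' `half_decay` seconds. The kernel is normalized to unit DC gain, so constant
#' signals pass through unchanged.
#'
#' The sampled kernel is `k[n] = (a^n - b^n)/S` with `a = exp(-dt/tau_decay)`,
#' `b = exp(-dt/tau_rise)` and `S` the normalizing sum. Convolution with this
#' kernel is an exact second-order recursion (an ARMA filter), and the
#' recursion is invertible, which [kernel_deconvolve()] exploits to recover
#' the pre-indicator drive.
#'
#' @param rise_tau Rise time constant in seconds (default 0.2 s).
#' @param half_decay Measured half-decay time in seconds (jGCaMP7s: 1.69 s).
#' @param dt Sampling interval in seconds.
#' @return An object of class `calcium_kernel`.
#' @examples
#' k <- calcium_kernel(0.2, 1.69, 1 / 30)
#' h <- kernel_impulse(k, 300)
#' @export
calcium_kernel <- function(rise_tau = 0.2, half_decay = 1.69, dt = 1 / 30) {
  assert_scalar_num(rise_tau, "rise_tau", lower = 1e-6)
  assert_scalar_num(half_decay, "half_decay", lower = 1e-6)
  assert_scalar_num(dt, "dt", lower = 1e-9)
  if (half_decay <= rise_tau / 4) {
    stopf("half_decay (%g s) too short relative to rise_tau (%g s)", half_decay, rise_tau)
  }
  measure <- function(tau_d) {
    k <- kernel_raw(tau_d, rise_tau, dt, n = ceiling((half_decay * 12 + 6 * rise_tau) / dt))
    measured_half_decay(k, dt)
  }
  # Half-decay grows monotonically with the decay constant; bracket and solve.
  lo <- half_decay / log(2) * 0.2
  hi <- half_decay / log(2) * 3 + rise_tau
  tau_decay <- stats::uniroot(function(td) measure(td) - half_decay,
                              lower = lo, upper = hi, tol = dt / 100)$root
  a <- exp(-dt / tau_decay)
  b <- exp(-dt / rise_tau)
  structure(
    list(rise_tau = rise_tau, half_decay = half_decay, tau_decay = tau_decay,
         dt = dt, a = a, b = b, gain = (1 - a) * (1 - b)),
    class = "calcium_kernel"
  )
}

kernel_raw <- function(tau_d, tau_r, dt, n) {
  a <- exp(-dt / tau_d)
  b <- exp(-dt / tau_r)
  a^(0:(n - 1)) - b^(0:(n - 1))
}

# Post-peak half-time of a sampled impulse response, linearly interpolated.
measured_half_decay <- function(k, dt) {
  ip <- which.max(k)
  peak <- k[ip]
  after <- k[ip:length(k)]
  below <- which(after <= peak / 2)
  if (length(below) == 0L) return(Inf)
  i2 <- below[1]
  if (i2 == 1L) return(0)
  # linear interpolation between samples i2-1 and i2
  k1 <- after[i2 - 1]; k2 <- after[i2]
  frac <- (k1 - peak / 2) / (k1 - k2)
  (i2 - 2 + frac) * dt
}

#' Sampled impulse response of a calcium kernel
#'
#' @param kernel A [calcium_kernel()].
#' @param n Number of samples.
#' @return Numeric vector of length `n` summing to (approximately) one for
#'   large `n`.
#' @export
kernel_impulse <- function(kernel, n) {
  k <- kernel$a^(0:(n - 1)) - kernel$b^(0:(n - 1))
  S <- kernel$a / (1 - kernel$a) - kernel$b / (1 - kernel$b)
  k / S
}

#' Convolve a signal with a calcium kernel
#'
#' Exact from-rest convolution with the unit-DC-gain kernel, implemented as a
#' second-order recursive filter (no truncation error). Because the kernel's
#' first sample is zero (continuous rise), the first output sample is always
#' zero.
#'
#' @param kernel A [calcium_kernel()] sampled at the signal's rate.
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
kernel_convolve <- function(kernel, x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  v <- kernel$gain * c(0, x[-n])
  as.numeric(stats::filter(v, c(kernel$a + kernel$b, -kernel$a * kernel$b),
                           method = "recursive"))
}

#' Invert the calcium-kernel convolution
#'
#' Recovers `x` from `y = kernel_convolve(kernel, x)` by applying the exact
#' inverse of the kernel's ARMA recursion. The final sample is not identified
#' by a from-rest convolution (the kernel delays by one sample) and is held at
#' the previous value; `kernel_convolve(kernel, kernel_deconvolve(kernel, y))`
#' reproduces `y` exactly from the second sample onward.
#'
#' @inheritParams kernel_convolve
#' @param y Numeric signal (kernel-filtered).
#' @return The deconvolved signal, same length as `y`.
#' @export
kernel_deconvolve <- function(kernel, y) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  yl1 <- c(0, y[-n]) # y[t-1], from rest
  # x[t] = (y[t+1] - (a+b) y[t] + ab y[t-1]) / gain, t = 1..n-1
  x <- (c(y[-1], NA) - (kernel$a + kernel$b) * y + kernel$a * kernel$b * yl1) /
    kernel$gain
  x[n] <- if (n >= 2L) x[n - 1] else y[1] / kernel$gain
  x
}

#' @export
print.calcium_kernel <- function(x, ...) {
  cat(sprintf(
    "<calcium_kernel> rise tau %.3g s, half-decay %.3g s (decay tau %.3g s), dt %.4g s\n",
    x$rise_tau, x$half_decay, x$tau_decay, x$dt))
  invisible(x)
}
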