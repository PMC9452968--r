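---
title: "Methods: models, generator design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generator design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the statistical
models it implements, what the synthetic-data generator does and does not
emulate, the numerical choices behind each stage, and the limits of what
passing tests demonstrate.

## The scientific setting

Cholinergic projection neurons in the medial septum / diagonal band of Broca
(MSDB) broadly modulate hippocampal circuits. Fiber photometry of a slow
calcium indicator (jGCaMP7s, half-decay ≈ 1.69 s) expressed in these neurons
yields a bulk activity trace whose relationship to the animal's movement is
the object of study: the activity is approximately *linear in the logarithm*
of neck movement speed, the relationship persists during stationary behavior
(neck speeds below 3 cm/s), is insensitive to lighting, carries a rearing
offset beyond what speed predicts, and aligns with speed on a time scale of
about a second. The package implements the full analysis chain and a
generator that reproduces the statistical structure those analyses assume,
with known ground truth.

## Photometry correction

The raw 500 Hz channels are the calcium-dependent signal `s` (473 nm
excitation) and the isosbestic control `c` (405 nm), both contaminated by
exponential photobleaching and shared motion artifacts. The correction
follows four steps: (1) resample both channels to the 30 Hz TTL frame clock
by averaging samples within each frame window `[t_i, t_{i+1})` — a mean, not
a decimation, so high-frequency sensor noise is attenuated and the result is
exact with respect to the TTL clock; (2) fit a 2nd-degree polynomial to
`d = s − c` against time and add it to `c`, aligning the control's slow trend
with the signal channel (the regressor is centered and scaled purely for
conditioning); (3) find the closed-form least-squares `(α, β)` minimizing
`Σ (s − (cα + β))²` — no iterative optimizer is needed because the problem is
linear; (4) ΔF/F = `(s − (cα+β)) / (cα+β)`, z-scored per session (n−1
denominator).

Numerical guards: the ΔF/F denominator must stay away from zero; frames with
`|cα+β| ≤ 1e-6 × median |cα+β|` raise an error naming the frames. A control
with zero variance is rejected before the `(α, β)` step.

Because the baseline has only three slow degrees of freedom per session, a
small fraction of genuinely slow signal is absorbed by the polynomial — on
5-minute synthetic sessions with realistic bout structure this removes about
1–2% of the signal variance, and the speed-coefficient attenuation it causes
is of the same order (the paired estimate in development was −0.001 ± 0.004
in slope units). Z-scoring per session was adopted over pooled z-scoring: the
session is the natural unit of signal strength (fiber placement, expression
level), and the mixed models include session effects that absorb the
remaining differences.

## Kinematics

Neck speed is the frame-to-frame displacement of the tracked neck point times
the frame rate, with the first frame copying the second. Frames whose
tracking likelihood falls below 0.9 are linearly interpolated (edges held).
No temporal smoothing is applied by default — the tracking jitter the
generator emulates is sub-pixel — but a 3-frame median filter is available
behind a flag. The `log₂` transform uses a floor of ε = 0.25 cm/s, roughly
the speed equivalent of one pixel of jitter at 30 Hz; below the floor the
transform is constant, above it strictly monotone. A session counts as
stationary-dominated when *strictly more* than two thirds of its frames are
below 3 cm/s.

## Tuning curves and fits

Scatter data are decimated to one frame nearest each whole second (the single
nearest frame, not a 1-s mean, so the scatter reflects instantaneous
activity). Tuning curves use half-open bins `[kw, (k+1)w)` — a value exactly
on an edge joins the upper bin — with means reported only for bins holding at
least 5 points. The saturating exponential `z = y∞ − A e^(−v/τ)` is fitted by
Levenberg–Marquardt with multi-start over τ ∈ {1, 5, 20} cm/s and the
best-SSE converged fit kept; the log-linear model is ordinary least squares
with the Pearson correlation reported alongside (a zero-variance response
returns r = 0 with a warning, by convention). Cohort curves average
session-level bin means (mean ± s.e.m. across sessions), not pooled frames:
session is the exchangeable unit.

## Integration-window scan

The moving average is a centered odd-width boxcar with shrinking edges.
Centered (rather than causal) smoothing was chosen because the question is
correlational — which integration width best aligns the activity with log
speed — not predictive; this is an assumption, recorded here, since the
analysis convention is not dictated by the data. Only the activity is
smoothed; speed is left untouched. The scan grid runs from one frame to 10 s
in one-frame steps, ties resolve to the smallest window, and the light/dark
comparison uses a pooled-variance t-test at the 1.3 s reference window plus a
two-sample Kolmogorov–Smirnov test on the per-session optima.

## Granger causality

Sessions are truncated to their first 5 minutes (shorter sessions are used
whole, with a warning) and mean-centered per trial, so sessions are
comparable as trials; an animal's sessions enter one stacked OLS estimate of
a bivariate VAR with no lag leakage across trial boundaries. The GC magnitude
is `ln(RSS_reduced / RSS_full)` for the target equation, reduced meaning
own-lags-only, both fitted on identical samples — so the statistic is
non-negative by construction up to round-off (clipped at zero). Order
selection minimizes AIC computed from the exact Gaussian log-likelihood on a
common effective sample (every candidate order discards the first `p_max`
frames of each trial); `p_max = 30` (≈ 1 s at 30 Hz) by default. Significance
uses the likelihood-ratio form `n·F ~ χ²(p)`; several asymptotically
equivalent tests exist, and one is fixed for determinism. Stationarity is the
user's responsibility; detrending is performed, unit-root testing is not.

## Mixed-effects models

Four designs are provided. The speed model regresses z-ΔF/F on an intercept,
`log₂(speed)`, and the `log₂(speed) × darkness` interaction, with
*uncorrelated* random effects on all three terms for animal and for session —
uncorrelated because the published covariance-parameter counts (7 for this
model: six variances plus the residual) identify a variance-only structure.
The stationary variant is the same design on the filtered subset. The GC
model regresses per-session GC magnitudes on direction, darkness and their
interaction with the same style of random structure (9 covariance
parameters). The behavior model adds community indicators (exploratory
running, rearing, grooming; exploratory walking is the reference, as the
published table lists the other three) with random intercepts for animal,
session, darkness level and community — exactly the intercept terms its
printed formula lists. That structure is deliberately confounded: the fixed
darkness and community dummies lie in the span of the corresponding random
intercepts, and `lme4`'s sparse factorization occasionally rejects it
("Downdated VtV is not positive definite"). When that happens the fit is
retried with the identifiable animal/session intercepts only, with a warning;
the confounded components are estimated at (numerically) zero whenever the
full structure does converge, so the fixed effects are unaffected.

Fitting is REML via `lme4`, with inference by residual-degree-of-freedom
t-tests (`df = n − p`): the published degrees of freedom in the millions
identify residual-DF inference, and Satterthwaite/Kenward–Roger corrections
are deliberately out of scope. Singular fits (variance components at zero)
warn rather than fail — with per-session z-scoring the intercept variances
are legitimately near zero. For frame-level data sets beyond ~100k rows the
optimizer is warm-started from a fit on a systematically thinned subsample;
this changes only the iteration count, not the optimum (verified in tests
against perturbation probes of the REML criterion).

Two caveats follow from per-session z-scoring. First, the *intercept* of the
speed model is not recoverable: centering removes each session's mean, so the
fitted intercept converges to `−β₁·E[log₂ speed]` regardless of the
generative β₀. Recovery claims therefore concern slopes and offsets
(within-session contrasts), which centering leaves intact. Second, residuals
are strongly autocorrelated at 30 Hz; the random session slopes absorb the
resulting extra between-session dispersion, which is why interval coverage
remains calibrated even though the residual model is i.i.d.

## The synthetic-data generator

**Behavior.** A semi-Markov chain over five states (exploratory running and
walking, grooming, rearing, still) with lognormal dwell times (sdlog 0.5;
medians 4, 1.5, 4, 2, 3 s). Default occupancies are the published open-field
time budgets (70.4% running, 26.2% walking, 1.4% grooming, 2.1% rearing,
normalized; still 0). The embedded bout chain has no self-transitions and its
transition law is solved numerically so the long-run *time* fractions equal
the targets while dwell distributions stay exactly as configured; a chain
without self-transitions cannot give any state more than half of the bouts,
so infeasible targets (and two-state configurations) fall back to i.i.d.
bout sampling, which preserves occupancy exactly but merges consecutive
same-state bouts (a warning says so). The run-dwell median of 4 s was chosen
to keep the default targets feasible and is within the range of observed
running-bout durations in open-field mice.

**Locomotion.** Within a bout, speed follows a reflected Ornstein–Uhlenbeck
process inside the state's speed range (run 8–25, walk 3–8, stationary states
0–2.5 cm/s; mean-reversion time 1 s); heading random-walks and reflects off
the 40 × 40 cm walls. The written pose track adds Gaussian jitter (SD
0.01 cm — sub-pixel, consistent with the 0.25 cm/s log floor) and ~1%
low-likelihood frames whose coordinates are additionally corrupted, emulating
markerless-tracking dropouts. Rearing is simulated as low planar speed with a
positive latent offset: vertical motion is invisible to an overhead camera.

**Latent signal.** The latent trace, in z-units, is
`β₀ + β_speed·log₂(max(v, ε)) + β_run·I[run] + β_rear·I[rear] +
β_groom·I[groom] + β_dark·I[dark] + β_darkslope·I[dark]·log₂(...) + AR(1)`,
with animal and session random intercepts/slopes (SDs 0.05/0.03 and
0.05/0.02 — the animal-slope SD of 0.03 corresponds to ~14% between-animal
variability in speed tuning, a realistic figure for this kind of recording).
Two design choices matter here:

* *The regressor is the tracking-derived speed*, computed from the written
  pose track with the same interpolation the analysis side uses. Published
  coefficients are defined with respect to measured kinematics; driving the
  latent with the measured speed makes them embeddable as recoverable truth
  and avoids errors-in-variables attenuation that would otherwise bias every
  recovery study.
* *The AR(1) noise SD defaults to the complement of the realized drive
  variance*, so each session's total latent variance is 1. The response
  analyzed everywhere is per-session z-scored ΔF/F; a unit-variance latent
  makes z-scoring approximately the identity, so coefficients keep their
  z-scale meaning. An explicit `noise$sd` overrides this.

**Indicator kinetics.** The kernel is a causal difference of exponentials
with rise τ = 0.2 s (a typical fast-rise figure for this indicator family;
the decay is what the literature reports, so the rise is a free parameter,
exposed in the config) and a decay constant *calibrated numerically* so the
sampled impulse response's post-peak half-time equals the configured 1.69 s.
Convolution is implemented as the kernel's exact second-order recursion — no
truncation — and the recursion is inverted exactly for deconvolution.

The generator defines the regression structure at the *measured* ΔF/F level:
the deterministic drive appears in the rendered ΔF/F unchanged (its
pre-kernel form is obtained by exact inverse filtering, so the identity
"true ΔF/F = kernel ∗ pre-kernel latent" holds to machine precision), while
the AR(1) noise is injected before the kernel and therefore carries the
indicator's temporal signature. This mirrors the physical situation: the
published coefficients describe the indicator-filtered signal, and the
underlying cholinergic drive is faster than what the indicator shows. Had the
coefficients been placed strictly before the kernel, convolution would
attenuate every measured-level slope by tens of percent (the speed
autocorrelation time is comparable to the kernel width) and no recovery
study could succeed.

The compensated mode is the default and is used wherever printed
coefficients serve as recoverable truth. It deliberately removes the
indicator's signature from the speed-locked component, so it is the *wrong*
mode for studying kinetics: there, `compensate_kernel = FALSE` renders the
physical forward model (the whole latent convolved with the kernel), the
measured trace's smoothness is set by the half-decay, and the
integration-window analysis behaves as matched filtering — a slower
indicator yields a longer optimal averaging window. That ordinal property
(medians over 20 seeds of roughly 4, 5 and 6 s for half-decays of 0.5, 1.69
and 3 s under the default noise budget) is what the acceptance checks
assert; the absolute optima are larger than in real recordings because the
synthetic noise budget is dominated by its indicator-filtered component.

**Channels.** `F470 = B·e^(−t/τ_b)·(1 + ΔF/F) + m(t) + noise` and
`F405 = B'·e^(−t/τ_b')+ γ·m(t) + noise`, with single-exponential bleaching
per channel (τ = 1200/1500 s, so bleaching is visible but not dominant within
a 5–15 min session), sensor noise SD 0.004 a.u. per 500 Hz sample, and
`m(t)` a Poisson train (2/min) of exponentially decaying transients (decay
0.3 s, channel gain γ = 0.8) shared across channels — the isosbestic channel
sees artifacts but no calcium. ΔF/F amplitude is 5% per z-unit. Lighting
affects nothing by default (`beta_dark = 0`), matching the null finding it
emulates; nonzero values are available for power studies.

**What the generator does not emulate:** lock-in carrier modulation
(demodulated channels are simulated directly), hemodynamic contamination,
slow drift in tracking calibration, theta-band or ripple structure in the
latent, non-exponential bleaching, and state-dependent artifact rates.
Passing recovery tests therefore shows the *pipeline* is correct and
calibrated under these assumptions — not that real recordings satisfy them.

## Problem sizes used in the automated checks

The recovery targets refit the speed model on 10 replicate cohorts of
5 animals × 10 sessions × 5 min at 30 Hz (450,000 frames per cohort) through
the full pipeline; the stationary variant uses 16 stationary-dominated
sessions over 3 animals; the behavior model uses 3 animals × 6 sessions
(both at 5 min, 10 replicates), matching the published cohort shapes (16
stationary sessions from 3 mice; 3 mice in the behavior analysis). The
behavior-model replicates are drawn as antithetic pairs — identical
behavior, trajectory and random effects with negated AR(1) noise — because
the rearing and grooming contrasts ride on rare states with autocorrelated
residuals; pairing cancels the noise contribution to the (linear) estimator
to first order and shrinks the Monte-Carlo spread of the replicate mean
about ninefold without touching the generating conditions. Interval
coverage is assessed on 100 latent-level replicates of 6 animals ×
4 sessions × 60 s: coverage under residual-DF t inference is governed by the
number of grouping levels, and with very few animals the `t` vs normal
quantile mismatch alone dominates, so the calibration check uses more, shorter
sessions to measure the procedure rather than that small-sample artifact.
Other checks (signal recovery, window ordering, Granger calibration) state
their sizes in the test code; they were chosen as the smallest sizes at which
the corresponding asymptotic statements are expected to hold with margin.

## Known limitations

* The intercepts of z-scored-response models are not recoverable (see above);
  the package reports them but recovery claims exclude them.
* The GC magnitudes of the study itself are not reproducible from synthetic
  data — the published numbers depend on unreleased recordings — so the
  Granger stage is validated by calibration (null rejection rate, long-run
  consistency against brute-force regression) and by the directional
  asymmetry the generator's physics implies (speed → ACh exceeding the
  reverse), not by matching magnitudes.
* Two-state behavior configurations cannot hit arbitrary occupancy targets
  (bout alternation fixes the bout-level law); the generator warns and
  preserves occupancy via the i.i.d. fallback at the cost of merged bouts.
* `lme4` occasionally reports singular fits on small cohorts; this is
  expected (true zero variance components after centering) and surfaced as a
  warning, not hidden.
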