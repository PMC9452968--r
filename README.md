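# cholspeed

Analysis of cholinergic population activity versus movement speed in freely
behaving mice, from dual-channel fiber photometry and markerless pose
tracking — with a ground-truth synthetic-data generator for validating every
stage.

## Who this is for

Labs recording bulk calcium signals (e.g. jGCaMP7s in cholinergic neurons of
the medial septum / diagonal band of Broca) with an isosbestic 405 nm control
channel, alongside 30 Hz video tracking of the animal. The package turns raw
recordings into frame-aligned, z-scored ΔF/F, quantifies how that signal
relates to the *logarithm* of neck movement speed, and asks how fast the
relationship is and which way the information flows.

## What it computes

* **Photometry correction.** Channels are resampled to the TTL video-frame
  clock; a 2nd-degree polynomial fitted to `s − c` adjusts the control for
  bleaching mismatch; `(α, β)` minimizing `Σ (s − (cα + β))²` scale the
  control onto the signal; ΔF/F = `(s − (cα+β)) / (cα+β)`; z-scoring within
  session makes signals comparable across sessions.
* **Kinematics.** Allocentric neck speed from pose tracks (`‖Δr‖·frame rate`),
  a floored `log₂` transform, a 3 cm/s stationary mask, and a strict
  two-thirds stationary-session filter.
* **Tuning.** 1-s-interval scatter sampling, binned tuning curves
  (mean ± s.e.m.), saturating-exponential fits `z = y∞ − A·e^(−v/τ)` and
  log-linear fits `z = β₀ + β₁·log₂ v`.
* **Temporal dynamics.** Correlation between the moving-averaged activity and
  log speed as a function of the window length; per-session optimal
  integration windows; pooled-variance t and Kolmogorov–Smirnov comparisons
  between lighting conditions.
* **Granger causality.** Multi-trial bivariate VAR by stacked OLS (sessions
  of one animal are trials), AIC order selection, GC magnitude
  `ln(σ²_reduced/σ²_full)` in both directions with χ² likelihood-ratio
  p-values — implemented from first principles and cross-checked against
  brute-force regressions in the tests.
* **Mixed models.** The four linear mixed-effects analyses (speed × darkness,
  its stationary-subset variant, GC direction × lighting, and
  speed + darkness + behavioral community), fitted by REML with residual-DF
  t inference, plus parameter-recovery studies.
* **Synthetic data.** Semi-Markov open-field behavior with target
  occupancies, bounded mean-reverting locomotion, a log-speed-driven latent
  cholinergic signal with AR(1) noise, calcium-indicator kinetics with a
  calibrated 1.69 s half-decay, exponential photobleaching, shared motion
  artifacts, and DeepLabCut-dialect pose files — all reproducible from a
  seed, with ground truth retained.

## Worked example

```r
library(cholspeed)

cfg  <- synth_config(session_duration = 300)  # one 5-min synthetic session
sess <- simulate_session(cfg, seed = 11)
al   <- process_session(sess, epsilon = cfg$speed_floor)

# how well did the isosbestic correction recover the true signal?
cor(al$dff, sess$truth$dff_true_frames)
#> [1] 0.9924

# log-linear speed tuning from 1-s samples
ss <- sample_interval(al, 1)
fit_linear_log(ss$logspeed, ss$zdff)$slope
#> [1] 0.1899

# optimal integration window of an indicator-filtered activity trace
k  <- calcium_kernel(rise_tau = 0.2, half_decay = 1.69, dt = 1/30)
set.seed(1)
z  <- kernel_convolve(k, al$logspeed) + rnorm(nrow(al), 0, 1.5)
ws <- window_scan(z, al$logspeed, frame_rate = 30)
ws$optimal_window
#> [1] 4.066667
```

The correlation shows the bleaching/artifact correction recovering the
ground-truth ΔF/F (≥ 0.9 at default SNR). The slope is this session's
estimate of the speed coefficient in z-units per log₂(cm/s) — the generator's
default truth is 0.221, and single-session estimates scatter around it
(across-session averages recover it; see the recovery studies). The last
block smooths an indicator-filtered trace at increasing window lengths and
reports the window maximizing the correlation with log speed — the optimum
grows with the indicator's half-decay, which is how the integration-window
analysis reads out the kinetics.

End-to-end, `simulate_cohort()` writes a cohort to disk and `run_pipeline()`
reproduces the whole analysis (preprocessing, tuning, dynamics, Granger,
mixed models) into a results directory with provenance sidecars.

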