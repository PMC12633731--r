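---
title: "Quantifying pectoral fin muscle function across gaits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pectoral fin muscle function across gaits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finmotor)
```

## The scientific problem

Amphibious fishes such as *Polypterus senegalus* swim with smooth pectoral
fin oscillations and walk by planting a fin and vaulting the body over it.
The same four fin muscle groups — abductor (Abd), adductor (Add),
coracometapterygialis (Cmt) and zonopropterygialis (Zpt) — power both
gaits, so quantifying how their activation timing, duration and intensity
change between water and land speaks directly to how terrestrial loading
could drive the muscle-fibre remodelling seen after long-term exposure to
land. `finmotor` implements that quantification as a reusable, testable
pipeline: EMG burst analysis, stroke-cycle kinematics with polar event
timing, a circular-statistics decision tree, mixed-effects comparison
tables, and an Evans Blue dye fluorescence analysis for muscle-membrane
permeability. A synthetic-data generator with exact ground truth makes
every stage verifiable without any recordings.

## Stroke cycles and the polar timing convention

A stroke cycle is annotated by three times: `t_start` (start of the
propulsive phase — adduction in swimming, stance in walking), `t_mid`
(start of recovery — abduction or swing) and `t_end`. Event times are
mapped onto a stroke circle by `to_polar_timing()` with a
*phase-normalized* convention: propulsion maps linearly onto
[0°, 180°) and recovery onto [180°, 360°), so the recovery
start is pinned at 180° regardless of the propulsion fraction of that
particular cycle. This is the convention under which minimum fin adduction
lands "just after the start of propulsion" and maximum adduction "just
after the start of recovery" at consistent angles across cycles of varying
duty cycle; a raw time-fraction mapping is available via
`mapping = "time"` for sensitivity checks.

## Kinematic variables

From 500 frames s⁻¹ trajectories of four landmarks (nose tip, caudal fin
tip, pectoral fin tip, pectoral fin base), `cycle_kinematics()` computes
per cycle:

* **Speed over ground** — 3D path length of the nose divided by elapsed
  time (BL s⁻¹). Whether the horizontal projection should be used instead
  is genuinely ambiguous for a fish pitching on land; the 3D path is the
  default and `use_z = FALSE` exposes the projection.
* **Swing distances** — x–y path length of the caudal and pectoral fin
  tips over the cycle (and the nose, for walking only).
* **Fin elevation** max/min/range from the vertical coordinate of the fin
  tip, with extreme timings on the stroke circle.
* **Adduction angle** — the oriented planar angle at the fin-base vertex
  between the nose tip and fin tip, unwrapped to a continuous scale so
  sweeps past the body axis read above 180°. The sign convention follows
  the right-handed x–y frame; data digitized with mirrored handedness give
  the reflected angle (360° − θ), which the analyst should flip before
  analysis. Ties among extrema resolve to the first occurrence with a
  warning.
* **Angular velocity summaries** — central differences of the adduction
  angle, unsmoothed by default (an optional low-pass is deliberately off
  because no smoothing rule is part of the published procedure). Negative
  samples pool as abduction and positive as adduction; the mean of the top
  5% of magnitudes per sign class is the "maximum" and the top 20% the
  "routine" velocity. An empty sign class reports `NA`, never zero.

Missing frames inside a cycle raise an error rather than being silently
interpolated; interpolation, where wanted, is the caller's explicit step.

## EMG processing

Each channel (10 kHz) passes through, in order:

1. **Centering** (`center_signal()`): subtract the mean over a declared
   quiet window (≥ 50 ms) so the trace fluctuates about zero.
2. **Band-pass 40–4000 Hz** (`bandpass_filter()`): a linear-phase
   1024-tap FIR (Hamming), applied with group-delay compensation so the
   output is zero-phase. Pass-band loss at 500 Hz is < 0.1 dB;
   10 Hz and 4500 Hz tones are attenuated by > 50 dB.
3. **Wavelet empirical-Bayes denoising** (`denoise_emg()`): periodized
   sym4 DWT to depth `min(floor(log2 n) − 4, 10)`; per detail level the
   noise scale is the rescaled MAD, and coefficients are shrunk by the
   posterior mean under a spike-and-slab prior (point mass at zero plus a
   Laplace slab, scale 0.5) whose mixing weight is estimated per level by
   marginal maximum likelihood. Approximation coefficients are untouched.
4. **Moving RMS envelope** (`rms_envelope()`): centred 400-sample (40 ms)
   window, truncated at the record edges.
5. **Burst detection** (`detect_bursts()`): maximal runs of the envelope
   above 25% of its whole-record mean. Using the whole-record mean (not a
   per-cycle mean) makes the threshold a property of the channel; the
   per-cycle alternative is exposed through the `threshold` argument.
6. **Rate filter** (`rate_filter()`): a muscle cannot switch on and off
   above 100 Hz, i.e. a full on–off cycle lasts at least 10 ms. Gaps
   shorter than 10 ms are merged *first*, then bursts shorter than 10 ms
   are dropped; the order matters (merging first preserves fragmented
   long bursts) and both thresholds are arguments. The filter is
   idempotent.

Burst metrics are computed from the centred band-passed signal — the
denoised signal serves detection only. Per cycle and per scope (full
cycle, propulsion, recovery), with bursts clipped at scope boundaries:
activation duration; duty factor (% of scope); amplitude (mean of the top
5% of rectified samples pooled across the scope's bursts); and RIA, the
rectified integrated area as a percentage of its theoretical maximum
(channel maximum amplitude × active duration, summed over bursts rather
than averaged per burst so cycle-cumulative values stay within [0, 100]).

**Normalization.** Amplitudes are expressed relative to the highest
amplitude recorded on that fish × muscle channel across all trials and
both behaviours. The channel maximum is taken over the same scope-level
pooled amplitude quantity being normalized: a clipped burst fragment can
have a higher top-5% mean than any complete burst, so normalizing pooled
scope amplitudes against per-burst maxima would occasionally exceed 100%.
With the self-consistent maximum, every percentage lies in [0, 100] and
exactly one scope per channel attains 100.

Integrals use the trapezoid rule on the closed sample window, so a
constant-amplitude burst at the channel maximum yields RIA = 100% and
amplitude = 100% exactly.

## Circular statistics and the decision tree

Event timings on the stroke circle are summarized by the angular mean,
mean resultant length $\bar R$, angular variance $1-\bar R$ (unit free),
angular deviation $\sqrt{2(1-\bar R)}$ in degrees (the convention used for
"mean ± variance"-style reporting — both quantities are returned since
published tables rarely state which is printed), and the large-sample
circular standard error $1/\sqrt{n \bar R \hat\kappa}$.

`timing_decision_tree()` routes each analysis:

1. **Shape**: Kuiper goodness-of-fit of the sample against a von Mises
   distribution with ML-fitted parameters. Because parameters are fitted,
   the null distribution is obtained by parametric bootstrap (500
   replicates by default, refitting within each replicate). A numerically
   one-point sample is flagged degenerate: the fit is unusable, uniformity
   is rejected by construction.
2. **Uniformity**: Rayleigh's test ($z = n\bar R^2$, asymptotic series)
   when the von Mises shape holds; otherwise the Hermans–Rasson test
   (pairwise-difference statistic, Monte-Carlo null at the observed n —
   10 000 replicates by default, and a precomputed shared null can be
   supplied for calibration studies).
3. **Two-sample comparison**, run only when *both* samples are
   non-uniform (an event with no consistent timing in one gait has no mean
   to compare): Watson–Williams (F with the $1+3/(8\hat\kappa)$
   correction) when both samples are von Mises and both $\bar R > 0.45$;
   otherwise the non-parametric Watson U² (asymptotic series p for
   n ≥ 8, permutation below). The 0.45 cutoff is applied per sample —
   both must exceed it — since the concentration assumption must hold in
   each group.

Every routing decision is recorded in a `selection_trace` so runs are
auditable.

## Mixed-effects tables

Linear variables are compared with linear mixed-effects models (REML, via
`nlme`) with a random intercept per fish — the individual is the unit of
replication, cycles are repeated measures. Kinematic models have behaviour
as the fixed effect; EMG models have behaviour × muscle (the interaction
is included by default because phase-specific reversals between gaits are
the phenomenon of interest; burst-count-style variables can be fitted
without it). "Correction for unequal variance" is available as
`varIdent` per-group residual weights through the `weights` argument; no
automatic selection is performed — the choice is the analyst's and is
visible in the fit object.

`anova_table()` reports marginal F tests with nlme's containment
denominator degrees of freedom, plus marginal and conditional R² from the
variance decomposition ($R^2_m$ uses fixed-effect variance only; $R^2_c$
adds the intercept variance). `emmeans_table()` gives estimated marginal
means with balanced reference weights (equal to arithmetic means under
balance, to machine precision), and `pairwise_bonferroni()` multiplies raw
contrast p-values by the family size, defaulting to all contrasts computed
for the variable (e.g. 6 muscle pairs × 2 behaviours = 12), capped at 1.
If a mixed fit fails, the wrapper falls back to a fixed-effects model with
fish as a blocking factor and flags it — never a silent degradation.

The Evans Blue analysis subtracts the per-section background from each
cell intensity (negative values are legitimate — a cell darker than the
background — and are not clipped), fits per size class
`intensity ~ pct_fin_length + treatment` (interaction optional), and
reports Cohen's d per muscle.

## The synthetic-data generator

`gait_sim_config()` encodes the study conditions: 4 fish, 10 cycles per
fish and behaviour; swimming cycles 0.25 ± 0.03 s and walking cycles
0.60 ± 0.08 s (walking strokes are roughly twice as long as swimming
strokes at comparable duty factors); adduction angle oscillating about
187° ± 11° (swimming) and 178.5° ± 31.5° (walking); fin elevation
amplitudes of 0.0065 and 0.0125 BL; speeds near 0.55 BL s⁻¹. Burst
schedules place each muscle's onset/offset at its characteristic stroke
angle, with the walking adductor firing three bursts per cycle (it
contracts in trains through stance and swing). The propulsion fraction is
0.5 for both behaviours, which makes the phase-polar mapping coincide with
the raw-time mapping and keeps scheduled phases interpretable on both
scales.

EMG is baseline Gaussian noise (sd 0.1 V) plus bursts of 40–4000 Hz
band-limited noise under a trapezoidal envelope (5 ms rise/fall) — the
interference-pattern shape of real EMG in the analysis band — with
occasional sub-40 Hz movement artifacts (0.2 s⁻¹). Burst timing jitter is
drawn von Mises on the cycle circle (κ = 8, ≈ 23° circular sd) so
circular-statistics ground truth is exact by construction. Trajectories
are generated directly in body-length units as sinusoids of the cycle
phase, so per-cycle extrema and their timings have closed forms; path
lengths and speed are integrated from the analytic curves by fine
quadrature. The adduction angle is constructed exactly as the oriented
angle the pipeline measures, so recovery is exact up to frame sampling.

What the generator does *not* emulate: electrode cross-talk, amplifier
drift, digitization error and occlusion gaps, non-sinusoidal fin paths,
inter-cycle kinematic correlation, and burst-amplitude modulation within a
burst. Green tests therefore certify the computational pipeline — that
every derived variable measures what it claims on signals whose truth is
known — not robustness to every pathology of real recordings.

## Numerical choices and degenerate inputs

* Integration windows are closed sample intervals (`floor(t·fs)+1` on
  both ends), making phase metrics additive at `t_mid` and constant
  signals exact.
* Detection onsets/offsets are reported at threshold-crossing samples;
  accuracy is limited by the 40 ms RMS window (≈ half-window boundary
  blur), which is why the acceptance checks use a ±20 ms criterion.
* The Hermans–Rasson constant 2.895 follows the modern form of the
  statistic; since p-values come from its own Monte-Carlo null, the test
  is exactly calibrated by construction.
* Watson U² p-values use the alternating exponential series truncated at
  200 terms, clamped to [0, 1].
* `a1inv` (the inverse of $A_1(\kappa)$) uses the standard three-branch
  approximation.
* All-zero envelopes yield empty burst lists; scopes without bursts
  report zero duration/count and missing amplitude/RIA; antipodal angle
  pairs give $\bar R = 0$ with an undefined (NA) mean.
* Every simulator call is deterministic given its config and seed; trial
  seeds are derived from the study seed, fish and behaviour, and kept
  below 2³¹.

## Problem sizes used in the test and acceptance suites

Simulation-backed checks are sized to be decisive yet quick as a
package-development suite: burst recovery uses 100 cycles at SNR 5
(≈ 200 bursts); circular-test calibration uses 2000 uniform samples per
condition with a shared 2000-replicate Monte-Carlo null; the mixed-model
recovery study uses 500 replicates of the 4-fish design; decision-tree
conformance uses 50 constructed cases. These sizes give Monte-Carlo
standard errors comfortably inside the asserted bands (e.g. ±0.5% on a
95% coverage estimate at 500 replicates).

## Known limitations

* The Kuiper bootstrap is the slowest element (each replicate refits and
  re-evaluates the von Mises CDF); for large batch analyses the replicate
  count is the knob to turn.
* Containment degrees of freedom are the only denominator-df method
  offered for the ANOVA tables; Satterthwaite-style approximations would
  require a different modelling backend.
* The polar mapping assumes annotated cycles; automatic cycle detection
  from trajectories is out of scope by design (cycle events are defined
  behaviourally, e.g. fin loading, and are annotated upstream).
* Angular-variance conventions differ across the literature; both the
  unit-free `ang_var` and the degree-scaled `ang_dev_deg` are returned,
  and reports should state which is printed.
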