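# finmotor

Quantifying how pectoral fin muscles change their function between
swimming and walking in amphibious fishes.

When a fish such as *Polypterus senegalus* leaves the water it keeps using
the same four pectoral fin muscle groups — abductor (Abd), adductor (Add),
coracometapterygialis (Cmt) and zonopropterygialis (Zpt) — but under
gravity instead of buoyancy. `finmotor` is the analysis pipeline for
asking, cycle by cycle, what changes: how long and how hard each muscle is
active, when in the stroke it turns on and off, how fin kinematics differ,
and whether a bout of walking leaves measurable muscle-membrane damage.
It is written for comparative biomechanists working with synchronized
EMG (10 kHz) and 3D landmark trajectories (500 frames s⁻¹), plus
cell-level fluorescence tables from Evans Blue dye assays.

## What it computes

* **EMG burst analysis** — baseline centering on a quiet window,
  zero-phase 40–4000 Hz FIR band-pass, wavelet empirical-Bayes denoising
  (periodized sym4, level-dependent noise, posterior-mean shrinkage),
  moving-RMS envelope (400 samples = 40 ms), burst onsets/offsets at 25%
  of the envelope mean, and a 100 Hz physiological on/off rate filter
  (merge gaps < 10 ms, then drop bursts < 10 ms).
* **Normalized burst metrics** per cycle and per phase (full cycle,
  propulsion, recovery): activation duration (s), duty factor (%),
  maximum amplitude (mean of top 5% of rectified samples, % of the
  channel maximum), and RIA — rectified integrated area as % of its
  theoretical maximum (channel max amplitude × active time).
* **Stroke-cycle kinematics** — speed over ground, caudal/pectoral/nose
  swing distances, fin elevation extremes, the continuous (unwrappable
  past 180°) fin adduction angle, and top-5%/top-20% angular velocity
  summaries; all event timings in polar coordinates on the stroke circle
  (propulsion start = 0°, recovery start = 180°).
* **Circular statistics decision tree** — Kuiper test against a fitted
  von Mises (parametric bootstrap); Rayleigh or Hermans–Rasson
  uniformity tests; Watson–Williams (when von Mises and mean resultant
  length R̄ > 0.45 in both samples) or Watson U² for
  swimming-vs-walking timing comparisons, run only when both gaits show
  consistent timing.
* **Mixed-effects tables** — `nlme` fits with a random intercept per
  fish, ANOVA-type F tables with containment df and marginal/conditional
  R², estimated marginal means ± s.e.m. (`emmeans`), and
  Bonferroni-corrected pairwise contrasts.
* **Evans Blue analysis** — background-subtracted cell intensities,
  per-size-class linear models `intensity ~ %fin length + treatment`,
  Cohen's d per muscle.
* **Synthetic-data generator** — EMG, trajectories, nested study tables
  and fluorescence tables with exact ground truth, so the entire pipeline
  is testable end to end without recordings.

## Worked example

Simulate one fish swimming, run the EMG pipeline on its abductor channel,
and summarize the first cycle:

```r
library(finmotor)
cfg <- gait_sim_config(n_fish = 1, cycles_per_fish = 4, seed = 42)
tr  <- simulate_trial(cfg, fish = 1, behaviour = "swimming")

p <- process_channel(tr$channels$Abd)
p$bursts
#>   onset_s offset_s duration_s amp_top5   ria_raw
#> 1  0.6137   0.7835     0.1698 2.239856 0.1038787
#> 2  0.8555   1.0168     0.1613 2.259109 0.1002338
#> 3  1.0855   1.2959     0.2104 2.236523 0.1398218
#> 4  1.4128   1.5965     0.1837 2.229121 0.1194649
```

Four bursts were detected, one per stroke cycle; the first true
(scheduled) burst ran 0.632–0.766 s, so both detected boundaries are
within the ±20 ms accuracy set by the 40 ms RMS window. Summaries per cycle and phase,
normalized against the channel maximum:

```r
cs  <- emg_cycle_summary(p, tr$cycles)
cs$summary <- normalize_emg_summary(cs$summary, channel_normalization(cs$summary$amp_raw))
subset(cs$summary, cycle == 1, c(scope, duty_factor_pct, ria_pct, amp_pct, n_bursts))
#>        scope duty_factor_pct   ria_pct  amp_pct n_bursts
#> 1 full_cycle       54.415813 28.445755 96.92790        1
#> 2 propulsion        8.831626  2.939859  9.25345        1
#> 3   recovery      100.000000 30.698341 98.38520        1
```

The abductor is scheduled to fire from mid-propulsion through recovery
(onset at 179° on the stroke circle), so in this cycle it is active for
the whole recovery phase but barely during propulsion — the same
asymmetry the comparison tables then test across gaits and muscles. The full workflow over all fish, gaits,
muscles and analyses is in `analysis/01_simulate.R` …
`analysis/06_evans_blue.R`; each script prints what it found and writes
its tables under `results/`. Running `analysis/03_emg.R`, for example,
reports perfect burst recall on the default study
(`Detection recall against scheduled bursts: 1.000 (383/383)`) and mean
full-cycle RIA rising from ≈ 23% (swimming) to ≈ 30% (walking) in three
of four muscles.

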