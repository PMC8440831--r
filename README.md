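# spinemc

Reliability and uncertainty analysis of subject-specific spino-pelvic
kinematic models in R.

Image-based subject-specific spine models — 18 rigid bodies (pelvis/sacrum,
L5–L1, T12–T1) connected by 17 spherical intervertebral joints and tracked
through 28 virtual skin markers — make it possible to measure intervertebral
joint angles during functional motion in adult spinal deformity (ASD)
patients. Building such a model, however, requires manual operator input for
three components: virtual-marker positions, vertebral-body poses, and
intervertebral joint frames — 294 scalar parameters in total
(28×3 + 18×6 + 17×6). `spinemc` is for motion-analysis researchers who need
to know how much of a measured spinal kinematic signal is real and how much
is operator- or session-induced noise. It provides:

* **Kinematics pipeline** — zero-phase 4th-order Butterworth low-pass
  filtering (6 Hz), weighted least-squares marker-driven inverse kinematics
  over the 57 degrees of freedom (6 base + 51 joint angles, solved per frame
  with an analytic Jacobian and an adaptive Levenberg–Marquardt iteration),
  time normalization to 100 frames, three-frame moving-average smoothing,
  and extraction of the six sagittal spino-pelvic parameters — lumbar
  lordosis (LL), thoracic kyphosis (TK), sagittal vertical axis (SVA, cm),
  pelvic tilt (PT), and T1/T9 spino-pelvic inclination — plus their ranges
  of motion (ROM = |end − start|).
* **Reliability statistics** — ICC(2,1) (two-way random effects, absolute
  agreement, single measure) with McGraw–Wong 95% CI and p-value,
  SEM = SD·√(1−ICC), SDD = SEM·1.96·√2, and the conventional
  poor / fair-to-good / excellent classification.
* **Monte-Carlo uncertainty propagation** — operator deviations pooled over
  levels and subjects into 15 component × parameter × direction groups,
  Gaussian-kernel density estimates fitted to the signed deviations,
  perturbed models sampled and re-solved until a mean/SD convergence
  criterion is met, and the results summarized as 5–95% confidence bands,
  box statistics at the time of maximal variance (t<sub>σ=max</sub>), and a
  294 × 51 Pearson sensitivity-factor grid.
* **Synthetic-data generators** — plausible ASD spino-pelvic geometry,
  seated maximal trunk-flexion trials with known ground truth, operator
  variants with realistic deviation magnitudes, and test-retest session
  pairs with execution jitter, so the entire pipeline is testable without
  patient recordings.

File formats: TRC marker trajectories in, MOT/STO and CSV out, JSON model
files (versioned schema), YAML configuration, JSON run manifests. A thin
command-line wrapper is installed at `inst/cli/spinemc` with subcommands
`synth`, `ik`, `params`, `reliability`, `montecarlo`, `report`.

## Worked example

```r
library(spinemc)

## a synthetic ASD subject and a seated maximal flexion trial
gm <- generate_spine_model(geometry_params(lumbar_lordosis = 45), seed = 3)
tr <- generate_flexion_trial(gm$model, motion_spec(n_frames = 300), seed = 4)

## markers -> joint angles -> spino-pelvic parameters
pl <- run_pipeline(gm$model, tr$trial)
pl$spino_pelvic
#> <spino_pelvic_series> 100 frames
#>   ROM: LL 19.2 deg, TK 20.6 deg, SVA 38.1 cm, PT 50.0 deg,
#>        T1_SPI 72.0 deg, T9_SPI 63.5 deg

## three emulated operators -> baseline model -> perturbation distributions
ops  <- emulate_operators(gm$model, operator_variability_spec(), 3, seed = 11)
base <- average_models(ops)
pool <- pool_deviations(list(ops), list(base))
summarize_deviations(pool)$marker_3d
#>    median       max
#> 0.2442935 0.5471572      # mm, 3D virtual-marker displacement

## Monte-Carlo propagation of operator variability
res <- run_monte_carlo(base, fit_kde(pool), tr$trial,
                       mc_settings(max_iter = 300, seed = 42))
res
#> <monte_carlo_result> 100 iterations (converged at n = 100)
#>   mean 90%-CI width at t_sigma_max: 0.832 deg, max: 2.166 deg
```

The ROM line reads: over this flexion the lumbar spine loses ~19° of
lordosis while the pelvis tips ~50° forward — and the Monte-Carlo line says
that for 90% of probable operator-error combinations, re-creating the model
by a different operator changes an intervertebral joint-angle estimate by
less than a degree on average (about 2° for the most sensitive joint).

Reliability of repeated measurements is summarized per parameter:

```r
rel <- reliability_summary(list(LL = rom_table))  # subjects x sessions
rel[, c("icc", "sem", "sdd", "classification")]
```

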