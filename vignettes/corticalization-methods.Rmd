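---
title: "Methods: the corticalization index and its statistical workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the corticalization index and its statistical workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Peri-implant bone on standardized intraoral radiographs changes texture as it
remodels: trabecular bone is mid-gray, heterogeneous, with short runs of
equal optical density; corticalized bone is bright, homogeneous, with long
uniform runs; bone-loss defects and soft tissue are dark and homogeneous.
`cortindex` quantifies this with three classical radiomic features computed on
a prepared region of interest (ROI) and combines them into a single
corticalization index (CI). The package also provides the longitudinal
statistics used to relate CI to marginal bone loss (MBL), and a synthetic
generator standing in for clinical radiographs that are shared only on
request.

## ROI preparation

An ROI (measurement protocol: exactly 1500 pixels, placed at the implant neck
or in distant intact bone) is prepared in two steps:

1. **Intensity windowing.** Raw gray levels are windowed to `[μ − 3σ, μ + 3σ]`
   where μ and σ are the mean and sample standard deviation of the raw ROI
   pixels. This is the standard normalization of dental texture-analysis
   software; it removes exposure differences between films.
2. **Quantization.** The window is mapped linearly onto
   `Ng = 2^bits` levels (default 6 bits, 64 levels) and clipped:
   `level(x) = clamp(floor((x − lo)/(hi − lo) · Ng), 0, Ng − 1) + 1`.

The windowing makes every downstream feature *exactly* invariant under affine
rescaling of the raw data (`x → a·x + b`, `a > 0`), because the window
co-transforms with the data; the acceptance suite asserts bit-identical
levels across 1000 random transforms. A constant ROI (σ = 0) cannot be
windowed; it maps to level 1 everywhere and is flagged `degenerate` rather
than raising an error, so batch runs survive pathological ROIs. Its CI is
undefined (`NA` with a warning) since its difference entropy is zero.

Whether the first-order mean should be computed before or after windowing is
not fixed by convention. The default here is the quantized mean (all features
then describe one prepared ROI, and the CI is fully affine-invariant); a
`mean_od_on = "raw"` switch in `analyze_roi()` is provided for workflows that
want the raw-histogram mean.

## Features

With `p(i)` the normalized level histogram:

* **Mean optical density** `= Σ_i i·p(i)`, in `[1, Ng]`.
* **Difference entropy.** For a lattice offset (default spacing 5 px along
  0°, 45°, 90°, 135°, i.e. offsets `(0,5), (−5,5), (−5,0), (−5,−5)`), every
  ordered in-ROI pixel pair under `±offset` is tallied by absolute level
  difference `k`, giving the difference histogram `p_{x−y}(k)`. Then
  `DifEntr = −Σ_k p_{x−y}(k) log10 p_{x−y}(k)` with `0·log 0 := 0`. The
  common (base-10) logarithm is the convention of the source software, so
  values are bounded by `log10(Ng) ≈ 1.806`.
* **Long-run emphasis.** Maximal runs of equal level are enumerated along
  lines of each direction; with `p(i,k)` the count of runs of level `i` and
  length `k`, `LngREmph = Σ k²·p(i,k) / Σ p(i,k) ≥ 1`.

Second-order features are computed per direction and the **arithmetic mean of
the four primary values** is carried forward — the analysis is deliberately
non-directional. The diagonal spacing is 5 lattice steps per axis (Chebyshev
distance 5); ~5-pixel Euclidean diagonal spacing would be offsets of ±3/±4
and is *not* used. Pairs and runs are confined to the ROI mask: a pair or run
never bridges a non-ROI pixel, which matters for polygonal and mask ROIs.

The **corticalization index** is

> CI = mean optical density × LngREmph / DifEntr

(the verbal definition of its source: long ordered runs of dense bone in the
numerator, textural chaos in the denominator; the printed formula block of
the source article duplicates the run-length equation and is not usable as a
definition). CI is ≥ 0 and unitless; it is undefined when `DifEntr = 0`.

Implementation note: both matrix enumerations are vectorized R (shifted
sub-matrix differences; `rle` over direction lines concatenated with `NA`
separators). The test suite validates them against deliberately naive
pixel-walking enumerators, exhaustively over all `4^9` 3×3 images at
`Ng = 4` in all four directions.

## Synthetic data: what it emulates, and what not

`generate_texture_patch()` draws Gaussian white noise, smooths it to a target
autocorrelation `exp(−d²/(2ℓ²))`, standardizes empirically, scales to the
class mean/contrast, and adds i.i.d. sensor noise (SD 3) before 8-bit
quantization. Class defaults:

| class | ℓ (px) | mean | contrast SD |
|---|---|---|---|
| trabecular | 4 | 120 | 40 |
| cortical | 12 | 190 | 12 |
| soft tissue | 8 | 60 | 8 |

These defaults were chosen once to reproduce the qualitative ordering the
clinical material shows — cortical patches have lower difference entropy at
5-px spacing and higher CI than trabecular patches (the acceptance suite
requires the CI ordering in ≥ 95 of 100 paired seeds) — not any quantitative
texture measurement. Note that after μ ± 3σ normalization the mean optical
density is ≈ Ng/2 for any homogeneous patch, so discrimination rests on the
second-order features; this mirrors how the index behaves on normalized
clinical ROIs. The generator does not model radiographic physics (scatter,
beam hardening, projection geometry) or implant thread rendering, so a green
discrimination test establishes that the *pipeline* ranks ordered-bright
versus chaotic texture correctly, not that the defaults match any scanner.

`generate_study_frame()` composes a 476 × 620, 70 μm/px canvas (trabecular
background, soft-tissue crest band, tapered dark implant silhouette, 40-px
corticalized collar) and returns one 50 × 30 peri-implant ROI inside the
collar and one 30 × 50 distant reference ROI — both exactly 1500 px.

`generate_cohort()` simulates the longitudinal cohort. Its stated world
follows the published cohort-level summaries: CI marginals 200 ± 146 /
282 ± 182 / 261 ± 168 at baseline / 5 y / 10 y; MBL zero-fractions
0.867 / 0.544 / 0.444 with positive-component moments 1.93 ± 1.85 /
1.91 ± 1.26 / 2.67 ± 2.04 mm; CI–MBL population correlations 0 (baseline,
no association) / 0.11 / 0.12. Numerical choices:

* **Moment-matched truncation.** CI must be ≥ 0. Naively truncating a
  normal with the target moments inflates the mean by several percent, which
  would bias every "within 3 SE" recovery test. Instead the parent (mean, sd)
  is solved (via `optim` on closed-form truncated-normal moments from
  `truncnorm`) so the *truncated* distribution has the configured moments.
  The positive MBL component is generated the same way.
* **Nested onset.** One uniform draw per implant decides bone-loss onset
  against the per-timepoint zero fractions, so the affected set only grows
  over time — bone loss, once present, persists. Positive MBL values are
  floored at 0.01 mm so rounding cannot erase an onset.
* **Coupling.** The latent CI mean is `m + slope_t·(MBL − E[MBL])` plus
  signed covariate terms; `slope_t` is back-computed from the target
  correlation and the analytic zero-inflated MBL variance (the clinical
  source reports correlations, not slopes). Residual variance is reduced by
  the injected components so the marginal CI moments stay on target.
* **Covariates.** Age, height, weight, TSH, calcium and triglycerides are
  drawn at the published population moments; their CI effects default to
  ±15 CI units per covariate SD — after truncation-induced attenuation this
  yields weak correlations (|CC| ≈ 0.03–0.06) that reach significance only at
  cohort scale, matching the character of the published covariate table.
  Signs: age +, height −, weight −, TSH +, calcium −, triglycerides +.
* `design_ci_effects` can inject option-level CI shifts for
  injection-recovery experiments; the default is no design-feature effect,
  so flag rates on design tables are nominal (≈ α) under the null.

## Statistical workflow

* **Test selection** mimics the clinical analysis: Shapiro–Wilk per group
  and Bartlett homogeneity, each at α = 0.05; only if all pass is the
  mean-based test used (pooled-variance t-test / one-way ANOVA), otherwise
  the rank-based counterpart. The source calls the latter the "W-test"; it is
  implemented as the Wilcoxon family — rank-sum for independent groups,
  signed-rank for paired — with normal approximation and tie correction.
  Note the joint gate passes truly Gaussian data with probability ≈ 0.95³.
* **Degenerate ties.** When all pooled values are identical, the rank tests'
  normal approximation is 0/0; the package returns p = 1 (no evidence of a
  difference) explicitly.
* **H/L flags.** When p < α, the group with the highest median is flagged
  `H` and the lowest `L` — the reporting convention of the clinical
  design-feature tables. Flags are per-comparison (no multiplicity
  correction), as in the source; `adjust = "holm"` optionally corrects
  across a table's cells.
* **Regression** reports Pearson CC, `R² = 100·CC²` (in percent, so CC 0.11
  prints as 1.2% and CC 0.12 as 1.4%), slope, intercept and the two-sided
  slope p; constant inputs give a flagged-undefined result.
* **Timepoint comparisons** are paired on the implants observed at both
  timepoints when at least 3 complete pairs exist, unpaired otherwise. The
  clinical source does not state whether its comparisons were paired; this
  is a package decision, not a claim about the source.
* **Covariate relations** use Pearson correlation on available pairs
  (labelled direct/inverse/none at α); the source does not name its
  estimator.
* Missing values are dropped pairwise per analysis and every table cell
  carries its n.

## Reproducibility

All randomness flows from a single integer seed through `withr::with_seed`
(derived child seeds stay below 2³¹); no function touches the global RNG
state. `run_simulate() → run_analyze() → run_stats()` writes its effective
analysis parameters (bits, spacing, alphas, seed, n) as `#` metadata headers
into every table — but not file paths, so two runs of one seed in different
directories are byte-identical, which the acceptance suite checks with MD5
digests.

## Limitations

* CI "version 1" only; the bone-index family (BI, 1/BI) is out of scope, as
  are other Haralick/run-length features, wavelet or autoregressive features.
* No image registration between timepoints, DICOM handling, or scanner
  calibration; images are taken as delivered 8/16-bit rasters (PNG or PGM —
  no 16-bit TIFF writer is available in the supported stack).
* The cohort simulator reproduces marginal and first-order coupling
  structure, not patient-level clustering (implants share patients in real
  cohorts) nor informative dropout.
* The statistical layer deliberately mirrors a per-comparison p < 0.05
  clinical workflow; treat flagged tables as descriptive unless the Holm
  option is enabled.
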