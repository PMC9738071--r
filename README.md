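# cortindex

Radiomic analysis of peri-implant bone **corticalization** on intraoral
radiographs.

After a dental implant is functionally loaded, the trabecular (spongy) bone
around its neck often remodels into dense, cortical-like bone. On a
radiograph this *corticalization* appears as brighter, more homogeneous
texture with long uniform gray-level runs. Whether that transformation is
benign or a risk marker for marginal bone loss (MBL) is a live clinical
question, and answering it requires a reproducible way to quantify bone
texture on standardized radiographs and to relate it to longitudinal MBL.
`cortindex` provides that pipeline for imaging scientists and implantology
researchers:

1. **Texture core.** ROIs (protocol size 1500 px) are windowed to
   μ ± 3σ of their raw gray levels, quantized to `Ng = 2^6 = 64` optical
   density levels, and measured by three features (pair spacing `d = 5` px,
   averaged over the four directions 0°/45°/90°/135°):
   - mean optical density `Σ_i i·p(i)` (first order),
   - difference entropy `DifEntr = −Σ_k p_{x−y}(k)·log10 p_{x−y}(k)` of the
     co-occurrence difference histogram (high in heterogeneous cancellous
     bone),
   - long-run emphasis `LngREmph = Σ_{i,k} k²·p(i,k) / Σ_{i,k} p(i,k)` of the
     gray-level run-length matrix (high for thick radio-opaque structures).

   These combine into the **corticalization index**

   ```
   CI = mean optical density × LngREmph / DifEntr
   ```

2. **Synthetic data.** Clinical radiographs of this kind are shared on
   request only, so the package ships a generator for radiograph-like
   textures (trabecular / cortical / soft tissue as smoothed Gaussian
   fields), full 476 × 620 study frames with implant silhouette and ROI
   sidecars, and longitudinal cohorts with zero-inflated MBL and a weak
   positive CI–MBL coupling — with ground truth returned for recovery tests.

3. **Cohort statistics.** The clinical workflow: normality-gated test
   selection (Shapiro–Wilk + Bartlett → t/ANOVA, otherwise Wilcoxon/
   Kruskal–Wallis), simple regression reporting CC and R² (%), longitudinal
   CI/MBL summaries with paired timepoint comparisons, median design-feature
   tables with H/L significance flags, and MBL prevalence splits.

## Worked example

```r
library(cortindex)

# one synthetic study frame with its two protocol ROIs
fr <- generate_study_frame(seed = 1)
analyze_roi(fr$image, fr$rois$peri_implant)
#> <texture_features 'peri_seed1' (peri_implant, initial): n=1500,
#>   mean_od=32.426, DifEntr=1.2271, LngREmph=1.3212, CI=34.91>
analyze_roi(fr$image, fr$rois$reference)
#> <texture_features 'ref_seed1' (reference, initial): n=1500,
#>   mean_od=32.494, DifEntr=1.4317, LngREmph=1.3844, CI=31.42>
```

The peri-implant ROI sits in the corticalized collar: lower difference
entropy (more ordered texture) and a higher CI than the distant trabecular
reference — the direction reported clinically.

The full workflow is scripted under `analysis/` (each step writes its tables
to `results/`):

```sh
Rscript analysis/01_simulate.R          # frames + 500-implant cohort
Rscript analysis/02_texture_features.R  # per-ROI features and CI
Rscript analysis/03_cohort_stats.R      # longitudinal + group statistics
```

Step 3 prints, for the simulated cohort (seed 20260917):

```
longitudinal summary:
  initial  CI   197 +/- 141   MBL 0.33 +/- 1.10 mm   CI~MBL: CC = -0.00, R^2 = 0.0%, p = 0.957
  y5       CI   294 +/- 184   MBL 0.89 +/- 1.26 mm   CI~MBL: CC = 0.12, R^2 = 1.3%, p = 0.00933
  y10      CI   250 +/- 167   MBL 1.47 +/- 1.95 mm   CI~MBL: CC = 0.05, R^2 = 0.2%, p = 0.3
```

i.e. corticalization rises sharply over the first five years of loading and
stays elevated, MBL progresses throughout, and from year five on the two are
weakly, positively associated — the configured stated world recovered by the
statistical layer (the year-10 association is genuinely underpowered at
n = 500).

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package — simulating the fixture bundle, extracting features and
CI, and producing the statistical report — and writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness flows from `--seed`.
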