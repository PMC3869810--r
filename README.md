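# spleenDCE

Semi-quantitative spleen DCE-MRI analysis for liver fibrosis staging.

## What this package is for

Staging liver fibrosis (METAVIR 0–4) currently requires biopsy, but the
haemodynamic consequences of portal hypertension reach the spleen early:
splenic transit slows and perfused blood volume falls as fibrosis
progresses.  Dynamic contrast-enhanced (DCE) MRI of the spleen captures
this in the signal-intensity–time curve of the organ, summarised by four
semi-quantitative parameters:

- **TTP** — time to peak: from the first detectable enhancement to the
  maximum signal intensity SImax (seconds); lengthens with fibrosis;
- **PEI** — positive enhancement integral: the baseline-subtracted area
  under the curve from onset to the end of acquisition (a.u.), a blood-
  volume surrogate that falls with fibrosis;
- **MSI / MSD** — maximum slopes of increase / decrease of the
  peak-normalized enhancement curve (1/s), wash-in / wash-out rate
  surrogates.

The package is for imaging scientists who want to develop or validate this
kind of staging analysis end to end without animal data.  It provides:

1. **A synthetic generator with analytic ground truth** (`dce_synth`
   layer): a gamma-variate enhancement model with washout plateau
   (`EnhancementModel`, signal = `s_base + A·τ^α·e^{α(1−τ)}` up to the
   peak, blending to a plateau `(1−w)·A`), per-stage calibration to
   published group statistics (`calibrateModel`), 4D phantom rendering
   with a hilar-vessel tube, noise and frame jitter (`renderSeries`,
   NIfTI I/O), and a longitudinal cohort simulator with deaths and
   repeat-stage bookkeeping (`simulateCohort`).
2. **The curve-parameter engine** (`stc_params` layer): smoothing, onset
   detection (baseline + 3 SD sustained 2 frames), TTP/PEI/MSI/MSD
   estimators, ROI extraction with margin erosion and vessel exclusion,
   three-section spleen measurement (`measureSpleen`) and voxelwise
   parametric maps (`parametricMaps`).
3. **The staging statistics** (`fibro_stats` layer): Spearman stage
   correlation, grouped-stage Mann-Whitney tests (exact for this study's
   group sizes) with Bonferroni correction, ROC analysis with rank-method
   AUC and Youden-index cutoffs, ICC(A,1), Pearson intra-observer
   correlation, Cohen's kappa with the conventional agreement bands, and
   a one-call `stagingReport` / `runPipeline`.

## Worked example

Draw a cirrhotic-stage (stage 4) ground-truth model, render the phantom,
and measure it back:

```r
library(spleenDCE)

m <- calibrateModel(stage = 4, seed = 1)
m
#> EnhancementModel (gamma-variate with washout plateau)
#>   s_base 100, onset 10 s, true TTP 85.13 s, amplitude 66.23
#>   shape alpha 3, washout fraction 0.6 (plateau 26.49 above baseline)

analyticParams(m)        # the analytic truth
#> PerfusionParams
#>   TTP 85.13 s   PEI 3.63   MSI 5.136 /s   MSD 0.5529 /s
#>   onset 10 s, peak 95.13 s, SImax 166.2

series <- renderSeries(m)             # 12 sections x 40 frames = 480 images
measureSpleen(series)                 # full image-path estimate
#> PerfusionParams
#>   TTP 83.7 s   PEI 3.63   MSI 5.125 /s   MSD 0.4887 /s
#>   onset 10.8 s, peak 94.5 s, SImax 166.2
```

The estimated TTP (83.7 s) sits within one frame interval (2.7 s) of the
truth (85.1 s) — onset detection lands on the first enhanced frame, 10.8 s
— and PEI matches the truth to well under 2%.

Simulate the full longitudinal cohort and run the staging statistics:

```r
coh <- simulateCohort(seed = 1)       # 69 observations over 5 visits
stageGroupSizes(coh)                  # after repeat-stage exclusion
#> S0 S1 S2 S3 S4
#> 16 11 13 13 10

report <- stagingReport(coh)
report$correlations
#>  parameter    rho        p
#>        ttp  0.836 1.41e-17
#>        pei -0.654 6.19e-09
#>        msi -0.821 1.80e-16
#>        msd -0.821 1.87e-16

simulateRocAuc("ttp", split = 1, n_rep = 2000, seed = 1)
#> [1] 0.8629348
```

TTP rises and PEI falls with stage in this single simulated cohort, and
the replicate-averaged empirical AUC of TTP for detecting any fibrosis
(stage >= 1) is about 0.86.  `runPipeline(pipelineConfig(seed = 1), "out/")`
writes the cohort table, the full report (JSON + CSV) and a manifest that
reproduces every number.

A thin command-line wrapper with `simulate` / `extract` / `stats` / `run` /
`fixtures` subcommands is installed at `inst/scripts/spleendce.R`.

## Vignette

`vignettes/spleen-dce-staging.Rmd` documents the model and its
assumptions, the calibration and its two display scalings, the estimator
definitions and their invariances, the numerical bounds (discretization,
window truncation of late washouts), the statistical conventions, and the
known limitations of the synthetic conditions.
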