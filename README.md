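# ethoacc

Behaviour classification from animal-borne tri-axial accelerometers, with
tools for quantifying how tag placement and sampling frequency affect
classification quality — built around the study design used for captive sea
turtles, where loggers are glued to the first or third vertebral scute of the
carapace.

## What it does

Tri-axial accelerometers record surge/sway/heave acceleration (here `x`, `y`,
`z`, in g) at high frequency. After ground-truthing — matching the signal to
video-annotated behaviour bouts on a shared UTC clock — a supervised
classifier can turn raw acceleration into an ethogram. `ethoacc` implements
that pipeline end to end:

1. **Synthetic cohorts** (`simulate_cohort()`): seeded generation of labelled
   recordings with the statistical structure the analysis assumes — per-behaviour
   posture (pitch/roll of the gravity vector), sinusoidal limb-beat
   oscillation on the surge axis, per-individual amplitude variation,
   a tag-position effect (dynamic gain and added noise), semi-Markov bout
   sequences, and 8-bit quantisation at a ±2 g or ±4 g dynamic range.
2. **Ingestion** (`read_accel_csv()`, `read_annotation_csv()`,
   `align_labels()`): logger/annotation CSVs synchronised on UTC, with the
   first and last second of every bout trimmed to absorb synchronisation
   error.
3. **Windowing** (`segment()`, `resample()`): non-overlapping 1 s or 2 s
   single-behaviour windows, downsampled from 100 Hz to
   50/25/12/10/8/4/2 Hz by nearest-sample decimation.
4. **Summary metrics** (`compute_features()`): the standard 18 per-window
   metrics — per-axis mean/SD/min/max, ODBA (mean L1 norm of dynamic
   acceleration), VeDBA (mean L2 norm), and pitch/roll mean and SD in
   degrees.
5. **Classification** (`blocked_cv_tune()`, `evaluate()`): a random forest
   (via `ranger`) with rare-behaviour filtering (dropping behaviours seen in
   ≤ 3 individuals), a stratified 70/30 split, minority up-sampling applied
   strictly inside training folds, individual-blocked cross-validation (each
   fold holds out one animal) tuned on macro one-vs-rest AUC, and
   confusion-matrix evaluation (overall and per-class balanced accuracy).
   A provenance guard (`assert_no_leakage()`) proves no window — nor any
   up-sampled copy — of a held-out individual reaches a fold's training data.
6. **Comparison statistics** (`fit_beta_regression()`,
   `pairwise_contrasts()`, `fit_ols()`): a maximum-likelihood beta regression
   (logit mean link, constant precision φ on a log link, Smithson–Verkuilen
   boundary squeeze) for accuracies in (0, 1), Wald tests, and Tukey-adjusted
   pairwise contrasts of estimated marginal means.
7. **Drag utilities** (`drag_coefficient()`, `compare_drag()`): the drag
   coefficient `Cd = D / (0.5 ρ U² A)` and the position × velocity regression
   with pairwise position contrasts, applied to CFD solver outputs or
   synthetic stand-ins (`synth_drag_data()`).

The beta regression maximises the likelihood of `y_i ~ Beta(μ_i φ, (1−μ_i) φ)`
with `logit(μ_i) = x_iᵀβ`, by BFGS with analytic gradients and Newton
polishing; coefficient covariance is the inverse observed information.

## Worked example

```r
library(ethoacc)

cfg    <- cohort_config(seed = 42L)          # 8 individuals x 2 positions
cohort <- simulate_cohort(cfg)
res    <- run_pipeline(cohort, window_s = 2, freqs = c(100, 2), seed = 42L)
res
#> <pipeline_result> 4 grid cells
#>   position window_s freq_hz overall_accuracy min_balanced_accuracy   auc
#> 1   scute1        2     100            1.000                 1.000 1.000
#> 2   scute1        2       2            0.956                 0.915 0.994
#> 3   scute3        2     100            1.000                 1.000 1.000
#> 4   scute3        2       2            1.000                 1.000 1.000
```

Each row is one model: behaviours at the clean third-scute placement are
recovered perfectly at both 100 Hz and 2 Hz (the slow limb-beat frequencies
of a turtle sit far below even the 1 Hz Nyquist limit of 2 Hz sampling),
while the degraded first-scute placement — the generator's default attenuates
dynamic acceleration by half and adds 0.1 g of noise there — loses accuracy
once sampling is sparse. Stacking accuracy tables over a few seeds and
running `accuracy_comparison()` quantifies that position effect as a
logit-scale beta-regression coefficient with a Wald p-value; `compare_drag()`
does the analogous comparison for hydrodynamic cost.

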