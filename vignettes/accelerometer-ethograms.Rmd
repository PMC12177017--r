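---
title: "Accelerometer ethograms: simulation, classification, and placement comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerometer ethograms: simulation, classification, and placement comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethoacc)
```

## The problem

Animal-borne tri-axial accelerometers let us infer behaviour continuously
and without an observer effect, but two design choices shape everything
downstream: where the device sits on the animal, and how fast it samples.
For hard-shelled sea turtles the device is glued to the carapace, and the
first (anterior) versus third (mid-dorsal) vertebral scute represent the
extremes of placements used in practice. Placement affects both the quality
of the movement signal reaching the sensor and the hydrodynamic drag the
animal must overcome; sampling frequency trades classification detail
against battery and memory. `ethoacc` packages the full analysis needed to
study those trade-offs: a generative simulator of labelled recordings, the
windowing/feature/classification pipeline, and the comparison statistics.

## Signal model of the simulator

The simulator writes, for each behaviour bout, a tri-axial signal

\[ \mathbf{a}(t) = R(\theta, \rho)\,\mathbf{g} + A\,\sin(2\pi f t)\,\mathbf{e}_x + \boldsymbol\varepsilon(t), \]

where the axis convention is fixed once for the whole package: `x` = surge
(anterior), `y` = sway (left), `z` = heave (dorsal), so a level, motionless
animal reads (0, 0, 1) g. The components are:

* **Posture.** The gravity unit vector rotated by the behaviour's pitch
  \(\theta\) and roll \(\rho\): \((\sin\theta,\; \cos\theta\sin\rho,\;
  \cos\theta\cos\rho)\). Downstream, pitch is recovered as
  \(\operatorname{atan2}(a_x, \sqrt{a_y^2+a_z^2})\) and roll as
  \(\operatorname{atan2}(a_y, a_z)\), so a noise-free static window returns
  the configured angles exactly (up to quantisation).
* **Limb-beat oscillation.** A sinusoid of amplitude \(A\) (g) and frequency
  \(f\) (Hz) on the surge axis. Sea-turtle flipper beats are slow; every
  default behaviour uses \(f \le 1\) Hz, which is why 2 Hz sampling—whose
  Nyquist limit is 1 Hz—remains workable.
* **Noise.** Independent Gaussian noise per axis. No empirical noise
  spectrum is imposed; i.i.d. Gaussian is the simplest testable choice.
* **Tag-position effect.** A per-position gain on the *dynamic* component
  plus extra Gaussian noise. The gain deliberately leaves gravity untouched:
  a placement can attenuate the transmission of limb-driven vibration, but
  no placement changes the orientation signal. The default degrades the
  first scute (gain 0.5, +0.1 g noise) and leaves the third scute clean,
  which is the minimal mechanism reproducing the observed accuracy ordering.
* **Quantisation.** Values are snapped to the \(2^{b}\)-level grid spanning
  \(\pm r\) g and clipped, mimicking the logger's analogue-to-digital
  conversion (defaults: 8 bits, ±2 g; the error per sample is at most
  \(r/(2^b-1)\)).

Bout sequences follow a semi-Markov chain: the next behaviour is drawn
proportionally to a transition-weight row (zero diagonal), and bout length
is exponential with a per-behaviour mean, floored at a minimum of at least
3 s so every bout survives the one-second trimming. Bouts tile the recording
exactly. Between-individual variation multiplies oscillation amplitudes by a
lognormal factor. The two positions of one individual share the behaviour
sequence, the amplitude multiplier, *and* the base noise stream, so a null
position effect yields bit-identical traces — a deliberate design that turns
the position comparison into an exact paired experiment.

### The default ethogram

Five behaviours: `rest` (flat, motionless), `swim` (nose down 30°, 0.8 Hz
at 0.45 g), `slow_swim` (nose down 20°, 0.7 Hz at 0.12 g), `breathe` (nose
up 45°, 0.4 Hz), `scratch` (rolled 45°, 0.9 Hz). Four of the five have
clearly distinct postures; `swim`/`slow_swim` deliberately share a similar
posture and differ mainly in limb-beat amplitude. That pair is what makes
the placement comparison informative: halving the dynamic signal and adding
noise at the first scute blurs exactly the amplitude cue, so first-scute
accuracy drops measurably while remaining high — mirroring how a real
placement effect expresses itself through movement-driven, not
posture-driven, metrics.

### What the simulator does *not* emulate

Real recordings include behaviour-dependent non-sinusoidal waveforms,
autocorrelated sensor noise, clock drift, gliding and other wild-only
behaviours, depth/temperature covariates, and annotation error. Passing
tests on synthetic cohorts therefore demonstrate that the *pipeline* is
correct and that the comparison statistics detect effects of the configured
kind and size; they do not certify accuracy levels on real animals.

## Labelling, windowing, resampling

Annotated bouts are aligned to samples on UTC; the first and last second of
every bout is discarded (half-open interval \([start+1, stop-1)\)), so a
bout of \(L\) s at rate \(f\) contributes \(\mathrm{round}((L-2)f)\)
labelled samples and \(\lfloor (L-2)/w \rfloor\) windows of length \(w\).
Windows tile each labelled run from its start; trailing remainders are
dropped, and a behaviour whose bouts never reach 2 s simply has no 2 s
windows. Downsampling to 50/25/12/10/8/4/2 Hz picks, for each target time
\(t_0 + k/f_{target}\), the nearest native sample — no anti-alias filter —
preserving the logger's quantised values; non-integer ratios (100→12 Hz)
snap to within half a native step. The window count is fixed to
\(\mathrm{round}(w f_{target})\) so feature arrays have predictable length.

## The 18 summary metrics

Per axis: mean, SD (n−1 denominator), min, max (12 metrics). The static
component of a window is its per-axis mean — windows are at most 2 s,
matching the usual smoothing horizon for dynamic-body-acceleration work —
and the dynamic component is the remainder. ODBA is the mean L1 norm and
VeDBA the mean L2 norm of the dynamic component, whence
\(\mathrm{VeDBA} \le \mathrm{ODBA} \le \sqrt{3}\,\mathrm{VeDBA}\) on every
window. Pitch and roll are computed per sample (degrees) and summarised by
mean and SD (4 posture metrics). The metric set is the package's canonical
default; `build_feature_table()` emits them in a stable column order.

## Classification protocol

Behaviours observed in three or fewer individuals are excluded before
modelling, keeping the cross-validation design well-posed. Rows are split
70/30 stratified by behaviour (individuals may appear in both sets — the
comparative design pools animals; individual-disjoint validation is exactly
what the blocked CV provides). Within the training set, folds are
individuals: for each candidate `mtry`, each animal is held out in turn, the
forest (up to 1000 trees, impurity importance) is fitted on the remaining
animals with minority behaviours up-sampled to the majority count *inside
the fold only*, and macro one-vs-rest AUC is scored on the held-out animal
(classes absent from the animal are skipped). The best mean-AUC `mtry` wins,
ties to the smallest value; the final forest is refitted on the full
up-sampled training set. Up-sampled copies keep row and individual
provenance, and `assert_no_leakage()` fails loudly if any copy of a held-out
animal's data reaches a fold's training rows. Evaluation reports the
confusion matrix, overall accuracy, per-class balanced accuracy
((sensitivity + specificity)/2, one-vs-rest), and macro AUC.

## Comparison statistics

Accuracies live in (0, 1), so position/frequency effects are modelled by a
beta regression fitted by maximum likelihood:
\(y_i \sim \mathrm{Beta}(\mu_i\phi, (1-\mu_i)\phi)\),
\(\mathrm{logit}(\mu_i) = x_i^\top\beta\), with a single precision
\(\phi = e^\gamma\) (no dispersion covariates). Boundary observations are
squeezed by \(y' = (y(n-1)+0.5)/n\) before fitting. Optimisation is BFGS
with analytic gradients from a logit-scale least-squares start, then Newton
steps until the score norm falls below 1e−6; the covariance is the inverse
observed information, and non-convergence is flagged, never silent. Wald
tests use \(Z = \hat\beta/\mathrm{SE}\). Post-hoc pairwise contrasts average
link-scale predictions over the levels of the other factors (numeric
covariates at their means), take delta-method SEs, and adjust p-values by
the studentised range (Tukey) within the factor family — with residual
degrees of freedom for least-squares fits and the asymptotic case for beta
fits. Contrast estimates are reported on the link scale and close cycles
exactly: \((a-b)+(b-c)+(c-a)=0\).

The drag module evaluates \(C_d = D/(0.5\rho U^2 A)\) (sea-water density
1028 kg m⁻³ by default; frontal area must always be supplied) and compares
positions by `Cd ~ Position × Velocity` least squares over the standard
0.2–1.2 m s⁻¹ velocity grid, with Tukey-adjusted position contrasts. CFD is
consumed, never run: inputs are solver-output CSVs or the synthetic
stand-in `synth_drag_data()`, whose default intercepts (bare carapace ≈
0.02, tagged ≈ 0.05–0.06, ordered none < third scute < first scute) emulate
the magnitudes typical of carapace-only simulations.

## Numerical choices and degenerate inputs

* Timestamps are UTC seconds in doubles; step-uniformity checks allow 2 µs
  of jitter because the ulp of an epoch-scale double is ~0.24 µs.
* Labelling uses half-open intervals with a 1 µs guard so adjacent bouts
  never share a sample and grid-aligned counts are exact.
* `sd` uses the unbiased n−1 denominator; single-sample windows are
  rejected.
* Ties in `mtry` selection resolve to the smallest (parsimony); forests run
  single-threaded with recorded seeds, so identical seeds give identical
  accuracy tables.
* Perfectly separable contrast designs (zero residual variance) report a
  zero statistic with p = 1 rather than 0/0.
* All randomness flows through explicit integer seeds; derived seeds stay
  below 2³¹.

## Problem sizes used by the test-suite and acceptance runs

Cohorts of 8 individuals × 2 positions × 360 s at 100 Hz (about 1.2 M
samples per cohort, ~1300 two-second windows per position) for end-to-end
checks; 4-individual, 120–180 s cohorts for unit-level checks; 200
replicates of n = 2000 for beta-regression coverage (200 replicates rather
than fewer so the Monte-Carlo error of the measured coverage proportion is
about 1.5 %); blocked-CV tuning over `mtry` ∈ {2, 4, 6} with 1000 trees.
These sizes make every statistical check stable under its stated
threshold while completing quickly on a single CPU.

## Known limitations

* The 18-metric list is the package's canonical set; supplements of
  individual studies sometimes swap in spectral or depth-derived metrics,
  which are out of scope here.
* The beta regression models fixed effects only; repeated measures across
  individuals are handled by the blocked CV design, not by random effects.
* Nearest-sample decimation (no low-pass filter) is faithful to common
  logger practice but aliases energy above the target Nyquist; with slow
  behaviours this is immaterial, for fast-moving species it would not be.
* Synthetic cohorts cannot validate absolute accuracy on real turtles; they
  validate pipeline correctness and the direction/detectability of
  configured effects.
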