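---
title: "Decoding speech production from sparse-sampled fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding speech production from sparse-sampled fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The experimental setting

`speechmvpa` analyzes slow event-related, sparse-sampled fMRI of overt
speech production. The design it models: volumes are acquired with TR = 2 s,
each TR containing a 900 ms silent gap during which the participant speaks
(so articulation happens without scanner noise and with reduced motion
artifact); trials arrive every 16 s and each trial comprises three
utterances of one item separated by one TR (a 6 s production block); items
come from a 2 x 5 condition inventory — task (voiced, whispered) crossed
with item (`bb`, `dd`, `mm`, `nn`, `schwa`) — balanced within each of 4
runs. The scientific questions are where articulatory (lip vs tongue, oral
vs nasal) and phonatory (voiced vs whispered) gestures are discriminable
from multivoxel activity, and which regions share trial-by-trial response
gain with primary-motor seed regions.

Because no public dataset accompanies this design, the package is organized
around a synthetic-data generator that plants known effects. Every
downstream stage is validated by recovering what was planted.

# The synthetic generator

`generate_experiment()` composes, per voxel and volume:

* a constant baseline (100);
* slow drift: Legendre polynomials of order 1..5 per run with i.i.d.
  Gaussian coefficients (`drift_sd`, default 2) — the same family the
  nuisance model removes;
* a global respiratory component over gray matter: each trial onset
  triggers a kernel whose peak latency is configurable (`resp_peak_s`,
  default 8 s) with a shallow late undershoot, scaled by `resp_amp`
  (default 1.5). This emulates the inhalation-locked global signal change
  that a trial-locked gray-matter average recovers as a respiratory
  impulse-response proxy;
* task-evoked responses: a 6 s boxcar per trial convolved with the
  canonical double-gamma HRF, unit peak, amplitude `evoked_amp` in all ROI
  voxels;
* optional planted multivoxel patterns: a fixed voxel-weight vector inside
  one ROI whose sign follows the trial's class under a named contrast
  (`pattern_type = "multivoxel"` uses random +/- weights, invisible to
  univariate contrasts; `"uniform"` is univariately visible);
* optional trial-gain coupling: a shared standard-normal per-trial gain
  added to a seed ROI and a remote ROI, creating genuine beta-series
  connectivity;
* i.i.d. Gaussian noise (`noise_sd`, default 1).

Motion parameters are a slow random walk (SD 0.01 per step) with a
configurable fraction of spike volumes whose derivative norm exceeds the
0.4 mm censoring threshold. Physiological traces (1000 Hz by default, with
TR triggers) show an inhalation peak ~0.4 s after the trial cue — before
articulation onset — an exhalation during production, and chin-pressure
deflections inside each silent gap; voiced and whispered trials are
generated from the identical model, so the two conditions are exchangeable
by construction (the matched-respiration premise). Utterance audio is an
all-pole synthesis: two resonators at item-specific frequencies excited by
a 120 Hz pulse train (voiced, amplitude 1) or white noise (whispered,
amplitude 0.08, F1 raised 15%); the resonance frequencies are stored as
ground truth for the formant estimator.

**Effect-size calibration.** The planted amplitude is computed so that the
realized per-voxel Cohen's *d* of the *single-trial feature* equals the
requested `effect_size`. Since the feature is a fixed linear functional
$\phi$ of the 9-lag epoch, its noise SD is $\sigma\lVert\phi\rVert$ and the
class separation from amplitude $a$ is $2a\,(\phi\cdot s)$ with $s$ the
unit trial-response epoch, giving $a = d\,\sigma\lVert\phi\rVert / (2\,
\phi\cdot s)$. Tests confirm the realized *d* to within Monte-Carlo error.

**What the generator does not emulate**: spatially correlated
(vascular/physiological) noise, anatomically realistic geometry, subject
motion that actually displaces voxels, or inter-subject variability in HRF
shape and pattern layout (pattern weights are shared across subjects on the
common grid). Passing tests therefore demonstrate correctness of the
estimation machinery under the stated noise model, not performance on real
tissue.

# Single-trial features (beta series)

Following the modeled procedure, MVPA features are computed from the
residuals of a *nuisance-only* GLM — Legendre polynomials 0..5 per run, the
6 motion parameters, and one indicator column per censored volume (volumes
whose motion-derivative Euclidean norm strictly exceeds 0.4 mm; the first
volume of a run is never flagged). Indicator-column censoring keeps the
residual grid aligned to the TR grid. The full GLM (adding one
HRF-convolved regressor per condition type) supplies condition betas for
univariate contrasts; ordinary least squares is used throughout, with rank
deficiency reported as an error naming the collinear columns.

Per trial, the 16 s epoch is sampled at 9 TR-grid lags (0, 2, ..., 16 s).
The source description gives both "16 s epochs" and "9 time points", which
only agree if both endpoints are included; we take the 9-sample convention,
accepting that lag 16 coincides with the next trial's onset volume (where
the next response is still negligible given HRF delay). Each epoch is
demeaned and detrended for a linear slope, then summarized to one scalar:
the mean over lags 4–10 s, the HRF peak window (how an epoch becomes one
feature is not stated in the source; the full 9-lag vector remains
available via `feature = "vector"`). Trials whose epoch contains more than
1/3 censored volumes, or runs past the run end, are dropped and reported.

# ROI decoding with recursive feature elimination

The classifier is a linear nu-SVM (libsvm via e1071). The described "5%
KKT" regularization — the fraction of trials allowed to violate the margin
during training — is not a standard C parameterization, so it is
implemented as the nu budget of nu-SVC, which upper-bounds exactly that
fraction; `slack_fraction = 0.05` is the default and the parameter is
exposed. Features are never rescaled, so the signed weight vector lives in
voxel space and ranks features directly.

Within each leave-run-out fold, RFE runs 40 nested splits: class-stratified
draws of 90% of the training trials *with replacement*. Every fourth split
the signed weights accumulated since the last elimination are averaged
(windowed, not cumulative — 40/4 = 10 eliminations matches the stated
arithmetic), box-smoothed over each voxel's 3x3x3 neighborhood intersected
with the current surviving mask, and the `ceiling(0.3 n)` voxels with the
smallest absolute smoothed weight are removed, ties broken by voxel index
for determinism. From 1000 voxels the survivor counts are therefore 700,
490, 343, ... exactly. If elimination would empty the set, the current set
is recorded and iteration stops early (a 1-voxel ROI yields one iteration).

At each iteration's surviving set the classifier is retrained on the *full*
training data (the nested splits serve only for ranking) and scored on the
held-out run; per-iteration accuracy is the mean over folds and the
**final accuracy is the maximum over the 10 iterations**. This
max-statistic inflates naive chance, which is why the chance level is the
mean of final accuracies under label permutations (100 by default),
shuffled *within run* to preserve the exchangeability structure that
leave-run-out validation assumes (the source does not state the shuffling
scope; within-run is the choice here). Group inference is a paired
two-tailed t of subject accuracies against subject chance levels with BH
FDR across ROIs.

# Searchlight

Sphere offsets are all integer voxel offsets with Euclidean norm at most
`floor(radius_mm / voxel_mm)` voxels — at 7 mm / 2 mm, 3 voxels in every
direction plus the centroid, 123 voxels. Each sphere is intersected with
the gray mask and then contiguity-filtered: 26-connectivity components are
computed within the masked sphere and only the centroid's component is
kept, so tissue that is close in volume but distant along the cortical
sheet cannot contribute. Edge spheres are truncated, never padded; spheres
with fewer than 2 voxels are skipped with a flag.

Classification is a pooled-covariance linear discriminant with
Ledoit-Wolf-style shrinkage toward a scaled identity, because spheres can
hold more voxels than trials; with one feature it reduces exactly to the
midpoint threshold rule, and on well-conditioned problems it agrees with an
unregularized reference. Permutation p-values use within-run shuffles
shared across centroids, and BH FDR runs across centroids; group mode is a
paired t of subject accuracies against chance, then FDR.

# Beta-series connectivity

Subject seeds are localized by thresholding the subject's contrast t-map at
uncorrected p < 0.05 (positive tail) inside an anatomical mask and keeping
the largest 26-connected cluster (the cluster rule is unstated in the
source; largest is the choice here, and subjects with no suprathreshold
voxel are flagged and excluded). The seed series is the mean beta series
over seed voxels; Pearson correlations against every voxel are Fisher
transformed, with r clipped to ±(1 − 1e-7) before atanh. Zero-variance
voxels are recorded as missing. Condition-specific maps use only that
condition's trials (at least 10), making them immune to amplitude
modulations across conditions. Group maps are one-sample two-sided t of z
against zero; condition contrasts are paired t of z differences.

# Acoustic and physiological measures

The envelope pipeline is fixed: zero-phase 4th-order Butterworth high-pass
at 150 Hz, analytic-signal magnitude (FFT construction), zero-phase
4th-order Butterworth low-pass at 8 Hz. Forward-backward filtering doubles
the effective order; that is intended, matching the named two-pass
implementation. Loudness is the mean absolute signal in a 100 ms window
centered on the envelope peak (earliest sample on ties, truncated at
edges). The spectrogram uses 100-sample segments, 90% overlap (hop 10), a
periodic Hann taper (no taper is named in the source), and 128 one-sided
frequency bins. Formants come from autocorrelation-method linear prediction
on the waveform segment (the order heuristic `2 + fs/1000` is a standard
choice; none is stated): roots with positive imaginary part, inside
(90 Hz, Nyquist − 50 Hz) and with bandwidth under 400 Hz, sorted ascending;
fewer than two valid roots sets a failure flag rather than returning
nonsense. Trace comparisons are pointwise paired t-tests across subjects
with BH FDR over time points. The respiratory IRF proxy is the trial-locked
gray-matter mean at lags 0..16 s, anchored to zero at lag 0.

# Numerical conventions

* Censoring threshold is a strict inequality at 0.4 mm.
* Elimination counts use `ceiling`; |weight| ties break by voxel index.
* Survivor sets are strictly nested; determinism follows from a single
  seeded RNG stream per decoding call (`withr::with_seed`), so a fixed
  `rng_seed` reproduces voxel sets, accuracies, and permutations exactly.
* Permutation p-values are reported conservatively as
  (1 + #{perm ≥ obs})/(B + 1). Decoding accuracy is a discrete statistic,
  so this p is super-uniform under the null; uniformity checks in the test
  suite use the standard randomized tie-breaking construction, which is
  exactly Uniform(0,1) under exchangeability.
* Zero-variance columns with numerically zero means yield t = 0, p = 1;
  with nonzero means they are flagged as infinite t with p = 0.
* The |r| = 1 guard clips at 1 − 1e-7 before the Fisher transform.

# Problem sizes used by the test suite

The shipped tests run the full machinery at desk scale, chosen so the whole
suite completes in minutes on one CPU while every stated statistical
property keeps its original threshold: grids of 16³–24³ voxels at 2 mm,
10–30 trials per run over 2–4 runs, ROIs of 20–200 voxels, RFE reduced to
2–5 iterations with 2 splits per elimination where the full 10 x 4 schedule
is not itself under test (the elimination-schedule test runs the complete
10-iteration, 40-split configuration on 1000 voxels), and 3–20 permutations
per chance estimate. Null calibration of the searchlight uses 100 fully
interior 123-voxel spheres with 20 within-run permutations; RFE null
calibration uses 200 replicates of 200-voxel, 32-trial datasets with 10
permutations each.

# Known limitations

* The generator's noise is spatially and temporally white; real fMRI noise
  is neither, so absolute accuracies and p-values here do not predict
  real-data effect sizes.
* Group analyses are volumetric on the shared synthetic grid; surface-based
  alignment is out of scope.
* Pattern weights are shared across synthetic subjects, which makes group
  decoding easier than with subject-unique patterns.
* The ROI-specificity property ("the planted ROI and only it survives FDR")
  is intrinsically marginal at q = 0.05 with 8 ROIs: with one strong true
  effect, the probability that no null ROI is co-rejected is about
  (1 − 2q/m)^(m−1) ≈ 0.92 per replicate, so occasional replicates with one
  extra rejection are expected behavior of a perfectly calibrated
  procedure, not a defect.
* Effect sizes of the planted patterns are free parameters: the modeled
  study reports no quantitative condition amplitudes to calibrate against.
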