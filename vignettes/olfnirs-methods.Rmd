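---
title: "Decoding olfactory task performance from fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding olfactory task performance from fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the generative model behind the synthetic cohorts, the preprocessing and
feature conventions, the classifiers, the grouped evaluation design, and
the numerical choices made where the underlying methodology left the
design open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The decoding problem

During a psychophysical olfactory battery (threshold, discrimination,
identification subtests), odor stimuli are presented in a block design
while a continuous-wave fNIRS device records dual-wavelength
optical-density changes over dorsolateral prefrontal and orbitofrontal
cortex. Each trial ends with a behavioral outcome — the participant
answered correctly or not. The analysis asks whether the stimulus-locked
hemodynamic response predicts that outcome, trial by trial, in models that
never mix one participant's data between training and testing.

## The synthetic cohort generator

`sim_config()` + `simulate_cohort()` define the study conditions every
downstream stage is tested under. Per participant, trials of each task are
scheduled sequentially with inter-stimulus intervals drawn uniformly from
25–35 s (so 35 s epochs never overlap), and each trial is labeled correct
with a per-task probability.

The evoked response is a canonical double-gamma HRF (`hrf()`): gamma
densities with unit rate, positive lobe peaking at 6 s, undershoot peaking
at 16 s with relative amplitude 1/6, normalized to unit peak. The trial
amplitude is label-dependent:

* correct: `hrf_amplitude * (1 + effect_amp)`
* incorrect: `hrf_amplitude * (1 - effect_amp)`,

with `hrf_amplitude = 1` µM peak ΔHbO by default. Incorrect trials may
additionally receive band-limited (0.01–0.20 Hz) noise of SD
`effect_complexity` µM during their epoch, emulating the "more irregular
response" axis of difference rather than pure amplitude. Setting both
effects to zero defines the null model: any cross-validated AUC above
chance then indicts the pipeline (leakage), not the data.

ΔHbR is generated as −ΔHbO/3 plus its own noise, reflecting the typical
measured anticorrelation of deoxy- and oxyhemoglobin; the ratio is
configurable.

Physiological noise per channel: cardiac (1.2 Hz, 0.25 µM amplitude),
respiratory (0.3 Hz, 0.18 µM), Mayer waves (0.1 Hz, 0.25 µM), a smoothed
random-walk drift normalized to 0.7 µM SD, and white noise (0.35 µM SD).
These amplitudes were chosen once so that the raw per-channel noise SD is
roughly 0.9 µM, i.e. single-trial peak SNR ≈ 1 — a realistic regime for
prefrontal continuous-wave recordings in which single trials are barely
visible before filtering. Motion artifacts are injected on the optical
signals (identically timed on both wavelengths, as real motion acts on the
optode): Poisson-timed one-sample spikes (default 0.3/min, 8×SD) and step
baseline shifts persisting to the end of record (0.05/min, 3×SD), all
logged in the session's ground-truth record.

Default trial counts (threshold 16, discrimination 24, identification 12)
and correct rates (0.5 / 0.55 / 0.7) mirror a plausible session of the
battery; the published per-task unit counts are mutually inconsistent, so
these stay free parameters rather than assertions. The default montage is
8 channels at 730/850 nm, 10 Hz, separations cycling 3.0/3.5/4.0 cm; the
channel count is configurable because typical reports leave it
unspecified.

What the generator deliberately does not emulate: superficial (scalp)
hemodynamics distinct from cortical ones, photon-transport physics,
spatially structured channel covariance, serial dependence between trials,
or participant-level traits beyond the label rates. Passing tests
therefore demonstrate that the pipeline recovers the structure it assumes
and raises alarms when none exists — not that real recordings satisfy
those assumptions.

## Optics

The modified Beer–Lambert law is linear per sample:
`ΔOD(λ) = [ε_HbO(λ)·ΔHbO + ε_HbR(λ)·ΔHbR]·d·DPF(λ)`, concentrations in
mM internally (µM at the interface). The default extinction coefficients
(730 nm: 0.390/1.1022; 850 nm: 1.058/0.6913 cm⁻¹·mM⁻¹ for HbO/HbR) come
from the widely used Prahl compilation; published tables differ by a few
percent, so correctness is asserted by the forward→inverse round trip
(relative error < 1e−9 in the acceptance suite) rather than against
absolute values. DPF defaults to 6.2/5.8 (dimensionless).

## Preprocessing

The stage order is part of the contract and is logged with every run:
MBLL inversion → channel screening → band-pass → motion correction →
epoching. Choices:

* **Screening** (before filtering, on ΔHbO): spike count = clusters of
  absolute first differences above 5 robust SDs (robust SD =
  1.4826×MAD); SNR = 0.01–0.20 Hz band power over 1.5–5 Hz band power
  (periodogram), threshold 0 dB; missing fraction ≤ 10%. Rejected
  channels keep a recorded reason; their features are emitted as missing
  and mean-imputed from training rows only, keeping the table shape
  stable without cross-fold leakage. If every channel fails, the session
  errors out explicitly.
* **Filter**: zero-phase Butterworth, realized as a 2nd-order high-pass
  at 0.01 Hz cascaded with a 4th-order low-pass at 0.20 Hz, each run
  forward-backward; the series mean is removed first. A single band-pass
  section of that bandwidth at 10 Hz places recursion poles close enough
  to the unit circle that DC transients and visible round-off
  nonlinearity appear; the cascade keeps each recursion well conditioned
  while meeting the same attenuation contract (the acceptance suite
  measures > 60 dB at 1.2 Hz and < 1% passband loss at 0.05 Hz).
* **Motion correction**: spline variant. Clusters of first differences
  above 5 robust SDs are classified by whether the level change is
  sustained (2 s medians before/after differ by more than half the
  detection threshold). Sustained steps are re-leveled by subtracting the
  jump across the cluster — measured at the cluster edges, where a wide
  median window would absorb local trend bias — and all flagged segments
  are then replaced by natural cubic-spline interpolation over a ±0.3 s
  guard window.
* **Epoching**: window (−5 s, +30 s), baseline mean over (−5, 0] s
  subtracted per channel and species; 351 samples at 10 Hz. The window
  covers the canonical HRF rise, peak and return at block timescales.
  Events whose window exceeds the recording are dropped with a warning —
  a data-layout problem should not silently become a smaller dataset, but
  edge trials are expected in real recordings.

ΔHbT is defined as ΔHbO + ΔHbR sample-wise and is recomputed after
filtering; because every stage up to epoching is linear per channel, the
identity survives preprocessing exactly.

## Feature conventions

Thirteen feature kinds × three species × channels, named
`<Feature>_<Species>_<Channel>` with 0-based channels. Decisions where the
convention was open:

* **Peaks**: local maxima with topographic prominence ≥ 0.5×SD of the
  epoch; prominence, not raw height, so filter ripple does not count.
* **LZC**: binarize at the median (≥ median → 1), LZ76
  exhaustive-history component count `c(n)` (implemented in C++; an
  independent brute-force parser in the test helpers checks every binary
  string up to length 12), normalized as `c(n)·log₂(n)/n`.
* **Mutual information**: plug-in estimate from an 8×8 equal-width
  histogram, in bits. The estimator is deliberately simple and
  deterministic: MI is used as a relative feature, so its bias is
  acceptable, and the brute-force double-sum oracle can verify it
  exactly. Each channel is paired with the mean series of all other
  retained channels of the same species, matching the single channel
  index in names like `MutualInfo_Hb_0`; a pairwise-matrix alternative
  would not serialize into that grammar.
* **Wavelets**: periodized orthonormal Daubechies-4 pyramid, depth
  `min(4, ⌊log₂ n⌋ − 2)`; statistics over the pooled detail
  coefficients. Lengths not divisible by `2^depth` are padded with the
  series mean, so a constant epoch still yields all-zero details; energy
  conservation is exact at divisible lengths and is tested there. The
  trailing index in wavelet feature names is the channel, consistent
  with every other feature.
* **Standardization**: z-scores per column with mean/SD estimated on
  training rows only and applied unchanged to held-out rows;
  zero-variance columns are flagged degenerate and emitted as 0.

## Models

Tabular tasks default to gradient-boosted trees (grid: depth {2,3,4},
learning rate {0.05, 0.1}, 100–300 rounds), with logistic regression,
random forest and a single-hidden-layer MLP as baselines. Inner tuning is
grouped k-fold AUC selection inside the training fold. Attribution uses
the exact tree-path (SHAP) algorithm of the boosted-tree backend; per-row
additivity (base value + contributions = margin) is asserted in tests, and
non-tree models are rejected — no attribution is offered for the deep
model.

### The attention-CNN

The identification task consumes raw preprocessed epoch tensors
(channels × species × time), not the feature table. The architecture:

1. a **weight-shared per-channel temporal encoder** — two blocks of
   (1D convolution → batch normalization → ReLU → dropout 0.2), kernels
   7 and 5, strides 2 and 2, 16 and 24 filters, applied to each channel's
   species × time slab with shared weights;
2. **channel attention**: a squeeze (mean squared activation per channel
   map) feeds a linear score network whose softmax pools the per-channel
   feature maps into one map;
3. **temporal attention**: an additive score network (tanh layer + inner
   product, softmax over time) pools the time axis;
4. a fully connected head with 2-class softmax.

An earlier design followed the more common sketch — convolution over all
channels jointly plus a multiplicative squeeze-excitation gate — but with
full channel mixing the gate is redundant: the convolution can route any
channel's content directly, the gate drifts freely, and (worse) the
sample-dependent squeeze lets label information leak through the gate
pattern itself, so the exported "channel attention" need not point at the
channels carrying signal. In the implemented design, channel content can
only reach the classifier through the attention-weighted pooling, which
makes "attention concentrates on informative channels" a structural
property; the test suite verifies it on planted-signal constructions
across several initialization seeds. Both attention maps are exposed
(`attention_weights()`), nonnegative and normalized over their axis; the
temporal map is upsampled back to input resolution for reporting.

Training: Adam (learning rate 1e−3), batch 32, cross-entropy with class
weights inversely proportional to training-class frequency, early
stopping when validation loss fails to improve by 1e−4 for 20 epochs,
learning rate halved after 10 stagnant epochs, best-validation weights
restored. Gradients are hand-derived; a finite-difference check over every
parameter block runs in the test suite. At the default configuration the
network has well under 10⁵ parameters. For the CNN the epochs are
decimated by 4 (to 2.5 Hz); the series are low-passed at 0.20 Hz, so
decimation by small factors loses nothing and cuts training cost.

## Evaluation design

* **Grouping**: all cross-validation is participant-grouped — 10 outer
  folds × 5 repeats by default, inner 5-fold tuning restricted to outer
  training participants. Standardization, imputation, balancing and
  tuning happen strictly inside training folds; an automated test plants
  a participant-identifying constant feature in a null cohort and checks
  that held-out AUC stays at chance.
* **Balancing**: random under-sampling of the majority class for
  threshold and discrimination; class weights in the loss for
  identification.
* **Pooling**: headline numbers pool test predictions (and confusion
  counts) over all folds and repeats — matching the single published
  confusion matrix per task — with fold mean ± SD alongside. A fold whose
  test set contains one class contributes to pooled counts but is
  excluded from per-fold AUC averaging.
* **Unit of analysis**: trial-level with participant grouping; a
  participant-level majority-vote summary is also emitted, since the unit
  counts in published reports of this design are often ambiguous.
* **Uncertainty**: participant-grouped stratified bootstrap (resample
  participants with replacement within strata defined by each
  participant's majority label; recompute the metric on the pooled
  trials; percentile interval), default 2000 replicates. The acceptance
  suite measures empirical coverage of a known proportion at 100 groups
  over 200 seeded replications with 500 replicates per interval —
  percentile-CI coverage is insensitive to the replicate count beyond a
  few hundred, and the default 2000 remains for analyses.
* **Decision threshold**: fixed at 0.5; ties score positive. No
  threshold tuning anywhere.
* **TDI scoring**: total = threshold + discrimination + identification;
  admissible ranges threshold [1, 12], others [0, 12] (package
  convention: only the total range 1–36 and the 12-item structure of the
  subtests are fixed externally); categories normosmic (> 21), hyposmic
  ((14.5, 21]), anosmic (≤ 14.5), with boundary cases tested explicitly.

## Problem sizes in the shipped suites

The test and acceptance suites run the full method at sizes chosen for a
single CPU: the null/leakage suite uses the full 100-participant cohort
with 8 discrimination trials each and an untuned logistic model (the null
property is model-free); effect-size recovery and monotonicity
(effect amplitude 0 → 0.1 → 0.25 → 0.5, complexity effect disabled to
isolate amplitude) use 24-participant cohorts with 10 trials each,
boosted trees with a fixed mid-grid configuration, and a 6-fold single
repeat; the CNN recovery uses the same cohort scale with at most 60
training epochs. These are the package's reduced study conditions for
verification, not recommendations for real analyses, where the defaults
(10×5 folds, full grids, 2000 bootstrap replicates) apply.

## Known limitations

* The generator's channels are exchangeable (no spatial structure), so
  channel-resolved claims — e.g. which cortical region drives an effect —
  cannot be validated against it.
* No superficial-signal regression is implemented; the acquisition design
  it emulates relies on optode placement to limit scalp contamination,
  and short-separation channels are out of scope.
* The MI estimator's histogram bias is uncorrected (by design; see
  above). LZC depends on the binarization convention; values are
  comparable within this package, not across LZC variants.
* The attention-CNN is a compact, CPU-sized network; it is the
  architecture family of interest at a scale suited to hundreds of
  epochs, not a GPU-scale model, and no attribution method is applied to
  it.
* Deep-model determinism holds for fixed seed and batch order; metrics
  from tabular models are reproducible to machine precision.
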