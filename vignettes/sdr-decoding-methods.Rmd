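---
title: "Decoding the short-duration levodopa response from motor-cortical band power: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the short-duration levodopa response from motor-cortical band power: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sdrdecode)
```

## The problem

About an hour after a carbidopa/levodopa dose, people with Parkinson's
disease show a short-duration response (SDR): motor signs improve, and
resting-state cortical oscillations shift. This package implements a
subject-specific analysis of that response with two arms:

* a **clinical arm** — the 33 items of the MDS-UPDRS Part III motor exam,
  scored 0–4, are grouped into 7 motor factors (midline function, rest
  tremor, rigidity, right/left upper-extremity bradykinesia,
  postural/kinetic tremor, lower-limb bradykinesia) and summarised per
  subject and medication condition; and
* a **neurophysiological arm** — per-subject linear support vector
  machines classify 5 s snippets of motor-cortical source-space signal as
  LEVODOPA-OFF or LEVODOPA-ON from band power in 7–13, 13–20, 20–30 and
  35–45 Hz, yielding a cross-validated accuracy (how separable the two
  states are) and a frequency-band weight profile (which bands separate
  them, and in which direction).

The two arms meet in a regression of per-factor clinical change on
decoding accuracy. Because the human dataset is not redistributable, the
package ships a synthetic cohort generator with the statistical structure
the analysis assumes, so that every stage is testable end to end.

## Spectral feature extraction

Per hemisphere and condition the pipeline applies, in order:

1. **Epoch rejection.** Non-overlapping 5 s epochs are scored by mean
   periodogram power in 50–330 Hz (muscle and spike artifacts live there);
   epochs scoring more than 1.5 standard deviations above the mean score
   are dropped. This must run *before* the lowpass, which would erase the
   scoring band. With a single clean synthetic channel per hemisphere,
   channel-level rejection has no counterpart here and is not implemented.
   Rejection statistics are computed per hemisphere signal.
2. **Lowpass.** An order-18 Butterworth with half-power frequency 48 Hz,
   designed by bilinear transform and applied single-pass as second-order
   sections. High-order Butterworths are numerically hopeless as a single
   polynomial but exact in cascade form. Single-pass (causal) filtering is
   used because phase does not affect Welch power; zero-phase filtering is
   deliberately not claimed. One consequence of the bilinear transform
   deserves note: at 1 kHz sampling, the response at 100 Hz is ~4 dB
   *below* the analog closed form `-20·18·log10(100/48)` dB because of
   frequency warping (scipy and MATLAB designs behave identically); the
   closed-form contract is therefore verified at 2–4 kHz where warping is
   negligible, while the 48 Hz half-power point is exact at any rate
   thanks to prewarping.
3. **Snippeting.** 5 s snippets with 50% overlap (2.5 s hop), trailing
   partial data dropped: a 180 s recording yields 71 snippets.
4. **Normalisation.** Each snippet is z-normalised to zero mean, unit
   variance. Absolute source amplitude is therefore irrelevant, which is
   also why the synthetic signals are unitless.
5. **Welch spectra.** Averaged modified periodograms: 1 s Hamming windows,
   50% overlap, zero-padded to a 2 s transform. Zero-padding is the only
   reading consistent with both a 1 s window and a 0.5 Hz grid.
   One-sided density normalisation, so integrated PSD approximates the
   (unit) snippet variance.
6. **Band power.** Mean PSD over half-open bands [7,13), [13,20),
   [20,30), [35,45) Hz. Half-open intervals keep the shared 13 Hz edge in
   one band only; the mean (rather than the sum) is invariant to grid
   refinement. Either choice only rescales features, which the later
   standardization removes — the choice is recorded for reproducibility.

Each retained (snippet, hemisphere) pair becomes one labelled sample with
4 features. This pooling matches a 4-weight profile display; an
alternative 8-feature mode (4 bands × 2 hemispheres per snippet) is
available via `hemisphere_mode = "features"`.

## The decoder

Class coding is ON = +1, OFF = −1, so a positive band weight means
standardized power in that band is higher on medication.

* **Balancing.** Classes are trimmed to equal size; surplus samples are
  removed deterministically from the chronological end of the larger
  class (a seeded random mode exists). Determinism without a seed was
  preferred for the default.
* **Standardization.** Features are standardized to zero mean, unit
  variance globally before cross-validation (the default, matching a
  standardize-then-construct-the-SVM description); a `per_fold` scope
  that fits on training folds only is available to eliminate the mild
  leakage of the global scope.
* **Folds.** 10 unshuffled folds, stratified by class: within each class
  the chronologically ordered samples are cut into 10 contiguous blocks,
  and fold i unites block i of both classes. Stratification is not
  guaranteed by the source description (which only promises no
  shuffling); it is adopted here because unstratified contiguous cuts can
  produce single-class test folds, which make accuracy and ROC
  undefined. OFF and ON come from separate recording sessions, so
  "chronological" order is within-condition.
* **SVM.** The linear soft-margin SVM minimises
  `0.5 ||w||^2 + C * sum(hinge)` via sequential minimal optimisation on
  the dual (compiled, maximal-violating-pair selection). Inside
  cross-validation the solver is capped at 30 000 pair updates: with very
  large C on non-separable data the dual creeps without changing the
  prediction, and fits at the loss-minimising C converge far below the
  cap. Standalone fits default to a much higher cap and tighter
  tolerance, and match an external QP oracle to 1e-4 relative objective
  error on small instances.
* **ROC.** Per-fold ROC curves from test-set decision values are
  vertically averaged on a fixed false-positive-rate grid (step 0.01);
  area by trapezoid. Folds with single-class test sets are skipped with a
  warning.

## Box-constraint selection

C is selected per subject (not per fold) by one-dimensional Bayesian
optimisation of the 10-fold cross-validation loss `1 − mean(fold
accuracy)` over `log10(C) ∈ [−6, 6]`, at most 30 objective evaluations:
a 4-point stratified random initial design, a Gaussian-process surrogate
(constant mean, squared-exponential kernel, maximum-likelihood length
scale and signal variance, small fixed noise since the objective is
deterministic on fixed folds), and expected improvement with an
exploration floor ξ = 0.01. Every 8th iteration proposes a seeded uniform
random point instead of the acquisition argmax. The "expected improvement
plus" acquisition of the original MATLAB environment is proprietary; the
floor-plus-restarts construction is this package's documented stand-in,
and the contract that matters — a near-optimal C within bounds in ≤ 30
evaluations — is verified against a 0.01-resolution grid search on
unimodal objectives. The search runs in log10 space because the bounds
span 12 decades.

## Clinical factor scores

`default_factor_structure()` fixes the canonical partition of the 33
items into 7 factors of sizes 8, 6, 5, 3, 3, 4, 4. Raw sums and weighted
averages are computed per factor; the weighted average
`sum(w*s)/sum(w)` stays on the 0–4 item scale. The published per-item
loadings live in a supplement that is not redistributed here, so default
weights are uniform and a `weights_csv` hook accepts the published
loadings unchanged. Missing items are an error, never imputed — silent
imputation would corrupt OFF/ON comparisons.

## Statistics battery

* **Wilcoxon signed rank** (paired OFF vs ON per factor): zero
  differences dropped (classic treatment, the default of the era's
  statistical environments; Pratt handling was considered and rejected
  for comparability). Exact two-sided p by enumeration of all sign
  assignments of the |difference| mid-ranks for n ≤ 12 (enumeration stays
  valid under ties), else a normal approximation with tie and continuity
  correction.
* **Bonferroni** over the 7 factors.
* **Friedman omnibus** across the 7 factor changes: chi-square form with
  mid-ranks and tie correction, df = k−1 = 6. The ambiguous label
  "Friedman F-test" is resolved in favour of the chi-square form, which
  is the only one consistent with df = 6; the Iman–Davenport F transform
  is offered as an option.
* **Post hocs**: all C(7,2) = 21 pairwise Wilcoxon comparisons of factor
  changes with Benjamini–Hochberg control; the reported "critical p" is
  the largest ordered p passing its step-up threshold. The exact pairing
  family is an interpretation (the source text does not spell it out);
  21 = C(7,2) makes the pairwise reading the natural one.
* **Spearman matrix** of SDR changes across factors (mid-ranks,
  t-approximation p-values).
* **Accuracy regression**: per factor, OLS of clinical change on median
  decoding accuracy, with unadjusted two-sided slope p, Bonferroni-
  adjusted p across the 7 factors, R², and a 95% pointwise confidence
  band of the fitted line.

## The synthetic cohort generator

Each synthetic hemisphere signal is a sum of

* four band-limited Gaussian components (white noise through 4th-order
  Butterworth band-passes at the analysis band edges, scaled to variance
  `exp(baseline + I(ON)·effect)`) — the medication effect is a per-band
  log-power shift, so `effect = +1` multiplies that band's ON variance by
  e;
* a 1/f^α background (frequency-domain shaping, α = 1, unit variance by
  default, flat below 1 Hz);
* white noise (sd 0.5 by default), which sets the high-frequency floor
  probed by the rejection rule; and
* optional muscle-artifact bursts: Poisson-placed 0.25 s Hann-windowed
  60–300 Hz noise bursts at 8× the white-noise amplitude. The default
  rate is 0 (clean); `contaminated_subject_spec()` uses 6/min.

Baseline band variances default to (1.0, 0.8, 0.5, 0.1) for mu/alpha,
low-beta, high-beta and low-gamma — a resting motor-cortical profile with
prominent mu and beta over a 1/f background. Ratings are generated by
giving every item the latent severity of its factor, reducing coupled
factors' ON severity by `coupling × ||effect||`, adding rater noise
(sd 0.5 per item), clipping to [0, 4] and rounding — which yields valid
ordinal items with a monotone dose–response.

All randomness flows from one integer seed through `derive_seed()`
(an FNV-1a hash of the seed plus stage/subject/condition tags), so a
cohort spec regenerates byte-identical data and a pipeline config
reproduces every output file exactly.

What the generator does **not** emulate: volume conduction and source
mixing, ECG/EOG contamination, head movement, session/order effects
(OFF is always recorded before ON in the emulated design), non-Gaussian
oscillatory waveform shape, and within-session nonstationarity. A green
test therefore establishes that the pipeline recovers the structure this
generative model encodes — not that it would survive every pathology of
real MEG.

### Cohort presets used by the recovery tests

Two "stated worlds" are fixed once and used by the acceptance battery:

* **Null cohort** (decoding chance control): 20 subjects, zero effect in
  every band, 180 s per condition per hemisphere at 1 kHz. Grand median
  cross-validated accuracy must sit at 0.5 ± 0.1.
* **Coupled cohort** (brain–behaviour recovery): subjects' effect
  vectors are uniformly random directions with magnitudes uniform on
  [0, 0.8] log units — spreading the cohort across the decoder's dynamic
  range, which saturates (accuracy 1.0) above ~1 log unit; clinical
  coupling 3 on factor 7 only, with that factor's OFF severity drawn
  around 3 of 4 so the response has headroom on the item scale. A
  coupling of 3 maps a typical 0.5-log-unit spectral response to a
  ~1.5-point factor-score improvement, the magnitude scale seen in
  strong clinical SDRs. With 12 subjects and 120 s recordings the
  factor-7 regression attains the smallest unadjusted p among the 7
  factors in the large majority of replicate cohorts.

The effect-size grid for the accuracy-monotonicity check spans 0–1 log
units for the same saturation reason: points above 1 are uninformative
ties at accuracy 1.0.

## Numerical choices and degenerate inputs

* Epoch rejection with a single epoch (sd undefined) keeps the epoch
  (sd is defined as 0 and the comparison is `score <= mean + 1.5·sd`).
* A rejection band extending beyond Nyquist is clipped with a warning.
* Constant snippets cannot be z-normalised and are an error.
* Signals shorter than one snippet yield an empty snippet list with a
  warning (so batch pipelines can skip), but a recording whose retained
  data yields zero snippets in either condition aborts the subject.
* Welch windows are symmetric Hamming (MATLAB convention).
* Band powers use strict half-open membership `low <= f < high`.
* The GP surrogate adds jitter 1e-10 and refuses nothing: a failed
  Cholesky falls back to a large penalised likelihood, and a collapsed
  acquisition (argmax on an already-evaluated point) proposes the most
  uncertain grid point, then a seeded random point.
* Wilcoxon with all differences zero is undefined and raised as an
  error, as is a Friedman matrix with missing cells and a regression on
  zero-variance accuracies.

## Known limitations

* The uniform default factor weights are a documented stand-in for the
  published loadings, not a claim about them; supply the loadings via
  `weights_csv` for faithful weighted averages.
* The SMO iteration cap inside cross-validation trades exactness at
  absurd C for runtime; solver-grade fits are available through
  `train_linear_svm()` directly.
* The fold-assignment stratification and the post hoc pairing family are
  documented interpretations of an ambiguous source description, not
  assertions about it.
* Decoding accuracy, not spectral effect size, is the abscissa of the
  brain–behaviour regression; accuracy saturates, so very large spectral
  effects are indistinguishable from merely large ones.
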