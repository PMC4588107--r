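---
title: "Personalized multi-class fNIRS BCI analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized multi-class fNIRS BCI analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsbci)
```

`nirsbci` implements an offline analysis pipeline for prefrontal fNIRS
brain–computer interfaces with personalized task selection: from raw
dual-wavelength optical intensities to each user's best-discriminating task
subset, its cross-validated accuracy, the chance-level limits it must beat,
and the correlation of accuracy with user characteristics. This vignette
explains the model at each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was open.

## Measurement model

A channel is a source–detector pair at a prescribed separation (default
3 cm), measured at two wavelengths (690 and 830 nm). The default montage is
a trapezoid of 5 sources and 3 detectors yielding exactly 9 channels; the
true optode coordinates of the instrument this layout mimics are not
published, so the shipped coordinates are a reconstruction honouring the
9-channel/3-cm constraints and are fully overridable
(`nirs_montage()`).

Intensity changes are converted to chromophore concentration changes by the
modified Beer–Lambert law. With $\Delta OD_\lambda = -\log_{10}(I_\lambda /
I_{0,\lambda})$,

$$\begin{pmatrix}\Delta[\mathrm{HbO}]\\\Delta[\mathrm{Hb}]\end{pmatrix}
 = \varepsilon^{-1}
 \begin{pmatrix}\Delta OD_{690}/(d\,\mathrm{DPF}_{690})\\
                \Delta OD_{830}/(d\,\mathrm{DPF}_{830})\end{pmatrix},
 \qquad \Delta[\mathrm{tHb}] = \Delta[\mathrm{HbO}] + \Delta[\mathrm{Hb}].$$

Parameters (`optics_parameters()`):

* $\varepsilon$ — 2×2 extinction matrix in 1/(mM·cm). Default: the widely
  used Gratzer/Cope tabulation (690 nm: HbO 0.276, Hb 2.052; 830 nm:
  HbO 0.974, Hb 0.693). Deoxygenated hemoglobin dominates below the
  isosbestic point, oxygenated above it, which keeps the inversion well
  conditioned.
* $d$ — source–detector distance, 3 cm.
* DPF — differential pathlength factor, 6.0 at both wavelengths (common
  adult-forehead convention). Every downstream feature is homogeneous of
  degree 1 in concentration, and classification is invariant to a global
  scale, so the DPF convention affects units only, not accuracies.
* $I_0$ — per channel and wavelength, the mean intensity over each block's
  30-s opening baseline (`raw_to_hemo()`), so concentration changes are
  relative to that block's rest state.

## Filtering and segmentation

The denoising filter (`filter_spec()`, `design_lowpass()`) is a third-order
Chebyshev type-I IIR low-pass: 0.1 dB passband ripple, passband 0–0.1 Hz,
transition 0.1–0.5 Hz, at 31.25 Hz sampling, realized as a cascade of
second-order sections. It suppresses the Mayer wave (≈0.1 Hz), respiration
(0.2–0.4 Hz) and the cardiac pulse (0.5–2 Hz) while passing the slow
task-locked response; being odd-order type I it has exactly unit DC gain.
The tests verify the realized magnitude response against the analog
prototype bound $|H| = (1+\epsilon^2 T_3(f/f_c)^2)^{-1/2}$.

Filtering is a single causal pass by default, matching a real-time feedback
setting; `zero_phase = TRUE` switches to forward–backward filtering.
Concentrations (not raw intensities) are filtered; up to the near-linearity
of the logarithm at these optical densities the order is immaterial, and
filtering after conversion keeps the filter in physical units. Δ[tHb] is
re-derived as the sum after filtering (equivalent, for a linear filter, to
filtering the sum).

Trials are the half-open 20-s windows from each task onset
(`segment_trials()`; 625 samples at 31.25 Hz, 0-indexed onsets floored to
the sample grid). Each epoch is referenced by subtracting its first sample;
slope features are offset-invariant anyway, and this pins the topography
baseline. An exclusion table (session, block, interval) supports discarding
motion-contaminated trials.

## Features

Three feature sets per epoch (`epoch_features()`):

* **Temporal (108)** — least-squares slopes of each channel × chromophore
  over the nested windows 0–5, 0–10, 0–15, 0–20 s.
* **Spatial (180)** — at every sample, the nine channel values are
  interpolated onto a trapezoidal 21-row image with parallel sides of 21
  and 61 pixels (861 in-mask pixels; pixel row/column indices are R's
  native 1-based convention); each chromophore frame is summarised by the
  15 orthonormal discrete Tchebichef moments of total order ≤ 4, and the
  features are the windowed slopes of each moment series.
* **Combined (288)** — concatenation, temporal first.

Two open design points and their resolutions:

* *Slope time normalization.* Time is normalized so that the **full epoch**
  spans [0, 1] and each window regresses over its initial segment; a ramp
  rising $R$ µM over the epoch therefore scores exactly $R$ in every
  window, so slopes share units (µM per epoch) and are directly comparable
  across window lengths. (Normalizing each window separately to [0, 1]
  would rescale the same ramp to $R\,w/20$ for window length $w$.)
  Amplitude is not rescaled, so features stay interpretable and degree-1
  homogeneous.
* *Topographic interpolation.* The scheme is a cubic radial-basis
  interpolant ($\varphi(r) = r^3$ plus an affine term) centred at the
  channel pixels: it passes exactly through the channel values and
  reproduces constant and planar fields exactly. Because it is linear in
  the data, interpolation and moment extraction collapse into one
  precomputed 15×9 matrix, so spatial features cost one small matrix
  product per epoch rather than an 861-pixel interpolation per frame.
  Moments are computed on the full 21×61 rectangle with zeros outside the
  trapezoid mask; note that a constant-on-mask image consequently projects
  onto higher-order polynomials too (only odd-horizontal-order moments
  vanish, by the mask's left–right symmetry).
* *Frame rate.* Moment series are computed at every filtered sample
  (31.25 Hz). A display refresh rate is a property of the feedback UI, not
  of the analysis, so no decimation is applied (configurable via the epoch
  windows).

## Feature selection: FCBF

Within every training fold, each feature set is reduced by the fast
correlation-based filter (`fcbf()`). Features are discretized into 10
equal-width bins fitted on the training fold only, ranked by symmetrical
uncertainty with the class,

$$SU(X, Y) = \frac{2\,I(X;Y)}{H(X) + H(Y)} \in [0, 1],$$

kept if $SU > \delta$ (default $\delta = 0$: any positive relevance), and
pruned by the FCBF redundancy rule — feature $j$ is removed if an
already-kept $i$ has $SU(i, j) \ge SU(j, \text{class})$. Ties are broken by
feature index, making selection deterministic. If nothing clears the
threshold the single top-SU feature is kept (with a warning) so a
classifier can always be fit. The discretization (equal-width, 10 bins) and
$\delta$ are configuration knobs; the values above are the defaults because
nothing in the problem constrains them more tightly, and the
cross-validation driver guarantees test data never reach the selector
(asserted by a dedicated leakage test).

## Classification

Each n-class problem over a task subset is decomposed one-vs-one into
$\binom{n}{2}$ binary units (`ovo_fit()`). A unit holds three ensembles —
one per feature set, each with its own FCBF selection refit on the unit's
training rows — and predicts by majority of the three (never tied: three
voters, two labels). An ensemble is 10 linear discriminants trained on
bootstrap resamples of the unit's training data (resamples missing a class
are redrawn), voting by member majority with ties broken by summed
discriminant score. The multi-class label is the plurality over binary
winners; ties go to the highest vote count and then the lowest-indexed task
in the subset — deterministic and seed-free.

The discriminant uses the MLE pooled covariance (denominator $n$, which
makes the fit invariant under duplicating the training set) plus a ridge
$\gamma\,\mathrm{tr}(\Sigma)/p \cdot I$ with $\gamma = 10^{-6}$: folds with
very few selected features can otherwise be singular. The threshold
includes the empirical log-prior ratio.

All stochastic pieces (fold assignment, label shuffling, bootstrap
resampling, every simulator noise component) draw from named streams
derived from one master seed, so any component is individually
re-generable, results are bit-for-bit reproducible, and a consistent
relabeling of tasks permutes predictions exactly.

## Evaluation and personalization

Accuracy is estimated by 10 iterations of stratified 10-fold
cross-validation (`cross_validate()`): within each iteration classes are
dealt round-robin into folds (the protocol's 60 trials per class make the
folds balanced), each fold serves once as test data, and the mean of the
100 fold accuracies is reported. Stratification is a deliberate choice
where plain random splitting was also defensible; it keeps per-class counts
stable in every fold. Personalization (`personalize()`) evaluates all
$\binom{6}{n}$ subsets (15/20/15/6 for n = 2…5) and returns the argmax,
ties to the lexicographically smallest subset.

Chance limits (`chance_interval()`): the chance level is $100/n$ percent;
with $T$ trials an observed accuracy fluctuates, so the pipeline computes
the Clopper–Pearson interval around $x = \mathrm{round}(p_0 T)$ successes
in $T$ trials (default $T = 60$, the per-class trial count of the full
protocol; $\alpha = 0.05$). At $T = 60$ this yields (36.8, 63.2)% for two
classes. A Wald option is provided. Clopper–Pearson was chosen as the exact
small-sample construction; published two-class limits for this protocol
match it to printed precision, while constructions behind some published
multi-class limits are not uniquely recoverable, so no single formula
reproduces every printed table — the package commits to one defensible
construction rather than mixing.

A `shuffle_labels` switch permutes the class labels before
cross-validation; the resulting accuracies are the null calibration and are
required (by the acceptance tests) to fall inside the chance limits for
every n.

## Correlates of accuracy

`correlate_report()` correlates per-user best two-class accuracy with user
characteristics: continuous variables (verbal IQ; averaged 7-point Likert
items — tiredness, concentration, enjoyment, ease of session, headgear
comfort) use Pearson correlation when they pass a Shapiro–Wilk normality
check (at 0.05), otherwise Spearman (logged); dichotomous demographics
(gender, handedness) always use Spearman on integer codes. All p-values are
two-sided; missing values are deleted pairwise (one missing IQ costs one
pair, not the participant); age is excluded by default, reflecting cohorts
too age-homogeneous to analyse; no multiple-comparison correction is
applied at the default α = 0.1 (favouring sensitivity at n ≈ 10), though
the caller can adjust the returned p-values.

## The synthetic-data generator

No recordings ship with the package; the generator exists so every
downstream stage is testable and so study-scale conditions can be
reproduced on demand.

* **Protocol** (`generate_protocol()`): 5 sessions × 3 blocks; each block a
  30-s baseline plus 24 intervals of 20 s task / 17 s rest; 6 tasks × 4
  repetitions per block, randomized within block; 60 trials per task
  overall; 918 s per block.
* **Responses** (`effect_spec()`): each task has a per-channel HbO
  amplitude (µM); the trial time course is a double-gamma HRF (peak 6 s,
  undershoot 16 s, ratio 1/6) convolved with the 20-s task boxcar and
  peak-normalized; Hb is −1/3 of HbO; tHb is the exact sum; per-trial
  amplitudes get lognormal jitter (sd 0.2). The default amplitude map
  (`default_amplitudes()`, ~1 µM peak) assigns distinct topographies so
  that some pairs (mental math vs unconstrained rest) are far more
  separable than others (mental math vs word generation) — the structure
  that makes personalization meaningful. Absolute effect sizes and SNR in
  real recordings are unknown; these magnitudes are declared defaults, not
  estimates.
* **Noise** (`noise_spec()`): Mayer wave 0.3 µM at 0.1 Hz with a slow phase
  random walk; respiration 0.2 µM at a rate drawn per block from
  0.2–0.4 Hz; cardiac 0.2 µM at 1.1 Hz; 1/f drift 0.3 µM; white noise
  0.1 µM; Hb noise at 1/3 amplitude; multiplicative intensity measurement
  noise (relative sd 10⁻³). Component centres sit inside the physiological
  bands the filter targets.
* **Forward optics** (`hemodynamics_to_intensity()`): exact inverse of the
  MBLL stage; with noise disabled the round trip is below 10⁻⁶ µM
  (asserted by tests).
* **Participants** (`participant_spec()`): verbal IQ ~ N(100, 12); Likert
  averages truncated-normal in [1, 7]; gender/handedness Bernoulli. A
  coupling coefficient ties each participant's effect scale to IQ by
  $\exp(c\,(IQ - 100)/\sigma)$; the default $c = -0.5$ plants the
  direction in which stronger responses accompany lower verbal IQ, so
  cohort-level correlation machinery has structure to find. Set $c = 0$
  for exchangeable participants.

What the generator does **not** emulate: systemic (scalp/superficial)
interference as a separate compartment, photon-transport/partial-pathlength
effects, motion artifacts, channel-specific optode coupling losses,
session-to-session nonstationarity, and any empirically calibrated effect
size. Passing tests on synthetic data therefore demonstrate that the
pipeline is correct and behaves as designed under its stated model — high
accuracy under strong planted effects, chance-level accuracy under label
shuffling, recovery of planted structure — not that any particular accuracy
will be achieved on real recordings.

## Numerical choices and degenerate inputs

* Non-positive intensities error with the offending channel and sample;
  singular extinction matrices, absent classes, unstable filter designs,
  onsets past the end of a recording, and collinear channel layouts all
  error eagerly with specific messages.
* FCBF's empty-selection fallback keeps the top-SU feature with a warning.
* Bootstrap resamples missing a class are redrawn (bounded retries).
* Grid pixels are inside the mask if the row's integer width (linear
  between the parallel sides) covers them; the 21/61 defaults give exactly
  861 mask pixels, the trapezoid area.
* Channel-to-pixel mapping normalizes the channel-midpoint bounding
  trapezoid onto the pixel trapezoid (vertical affine, horizontal
  normalized against linearly interpolated edges), so it is invariant to
  rigid translation and uniform scaling of the montage.

## Problem sizes used by the tests

The test suite exercises the full five-session protocol (360 epochs) for
the capability and null-calibration checks, two-session recordings for the
planted-pair recovery check, and single-session recordings (12 trials per
class, the minimum for 10-fold stratification) for cohort-level smoke
tests; unit tests use closed-form or tiny constructed inputs. These sizes
are the package's choices for routine verification; all of them scale up by
configuration.

## Known limitations

* The per-fold FCBF + bagged-LDA refit makes exhaustive personalization
  O(subsets × folds × units); it is comfortable at the default scale but
  grows combinatorially with task count.
* The chance-limit construction is per-class-trial-count binomial; it does
  not model dependence between folds of cross-validation.
* Correlation analyses at n ≈ 10 participants have very low power and are
  reported with that caveat built into the default α.
* The SNIRF interchange format is not yet supported; recordings use the
  package's plain-text TSV/JSON layout.
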