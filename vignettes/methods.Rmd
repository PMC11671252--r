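---
title: "Category decoding and directed spectral connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Category decoding and directed spectral connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`ecogflow` implements an analysis chain for trial-epoched multichannel
field potentials (ECoG/LFP) recorded during a two-category task:

1. **Signal conditioning** — zero-phase band-limiting, resampling,
   high-pass filtering, per-array common-average re-referencing and
   vertical bipolar derivation.
2. **Multitaper spectral perturbation (ERSP)** — moving-window DPSS
   multitaper power, single-trial baseline normalization to dB.
3. **Decoding** — linear-SVM classification of the trial category from
   non-normalized spectral power at every time-frequency point, with
   band-wise summaries, a train/test bootstrap for significance and
   Benjamini-Hochberg FDR control.
4. **Searchlight mapping** — the same classifier on raw-voltage
   features of sliding 2 x 2-electrode regions of interest.
5. **ICA subnetwork discovery** — a square independent component
   decomposition of the concatenated signals, permutation scoring of
   components by category decoding, topographic back-projection and
   peak-based site selection.
6. **Directed connectivity** — frequency-resolved conditional Granger
   causality (GC) between selected bipolar sites via multitaper
   cross-spectra and Wilson's nonparametric spectral matrix
   factorization, permutation thresholds on the max-across-frequency
   statistic, and a band-wise directionality statistic (dGC).

Because no recording is bundled, every stage is exercised against the
package's own synthetic-session generator, which plants known
category effects and known directed couplings; all quantitative claims
in the test suite are checked against this ground truth or against
closed forms, never against recorded data.

# The synthetic session generator

`simulateSession()` produces a trials x channels x samples array on an
electrode grid. The defaults mirror the emulated recording setup at
desk scale: an 8 x 16 plus an 8 x 8 array at 2.5 mm pitch (192
channels), 200 trials, epochs from -0.7 s to 4 s at 500 Hz, balanced
"animate"/"inanimate" labels, unit-variance Gaussian background noise.

**Band-limited category effects.** The generative model for a category
effect is white noise masked to the target band in the frequency
domain, scaled by the square root of a per-category power factor, and
gated by a raised-cosine onset/offset envelope with 10 ms ramps. This
was a genuinely open design choice: the emulated experiment reports
band-wise power contrasts but no generative model, and band-masked
noise is the simplest process with an exactly controlled spectral
support and a smoothly parameterizable contrast. Optionally an
`evoked` carrier (a deterministic sinusoid at the band centre, common
to all effect channels and scaled like the stochastic part) is added.
The evoked term makes category information visible to
*voltage-domain* classifiers — a pure variance modulation is linearly
undecodable from raw voltage, so searchlight scenarios need it. A
separate `shared` switch makes one band-noise realization per trial
drive all effect channels: with it the effect is a genuine subnetwork
source spanning the channel set (what the ICA stage is meant to
recover as a single component); without it (the default) each channel
carries an independent induced component and ICA correctly reports
per-channel sources instead.

A useful consequence of the induced-power model: the between-category
power ratio at an effect channel saturates at the per-category power
factor as the injected amplitude grows, because both categories
receive the same carrier noise floor. Strong single-point decodability
therefore requires a generous power factor (the suite uses 4) rather
than a large amplitude.

**Directed couplings.** A stable MVAR process (stability enforced via
the companion-matrix spectral radius) is superposed on selected
channels, per trial, with Gaussian innovations. Coefficient
conventions: `coef[i, j, k]` is the influence of channel *j* at lag
*k* on channel *i*. An optional per-category gain on the off-diagonal
coefficients can plant category information in connectivity; it is off
by default.

What the generator does **not** emulate: volume conduction and
realistic forward models, eye movements, reward events, line-noise
nonstationarity, electrode drift, artifact trials. Passing tests on
this generator therefore demonstrate the correctness of the analysis
chain, not its robustness to every pathology of real recordings.

# Spectral estimation choices

DPSS tapers are computed from the standard symmetric tridiagonal
eigenproblem and normalized to unit energy. The moving-window
decomposition stamps each window at its centre sample, with the first
window starting at the epoch start. The FFT length is the next power
of two of the window length; for a 400 ms window at 500 Hz (200
samples, padded to 256) this yields a bin spacing of about 1.95 Hz and
exactly 76 bins inside 1.5-150 Hz, and it is the only convention that
reproduces the canonical 87 x 76 (high-resolution), 6 x 17
(low-resolution) and 13-time-point (band-decoding) grids from the
stated window/step/epoch parameters; `fftMode = "exact"` switches the
padding off.

Baseline normalization is single-trial: each trial's power is divided
by that trial's mean power over the pre-stimulus baseline (default
-0.7 to 0 s) at the same channel and frequency, ratios are averaged
over trials, and the result is expressed as 10 log10 (dB). Zero
baseline power aborts with a channel/frequency diagnostic rather than
propagating infinities.

Stated analysis windows such as "-98 to 602 ms" sit 2 ms off the
sample-aligned window-centre grid (centres fall at -450 + 350k ms for
the band-decoding parameterization); window selection therefore uses a
one-sample tolerance at the interval edges, which selects three
centres per analysis window exactly.

# Decoding and inference

The classifier is a linear support-vector machine (`e1071::svm`,
libsvm) with the implementation's default regularization, trained on
unstandardized features (an optional standardization exists nowhere on
purpose: the analysis specifies non-normalized spectra). Fold
assignment is stratified and seeded; accuracy is the mean held-out
accuracy over 5 folds, and 0.5 is the chance level of the balanced
two-class design — class imbalance warns rather than reweights.

The bootstrap splits trials into a stratified 80 % training / 20 %
test partition once, then per iteration resamples the training trials
with replacement, fits the classifier and records its accuracy on the
fixed test set. The description of the original procedure is ambiguous
about whether the recorded statistic is this held-out accuracy or the
within-resample cross-validation accuracy; the package records the
held-out accuracy by default and exposes `statistic = "cv"` for the
alternative. The p-value is the proportion of the bootstrap
distribution below chance; because desk-scale test sets quantize
accuracy, values exactly at 0.5 are counted half (mid-p), which keeps
the test from treating ties as evidence. Band-wise decoding summarizes
each band by the median accuracy across the (frequency, time) points
inside the band and analysis window, and bootstraps that median.

FDR control is the standard Benjamini-Hochberg step-up (via
`p.adjust`), applied over all ROIs of all arrays jointly in the
searchlight, and across bands and windows in band decoding. Component
scoring uses a label-permutation null with Bonferroni adjustment
across components by default (`correction = "BH"` is available, since
the original description is internally inconsistent about which was
used).

# ICA

`fitICA()` is a deterministic symmetric fixed-point iteration
maximizing negentropy with the log-cosh contrast after centering and
whitening — a contrast that separates both sub- and super-Gaussian
sources, which is the property the recovery contract (Amari index
< 0.1 on 4-source mixtures of cubed-Gaussian, Laplacian and uniform
sources; mutual source correlations below 0.05) actually tests.
Component sign and scale are fixed by unit-norm topographies with a
positive maximal element. Directions spanning a purely Gaussian
subspace have no preferred rotation, so on sessions where most
channels are plain noise the iteration legitimately hits `maxit`
without formal convergence; the informative (non-Gaussian) components
stabilize within tens of iterations regardless.

Site selection thresholds the topography at the 95th percentile of all
channels of both arrays jointly (linear interpolation between order
statistics), keeps local maxima of the weight map under a 4-neighbour
within-array adjacency — the neighbourhood had to be chosen, since
"peak" is otherwise undefined on a grid — and returns the four
strongest.

# Conditional Granger causality

Cross-spectra are taper- and epoch-averaged DPSS periodograms (default
15 tapers on the 0-1 s window) on the uniform one-sided grid up to the
Nyquist frequency: the factorization requires the full grid even
though reported GC is cut at 150 Hz. Wilson's iteration factorizes
S(f) = H(f) &Sigma; H(f)\*, initialized from the Cholesky factor of the
frequency-averaged CSD, with tolerance 1e-9 on the successive-iterate
change and a 1000-iteration cap; near-singular inputs are
ridge-regularized and flagged. One numerical detail matters: the
causal ("plus") projection halves the shared Nyquist lag, exactly as
the scalar cepstral method does — without this the iteration stalls at
the noise level of estimated spectra instead of converging to
reconstruction residuals near machine precision.

Conditional GC from a source to a target given the remaining sites
follows Geweke's construction from two nested factorizations (the full
set, and the set without the source), with the usual orthogonalization
of the source innovations against the rest; with an empty conditioning
set the same code path reduces to the pairwise measure (the reduced
model is then a scalar factorization). The closed-form oracle
`analyticVarGC()` evaluates the same quantities for a known VAR from
its analytic transfer function and innovation covariance; only the
reduced model of a conditional measure requires a (deterministic)
factorization of the exact spectrum, and for a bivariate VAR the
pairwise spectrum needs no factorization at all.

The permutation null shuffles epoch indices independently per site,
which preserves marginal spectra while destroying cross-site
alignment; per permutation and ordered pair the maximum GC across the
reported frequencies is recorded, and the per-pair threshold is the
99th percentile of these null maxima. The 99th-percentile threshold
and a Bonferroni correction are both part of the emulated procedure
even though the max statistic alone already controls across
frequencies; the package keeps the printed convention — thresholds at
the 99th percentile — and additionally reports permutation p-values
Bonferroni-adjusted for the 24 band-wise connections (6 pooled
inter-subregional connections x 4 bands). A stricter 48-test count
(directions counted separately) can be requested via `nTests`.

The dGC statistic per unordered pair and band: smooth both direction
spectra with a 3-bin moving average; a "peak" is the highest interior
local maximum strictly above both neighbours. If both directions are
significant in the band, the dominant direction is the one with the
larger band value (peak value if a peak exists, else the band mean)
and dGC is the difference between directions at the dominant peak
frequency (or of band means when no peak exists); if only one
direction is significant, dGC is that direction's band value; if
neither, the band is marked none; exactly tied spectra give dGC 0
with no direction. The gamma band of the dGC table is 31-70 Hz — the
low-gamma decoding range, adopted because the connectivity convention
leaves "gamma" unspecified — and is configurable.

# Problem sizes used by the test and acceptance suites

All suites generate their data at run time. Structural counts use the
full-size grids (they are pure functions of the printed parameters);
statistical checks run at desk scale, chosen as the smallest sizes at
which the planted effects are comfortably detectable: 2-4 channel
grids with 24-60 trials for decoding properties, 10^5-sample VAR
realizations (200 epochs x 500 samples) for GC oracle agreement,
200 replicates at 200 permutations/bootstrap iterations for the null
calibration of both inference procedures, and 20 seeded replicates of
a 16-channel session (60 trials, 1.5 s epochs) for the end-to-end
subnetwork recovery. The acceptance script recomputes the same
quantities from scratch with a caller-supplied seed.

# Known limitations

* The conditioning chain is a defensible zero-phase FIR design; it
  does not claim bit-exact equivalence with any particular toolbox's
  resampling filters, whose exact parameterization is ambiguous.
* ICA noise-component screening is reduced to reproducible flags
  (convergence warnings, score ranking); there is no manual-inspection
  stage.
* The permutation threshold treats epochs as exchangeable; slow
  drifts across a session would violate that.
* dGC depends on the peak definition; the 3-bin smoothing and
  strict-local-maximum rule are documented choices, not canonical.
* The generator's effects are additive and stationary within their
  window; none of the suites probe robustness to artifacts or
  nonstationary noise.
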