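---
title: "EEG biomarkers for two-group discrimination: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG biomarkers for two-group discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmarkers)
```

This vignette documents the models behind `eegmarkers`, the parameters
that matter, the synthetic cohort generator and what it does (and does
not) emulate, and the numerical and design choices made where the
methodology left room.

## The scientific setting

The package addresses cohort comparisons of the following shape: two
groups of subjects (a clinical group and matched controls), one
artefact-free multichannel EEG epoch per subject (default 30 channels of
the 10/20 system referenced to linked ears, 400 Hz, 10.24 s — short
enough to treat the signal as stationary), and the question of whether any
band- and region-resolved quantity discriminates the groups. Two
complementary views are computed: *where power differs* (univariate
spectral biomarkers) and *how regions couple* (bivariate linear
synchronization biomarkers). All features are scalars per subject ×
(band, lobe) cell so that standard two-sample inference and simple
classifiers apply directly.

Channels are grouped into named lobes; the defaults are fixed scalp
groupings (frontal, central, parietal, temporal, occipital, left/right),
with one deliberate channel reuse (P7 serves both the left parietal and
left occipital groups) and, for the bivariate case, groups of channel
*pairs*. Montage matching is case-insensitive but performs no T3/T7 or
T4/T8 aliasing: silently mapping between the two 10/20 naming conventions
would hide montage errors, so mismatches fail loudly.

## Wavelet power biomarkers

Each channel is standardized to zero mean and unit variance, then
convolved with scaled and translated copies of the unit-energy complex
Morlet wavelet
$\psi_0(\eta) = \pi^{-1/4} e^{i\omega_0 \eta} e^{-\eta^2/2}$ with
$\omega_0 = 6$ — the conventional compromise between temporal and spectral
localization. Scale maps to an equivalent Fourier frequency through
$f = 1/(k s)$; the analytic Fourier-period factor
$4\pi/(\omega_0 + \sqrt{2 + \omega_0^2})$ equals 1.0330 for
$\omega_0 = 6$, and the conversion uses the conventional two-decimal
constant $k = 1.03$.

Numerical choices:

- **Convolution.** The transform is evaluated by FFT against the
  *explicitly sampled* wavelet on a circular grid zero-padded to the next
  power of two past $2N$, with the signal taken as zero outside the
  epoch. This is numerically identical (to ~1e-15) to direct time-domain
  convolution — the equivalence is asserted in the tests — and avoids the
  small aliasing discrepancies of evaluating the wavelet's continuous
  Fourier transform on the DFT grid. Kernel FFTs are cached per grid
  geometry, which matters in Monte-Carlo work.
- **Scale grid.** Logarithmic, 12 voices per octave, spanning 0.5–90 Hz of
  equivalent frequency. The delta band's nominal 0 Hz edge is gridded from
  0.5 Hz: a zero-frequency scale is infinite, and sub-0.5 Hz scales are
  not resolvable on a 10.24 s epoch. Every default band contains at least
  four grid scales. Band membership is half-open, $(f_{low}, f_{high}]$,
  so shared edges belong to the lower band.
- **Power convention.** Per-scale power is the time-average of
  $|W|^2 / s$ — the scale-rectified spectrum. Under plain $|W|^2$ the peak
  response to a fixed-amplitude sinusoid grows as $1/f$, which makes
  power comparisons across bands misleading; the $1/s$ rectification makes
  equal-amplitude sinusoids produce equal peaks (within 3 % across
  5–40 Hz, dominated by edge effects). The biomarker is
  $10 \log_{10}(\text{mean power})$; the multiplier is configurable (10
  for dB, 1 for plain $\log_{10}$) and all downstream statistics are
  invariant to this monotone rescaling.
- **Averaging order.** Band × lobe cells average jointly over the band's
  scales and the lobe's channels before the log. Within a lobe no channel
  repeats, so joint and channels-then-scales averaging coincide.
- **Edges.** Time averaging uses all samples (no cone-of-influence
  exclusion), matching full-epoch averaging practice; on a 10.24 s epoch
  the COI region is negligible above ~2 Hz.

## Synchronization biomarkers

Both coherence estimators run on band-filtered signals — zero-phase
(forward–backward) 4th-order Butterworth band-passes, delta filtered as
0.5–4 Hz — and only bins inside the filter passband enter the band
average. (A configuration switch estimates coherence on broadband signals
instead, for users who prefer that reading; the band-filtered estimate is
the default.)

**MS-COH.** $\gamma^2(f) = |S_{xy}|^2 / (S_{xx} S_{yy})$ with spectra
estimated by Welch's smoother: non-overlapping consecutive Hamming windows
of 1024 samples, so a 4096-sample epoch yields exactly 4 segments. Two
estimator facts shape the interpretation and are asserted in tests:

- with a single segment the estimator is identically 1 (the ratio
  collapses algebraically), so segment averaging is not optional;
- for independent signals the estimator's expectation is the *no-coupling
  floor* $1/K$ for $K$ segments ($0.25$ at the default), not 0. On
  band-filtered signals the realized floor sits slightly above $1/K$
  (≈ 0.27 at $K = 4$) because filtering correlates adjacent segments.

Welch scaling constants cancel in the ratio; spectra are nonetheless
reported as one-sided densities. Bins with zero auto-spectral power are
flagged missing and excluded from band averages rather than divided.

**AR-COH.** The channel pair is modelled as a bivariate autoregression
$z_n = -A_1 z_{n-1} - \dots - A_m z_{n-m} + e_n$ (pre-sample values zero,
$A_0 = I$), estimated by the Whittle–Wiggins–Robinson multichannel
Levinson recursion on biased autocovariances. The recursion is verified
against a direct block-Toeplitz least-squares solve to 1e-6. The order is
selected from {1, …, 50} by
$\mathrm{MDL}(m) = N \ln\det \hat Q_m + 4m \ln N$ (four real parameters
per lag of a bivariate model); the criterion is a pluggable function.
Coherence is then evaluated from the spectral factorization
$S(f) = H(f)\, Q_m\, H(f)^*$, $H(f) = [\sum_j A_j e^{-i 2\pi f j
\Delta t}]^{-1}$, on the same frequency grid as the Welch estimate so the
two are directly comparable. Stability (companion-matrix spectral radius
< 1) is checked and reported on the fitted object.

On simulated AR(2) data at $N = 4096$ the MDL selects the true order in
≥ 90 % of seeds and recovers coefficients to 0.05 max-abs; on strongly
coupled simulations at $N = 8192$ the two coherence estimators agree to
$L_\infty \le 0.1$ in-band. The agreement bound is meaningful only when
true coherence is high: the Welch estimator's per-bin standard deviation
scales with $(1 - \gamma^2)$, so at $\gamma^2 \approx 0.9$ sampling noise
alone exceeds 0.1 somewhere over ~400 bins in a nontrivial fraction of
realizations. The test generator therefore uses innovation correlation
0.99 (in-band coherence ≈ 0.96–1).

## Group statistics

One Welch unequal-variance $t$-test per (measure, band, lobe) cell — the
Behrens–Fisher treatment is warranted because variance homogeneity
typically fails for these features — with Welch–Satterthwaite degrees of
freedom and two-sided p-values. Diagnostics accompany every cell:
D'Agostino–Pearson omnibus normality (implemented from the standard
Z₁/Z₂ transforms, validated against an independent reference
implementation), Kolmogorov–Smirnov against a normal with estimated
moments (a Lilliefors-style usage whose nominal p-values are conservative;
the caveat is attached to the result), and Levene's test on absolute
deviations from group means.

Cells are classed by the topographic map thresholds: blank ($p > 0.1$),
shaded ($0.01 \le p \le 0.1$), strong ($p < 0.01$). **No multiple-testing
correction is applied** — this mirrors per-cell reporting practice in the
clinical literature the package serves — but the map carries the number
of cells tested as an attribute so users can correct; the README's worked
example shows a false positive produced exactly this way.

## Classification and fusion

A two-class linear discriminant (shared pooled covariance, equal priors)
with leave-one-out validation: each subject is predicted from a model
fitted on the other $n-1$. The pooled covariance receives a ridge
($\varepsilon = 10^{-6}\,\mathrm{tr}(S)/p$) only when numerically
singular, with a warning — at 39 training subjects and multi-feature
fusion this is a real possibility. Reported metrics are the
classification score (% correct), sensitivity (% of the clinical group
correct) and specificity (% of controls correct); with balanced groups the
score is their mean.

Four fusion operators combine single biomarkers:

1. **LDC on average** — selected features are column-standardized and
   averaged to one scalar, then classified by LDA.
2. **Majority vote** — each feature votes with its own LOO prediction; a
   class needs more than half the votes.
3. **Weighted sum** — votes encoded ±1, weighted by each feature's
   individual classification score, summed and thresholded at zero. With
   equal weights this reduces exactly to the majority vote. (The
   operator's published description fixes neither weights nor threshold;
   this is the most literal reading that yields a per-subject decision.)
4. **MINDIST** — nearest class centroid in Euclidean distance on
   standardized features; equivalent to LDA under isotropic shared
   covariance, which the tests confirm at ≥ 95 % decision agreement.

Leakage control: all standardization statistics, class centroids and LDA
fits are computed on training folds only, and the votes consumed by
fusion operators are LOO predictions in which the test subject never
entered any training set. Whether published fusion analyses of this type
kept the vote generation inside the validation loop is usually unstated;
the leakage-free reading is the defensible one and is what is
implemented. Decision ties (even vote splits, zero weighted sums,
equidistant centroids) resolve to "control" — favouring specificity in a
screening context — and the tie-break label is configurable. Feature
selection filters to individual sensitivity and specificity > 50 % and
ranks by individual score; named presets reproduce published resting and
arithmetic-task feature subsets (`biomarker_presets()`).

## The synthetic cohort generator

`cohort_spec()` describes a cohort; `generate_cohort()` realizes it
deterministically (per-subject seeds are derived from the cohort seed, so
identical specs are bit-identical and subjects are independent).

The generative model is deliberately the simplest one whose spectra and
coherences are analytically controllable: per band and synthesis lobe,
one shared band-limited Gaussian source is mixed into the lobe's channels
with weight equal to the coupling strength $c$, each channel adds
independent band-limited noise with weight $1 - c$, and every channel
receives $1/f^a$ broadband noise ($a = 1$ by default). Band-limiting uses
the same zero-phase Butterworth filters as the analysis pipeline, so
synthetic in-band coherence rises monotonically from the estimator floor
($c = 0$) to 1 ($c = 1$) — an invariant the tests check. An AR-process
option exists separately (`simulate()` on a `bvar` object) for the
parametric estimator's oracle tests.

Defaults encode the emulated study conditions: 20 + 20 subjects, 400 Hz,
10.24 s, 30 channels, band amplitudes decaying with frequency as resting
EEG does, coupling 0.75 in every band (within-lobe band coherences around
0.6–0.8, the range reported for parieto-occipital pair groups), and a
mild epileptic-group amplitude elevation of ×1.07 in theta and ×1.13 in
alpha. Those two numbers are calibrated to the reported resting-state
group gaps on the log-power scale (≈ 0.06 and 0.11 with SDs ≈ 0.2–0.3),
i.e. real but *non-significant* at $n = 20$ per group — the situation the
fusion machinery exists for.

Effect sizes for power biomarkers live on the log-power scale, while the
generator's knobs are linear amplitudes, so the mapping is measured, not
assumed: `calibrate_band_effect()` runs pilot subjects at two amplitude
levels, estimates the biomarker's between-subject SD and its slope in
log-amplitude, and returns the multiplier achieving a requested
separation in pooled-SD units.

Between-subject variability — which no published table fully specifies —
is modelled as (a) a regional log-normal amplitude gain drawn per
(subject, band, lobe) with SD 0.25 on the log10-power scale, matching the
reported SD range of 0.17–0.31 for resting biomarkers, and (b) Gaussian
jitter of the coupling strength (SD 0.05, clipped to [0, 1]). Regional
(rather than global) gains were chosen so that same-band features from
different lobes carry partly independent information, as real regional
EEG power does; a global-only gain would make every lobe's feature a copy
of the same subject factor and render fusion pointless by construction.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: volume conduction and reference effects (real
scalp channels are correlated through the head, not just through lobe
membership), artefacts (EOG/EMG/movement), non-Gaussian and non-stationary
dynamics, genuine 10 Hz alpha rhythmicity (band-limited noise has no
spectral peak), and any physiological relationship between power and
coupling changes. Calibration results (type-I rates, detection power,
fusion gains) transfer to real cohorts only to the extent that biomarker
distributions there are similarly well-behaved; the assumption
diagnostics in the significance map are the per-dataset check.

## Problem sizes and runtime

Monte-Carlo tests honour the cohort *counts* that matter statistically
(≥ 500 null cohorts for type-I calibration, 50 seeds for AR recovery,
≥ 200 realizations for the estimator floor, ≥ 200 label permutations,
20 + 20 subjects throughout) while running each cohort at reduced
physical scale — 4–10 channels, 128 Hz, 2 s epochs, one or two bands —
because the properties under test (test calibration, estimator floors,
recovery rates, fusion gains) do not depend on channel count or epoch
length beyond the segment minimum. The full-scale default configuration
is exercised once per test run. The complete suite takes roughly eight
minutes on one core; `scripts/acceptance.R` is analytic and takes
seconds.

## Known limitations

- EDF support is a minimal single-record reader/writer (16-bit
  quantization, uniform sampling rate across signals); it is meant for
  interchange of single epochs, not continuous recordings.
- No artefact handling, re-referencing or channel interpolation: epochs
  are assumed clean and referenced upstream.
- The mains-interference question is left open deliberately: no notch
  filter is applied or assumed. If 50/60 Hz contamination is present it
  will surface in gamma1/gamma2 biomarkers.
- Nonlinear synchronization measures (phase locking, generalized
  synchronization) and directed measures (PDC, Granger) are out of scope.
- The significance map is uncorrected by design; treat "strong" cells at
  face value only after your own multiplicity control.
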