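---
title: "Methods: EEG feature engineering and classifier evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG feature engineering and classifier evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmci)
```

## Overview

`eegmci` implements an end-to-end resting-state EEG pipeline for
discriminating mild cognitive impairment (MCI) from healthy controls (HC):

1. **Core processing** — 19-channel 10-20 montage recordings, zero-phase
   Butterworth band-pass (0.5–32 Hz), non-overlapping 60 s segmentation.
2. **Spectral features** (108 per segment) — Welch band powers in the
   delta/theta/alpha/beta bands for all 19 channels, plus interhemispheric
   asymmetry for 8 left–right electrode pairs per band.
3. **Functional connectivity** (171) — pairwise synchronization likelihood
   (SL) across all channel pairs.
4. **Nonlinear descriptors** (152) — eight per channel: DFA exponent,
   Higuchi fractal dimension, correlation dimension, largest Lyapunov
   exponent, C0-complexity, correlation (K2) entropy, Shannon entropy, and
   approximate entropy.
5. **Evaluation** — z-scoring, sequential backward floating selection (SBFS)
   with an LDA 10-fold criterion, eight classifier families, stratified
   10-fold and leave-one-participant-out (LOPO) cross-validation, and
   per-feature Welch t-tests.
6. **Synthetic cohorts** — a seeded generator so every stage can be tested
   against known ground truth.

The full feature vector is 108 + 171 + 152 = 431 wide.

## Spectral features

`welch_psd()` is a hand-rolled Welch estimator: Hamming windows of 512
samples with 50 % overlap, one-sided density normalised by
$f_s \sum_n w_n^2$ so that the integral of the density over frequency equals
the signal variance (Parseval). Band power integrates the density over
$[f_{lo}, f_{hi})$ by the trapezoid rule. Interhemispheric asymmetry for a
right/left pair is $\ln P_R - \ln P_L$, which is invariant to common
amplitude rescaling.

## Synchronization likelihood

For each channel, delayed embedding with lag $l = 10$ and dimension
$m = 10$ produces state vectors. For reference vector $i$ on channel $k$,
the critical distance $\varepsilon_{k,i}$ is the distance to the
$\lceil p_{\mathrm{ref}} W \rceil$-th nearest neighbour among the $W$
vectors $j$ in the window $w_1 < |i - j| < w_2$ (defaults
$p_{\mathrm{ref}} = 0.01$, $w_1 = 100$, $w_2 = 410$). The pairwise SL is the
**conditional** recurrence probability, averaged symmetrically:

$$
S = \tfrac12\left(
 \frac{\#\{j : d^x_{ij} \le \varepsilon_{x,i} \wedge d^y_{ij} \le \varepsilon_{y,i}\}}
      {\#\{j : d^x_{ij} \le \varepsilon_{x,i}\}} +
 \frac{\#\{\cdot \wedge \cdot\}}{\#\{j : d^y_{ij} \le \varepsilon_{y,i}\}}\right),
$$

averaged over all reference points $i$. This normalisation makes two
identical channels score exactly 1 and two independent channels score
approximately $p_{\mathrm{ref}}$, which is the designed dynamic range of the
estimator. A normalisation by the window size instead of the per-channel
recurrence count would compress the independent-channel baseline to
$p_{\mathrm{ref}}^2$ and the identical-channel value to
$p_{\mathrm{ref}}$, contradicting that range, so the conditional form is
used. Because $\varepsilon$ is a rank statistic of within-channel distances,
SL is invariant to per-channel affine rescaling.

## Nonlinear descriptors

* **DFA**: the profile (cumulative sum of the centred signal) is split into
  non-overlapping boxes at 12 log-spaced scales between 4 and $N/4$; within
  each box a least-squares line is removed and the RMS residual computed.
  The exponent is the slope of log-fluctuation versus log-scale. White noise
  gives 0.5, Brownian motion 1.5.
* **Higuchi fractal dimension**: curve lengths $L(k)$ for
  $k = 1, \dots, 30$; FD is the negative slope of $\log L(k)$ versus
  $\log k$. A straight line gives exactly 1; white noise approaches 2.
* **Correlation dimension**: Grassberger–Procaccia correlation sums
  $C_m(r)$ with a Theiler window, fitted only on the scaling region
  $0.01 \le C \le 0.3$ (the region is selected on the $C$ axis rather than
  the $r$ axis because the informative radii shift with the attractor size
  and noise floor); the estimate is taken where the slope saturates over
  embedding dimension. The Hénon attractor gives $\approx 1.22$.
* **Largest Lyapunov exponent**: Rosenstein's method — mean log divergence
  of nearest-neighbour trajectories (neighbours separated by at least one
  mean period) fitted over the initial linear rise. The fully chaotic
  logistic map gives $\ln 2$.
* **C0-complexity**: the spectrum is thresholded at its mean power; the
  regular part is reconstructed by inverse FFT and the complexity is the
  residual power fraction. A pure tone scores near 0; a single impulse
  (flat spectrum, every bin at the mean, strict `>` threshold keeps none)
  scores exactly 1.
* **K2 (correlation) entropy**: $\ln(C_m(r)/C_{m+1}(r))/\tau$ averaged over
  the scaling region.
* **Shannon entropy**: a 16-bin amplitude histogram over the signal range;
  entropy of the bin probabilities in nats. Uniform occupancy gives
  $\ln 16$.
* **Approximate entropy**: Pincus' ApEn with Chebyshev distance,
  self-matches included, $N - m + 1$ template convention, default tolerance
  $r = 0.2\,\mathrm{sd}(x)$.

Per-segment, each descriptor is computed on each of the 19 channels, giving
$8 \times 19 = 152$ features.

## Selection and evaluation

`zscore_fit()`/`zscore_apply()` standardise with the sample (n − 1) standard
deviation; constant columns map to zero. `sbfs()` performs sequential
backward floating selection: repeatedly remove the feature whose removal
maximises the criterion (mean LDA accuracy under an internal stratified
10-fold split with fixed fold assignment), with floating re-inclusion of
previously removed features when it strictly improves on the best criterion
seen at that subset size.

Eight classifier families are available: linear and RBF SVM, logistic
regression, k-NN (k = 5), decision tree, naive Bayes, GentleBoost
(Newton-step regression stumps) and RUSBoost (AdaBoost.M1 with
majority-class undersampling). The boosting variants are implemented in the
package because no installed dependency provides them.

Cross-validation (`kfold_cv()`, `lopo_cv()`) fits the scaler and the
feature-selection step *inside* each training partition only, so held-out
rows can never influence preprocessing. Metrics follow the standard
confusion-matrix identities, reported in percent: accuracy, sensitivity,
specificity, F1, and the false discovery rate. The FDR has two modes:
`"reported"` uses FP/(FP + TP) (the conventional definition), while
`"eq27"` uses FP/(FP + TN), which equals 100 − specificity; both are exposed
because both conventions appear in applied EEG classification work.

## Synthetic cohorts

`gen_cohort()` builds seeded per-subject recordings: each channel is a sum
of band-limited sinusoids (delta 2 Hz, theta 6 Hz, alpha 10 Hz, beta 20 Hz)
with per-channel frequency jitter (±10 %) plus $1/f$-shaped noise. Group
structure enters through band amplitudes (e.g. an MCI alpha deficit) and
through convex coupling: selected channel pairs mix in a shared,
SD-matched, 10-sample-lagged pink source, so synchronization likelihood
rises monotonically with the coupling coefficient. The per-channel jitter
keeps the *uncoupled* SL baseline near $p_{\mathrm{ref}}$, which a shared
set of exact oscillator frequencies would inflate.

The generator's defaults (18 MCI vs 16 HC, 300 s at 256 Hz) mirror a
realistic small-cohort screening study; smaller problem sizes used in the
test suite are the package's own choices to keep runtimes bounded.

## Limitations

* The synthetic generator is a stationary linear-plus-noise model; it does
  not reproduce artefacts, non-stationarity, or volume conduction.
* Correlation dimension and Lyapunov estimates on short, noisy windows are
  biased; they should be read as comparative descriptors, not absolute
  invariants.
* The EDF reader/writer covers the plain 16-bit continuous EDF layout only
  (no EDF+ annotations).

## A minimal run

```{r example, eval = FALSE}
spec <- cohort_spec(n_mci = 6, n_hc = 6, duration_s = 60, fs = 128, seed = 1)
recs <- lapply(gen_cohort(spec), bandpass_filter)
segs <- unlist(lapply(recs, segment, window_s = 60), recursive = FALSE)
features <- assemble_features(segs, sets = "spectral")
cv <- lopo_cv(features, classifier = "LSVM", seed = 1)
glance(cv)
```
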