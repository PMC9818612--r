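---
title: "Multifractal gait stability: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifractal gait stability: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfgait)
```

## The problem

Gait is not a strictly periodic process. The coordinate of an anatomical
landmark recorded during walking fluctuates around its stride cycle in a
manner that is irregular across many time scales, and the degree and
structure of that irregularity carries clinical information: elderly
people at high risk of falling move less stably than their peers. mfgait
quantifies that instability per joint with multifractal detrended
fluctuation analysis (MF-DFA) and feeds the resulting per-channel
stability indices into group statistics and a fall-risk classifier
benchmark.

The data model is a 42-marker body calibration: 42 named anatomical
landmarks, each tracked in the sagittal (x), coronal (y) and transverse
(z) plane at 60 Hz, giving 126 scalar trajectories per subject
(`marker_model()`).

## MF-DFA and the D(alpha) stability index

For a series $\{x_i\}_{i=1..n}$ the analysis proceeds in five steps.

1. **Profile.** $X(k) = \sum_{i \le k} (x_i - \bar x)$ — the cumulative
   sum of the mean-centered series (`mf_profile()`).
2. **Local detrending.** The profile is cut into $L = \lfloor N/s
   \rfloor$ non-overlapping windows of length $s$; an OLS polynomial of
   degree $m$ (default $m = 1$) is removed per window, and the mean
   squared residual $F^2(s, v)$ retained (`mf_segment_rss()`). The
   default segmentation walks forward from the start and discards the
   tail remainder; a bidirectional option repeats the split from the end
   so no samples are lost.
3. **Fluctuation function.** $F_q(s) = \{\frac1M \sum_v
   [F^2(s,v)]^{q/2}\}^{1/q}$ for $q \ne 0$, with the logarithmic average
   $F_0(s) = \exp\{\frac{1}{2M}\sum_v \ln F^2(s,v)\}$ at $q = 0$ — the
   $q \to 0$ limit of the power mean (`mf_fq()`).
4. **Scaling.** $h(q)$ is the slope of $\log F_q(s)$ on $\log s$
   (`mf_hurst()`); $h$ constant in $q$ signals a monofractal series,
   $h$ decreasing in $q$ a multifractal one.
5. **Legendre spectrum.** $\tau(q) = q\,h(q) - 1$, $\alpha = d\tau/dq$
   (central finite differences on the $q$ grid), $f(\alpha) = q\alpha -
   \tau(q)$ (`mf_spectrum()`). The spectrum is the familiar inverted
   bell; its width $\Delta\alpha = \alpha_{max} - \alpha_{min}$ measures
   the strength of multifractality and $\Delta f = f(\alpha_{min}) -
   f(\alpha_{max})$ contrasts the dimensions of the extreme-fluctuation
   subsets.

The motion-stability statistic is the **arm asymmetry** of the spectrum
about its peak $\alpha_0$ (the $\alpha$ at which $f$ is maximal):

$$D(\alpha) = |\alpha_{max} - \alpha_0| - |\alpha_{min} - \alpha_0|.$$

A lower $D(\alpha)$ indicates a more stable trajectory. The source
formula for this index is typeset ambiguously in the literature this
package follows (the second absolute value is dropped); we implement the
arm-asymmetry reading, which is the only one consistent with "lower is
more stable" and with stability values of both signs, and expose the
literal variant behind `mf_summary(..., d_alpha = "printed")` for
comparison.

## Tunable parameters

* **Scales** — default ~20 geometrically spaced integers from
  $\max(16, m + 2)$ to $\lfloor n/4 \rfloor$. The lower bound keeps at
  least a handful of residual degrees of freedom per window; the upper
  bound keeps at least four windows per scale.
* **q grid** — default $-5$ to $5$ in steps of $0.5$, symmetric about 0.
  $\alpha_{min}/\alpha_{max}$ are finite-$q$ truncations of the ideal
  spectrum and therefore depend on the grid extent; every summary
  records the q range used.
* **Detrending order** — default 1 (MF-DFA1). The source work does not
  state its order; order 1 is the common default and is configurable.
* **Zero-residual windows** — exactly zero residuals make negative
  moments undefined. Default: exclude such windows from the mean and
  count them (`n_zero_dropped`); alternatively floor them at `1e-15`.

## The synthetic cohort generator

No public motion-capture cohort accompanies the source study, so the
package ships a generator whose contract is to realize the statistical
structure the analysis assumes — not biomechanical realism:

* **Quasi-periodicity.** Each channel is a ~1 Hz sinusoid whose
  amplitude and phase jitter independently from stride to stride
  (relative SD 0.1).
* **Multifractality with a stability dial.** The sinusoid's
  instantaneous amplitude is modulated by a canonical binomial
  volatility cascade with weight $a$: at every dyadic refinement each
  cell independently receives weight $a$ with probability 0.8 (the
  *branch bias*), else $1-a$. The bias skews the singularity spectrum to
  the right, so both $\Delta\alpha$ and $D(\alpha)$ grow monotonically
  with $a$; at $a = 0.5$ the cascade degenerates to a constant and the
  signal is monofractal. A conservative (mass-preserving) cascade
  without bias is symmetric in theory, and its MF-DFA estimate skews
  slightly the *other* way at finite length — the bias is what makes
  $a$ an effective one-parameter stability dial. This was verified by
  simulation during design and then frozen.
* **Groups.** Default cohort composition is 1 male + 8 female fallers
  and 17 male + 20 female nofallers (46 subjects), with cascade weights
  $a = 0.75$ (faller) and $a = 0.62$ (nofaller), 60 s recordings, and
  age/BMI drawn as truncated normals from the per-cell reference
  moments (the lone male faller keeps his reference covariates 73 y,
  24.3 kg/m²). Channels are seeded per (subject, serial), so any subset
  of channels reproduces exactly the values it would have in a full run.

What the generator does **not** emulate: inter-marker kinematic
coupling (channels are independent), gait events, drift, sensor
dropout, or the absolute scale of real marker coordinates. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline
recovers known structure from signals *with that structure*, not that
real cohorts separate this way.

With these defaults the synthetic group means of the posture-stability
scalar (mean $D(\alpha)$ over channels, plane-mean then joint-mean) land
around 0.3 for fallers vs 0.2 for nofallers — ordered as in the
reference cohort though lower in absolute level, which is expected: the
absolute level of $D(\alpha)$ is driven by the modulation depth and the
finite q grid, and only its ordering is the generator's contract.

## Group statistics

Per-channel faller-vs-nofaller comparisons use two-sided
independent-samples t-tests, pooled variance by default (Welch
optional). No multiple-testing correction is applied to the raw
per-channel p column — mirroring the per-channel tables this package
models — but a Benjamini–Hochberg column is appended, clearly labelled.
The headline significance threshold defaults to 0.005. Baseline balance
(age, BMI) is checked with Wilcoxon rank-sum tests, exact for groups of
at most 10 without ties.

## Classifier benchmark

Six methods, hyperparameters fixed at their reference settings
(`classifier_spec()`):

* **L1/2 sparse kernel iteration** — authored in-package: a
  degree-2 polynomial-kernel expansion fit by proximal gradient descent
  with the half-thresholding operator of the $|\beta|^{1/2}$ penalty
  (closed-form threshold $(54^{1/3}/4)\lambda^{2/3}$), plus a hard
  top-3 support constraint per iteration. The Gram matrix is spectrally
  normalized so the fixed step 0.1 is stable; non-convergence flags the
  model instead of failing.
* **SVM** — polynomial kernel, degree 1, cost 0.01 (e1071).
* **GBDT** — 20 depth-5 regression trees, learning rate 0.1, squared
  error on ±1 targets, class by the sign of the prediction (xgboost).
* **RF** — 20 trees, depth capped via 32 leaf nodes, on features
  discretized into 32 equal-width bins (randomForest).
* **DNN** — one hidden layer of 4 ReLU units, Xavier init, minibatch
  SGD (lr 0.01, L2 0.01, batch 16, 30 epochs); hand-written because the
  reference configuration (ReLU + Xavier + minibatch SGD) is not
  exposed by the installed fitters.
* **RNN** — a minimal ReLU recurrent cell (4 hidden units) consuming
  the feature vector as a scalar sequence in serial order, full BPTT
  with gradient clipping at ±1 for stability; same optimizer settings.

The evaluation protocol is explicit (`eval_protocol()`):
*resubstitution* (evaluate on the training data — optimistic, but the
natural reading of perfect reported scores on a 46-subject cohort),
seeded *stratified k-fold*, or a stratified *holdout*. Benchmarks always
include the three constant-predictor reference rows. RMSE is computed on
hard 0/1 predicted labels, which makes it $\sqrt{1 - \text{accuracy}}$
and zero exactly when accuracy is perfect.

## Numerical choices and degenerate inputs

* Residuals per window come from one QR decomposition of the shared
  Vandermonde design, applied to all windows at a scale at once.
* $\alpha$ uses three-point central differences in the interior of the
  q grid and one-sided differences at its ends.
* A spectrum with all $\alpha$ equal (within 1e-12) is flagged
  monofractal and summarized as $\Delta\alpha = D(\alpha) = 0$.
* Channels both-groups-constant-and-equal yield $t = 0, p = 1$;
  constant-but-unequal zero-variance channels are an error.
* Degenerate (zero-denominator) precision/recall are defined as 0.
* All stochastic components (generator, fold assignment, network
  initialization) run on seeds derived from a single master seed by
  seeded integer draws, so every stage is reproducible in isolation.

## Problem sizes used in the shipped checks

The package's own verification uses cohorts of 46 subjects at 60 s /
60 Hz on a 12-channel subset for the group-separation and
classifier-ordering simulations (5 cohort seeds), the full 126-channel
extraction at 20 s for structural checks, cascades of 2^12 samples and
fGn of 4096 samples for the estimator oracles. These sizes were chosen
to give stable Monte-Carlo summaries while keeping a full verification
run in the minutes range on a single core.

## Known limitations

* $\alpha_{min}$, $\alpha_{max}$, and hence $D(\alpha)$ depend on the
  finite q grid; comparisons are only meaningful at a fixed
  configuration (which the feature extractor records as provenance).
* Negative-q moments are noisy on short series; the default scale cap
  $n/4$ limits but does not remove this.
* The generator's channels are statistically independent, so
  channel-level significance patterns (which real anatomy would
  correlate) are exchangeable across serials.
* The RNN at its reference settings is a weak learner on static
  126-vectors; it is included for benchmark completeness, not as a
  recommendation.
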