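---
title: "Neural congruency of fixation-related potentials: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural congruency of fixation-related potentials: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrnc)
```

## The problem

Serial rapid automatized naming (RAN) asks a child to name a matrix of
letters aloud, left to right, as fast as possible. Because the reader
self-paces, there are no experimenter-controlled stimulus onsets, and
classical event-related-potential averaging cannot be applied to the
EEG recorded during the task. The eye-tracker, however, provides a
natural set of time-locking events: fixation onsets. An EEG epoch cut
around each fixation is a single-trial fixation-related potential
(sFRP).

`rrnc` implements a correlated-component analysis of these sFRPs built
on the *neural congruency* hypothesis: children who have mastered the
task produce fixation-locked neural activity that is similar
(congruent) across individuals, while children with reading
difficulties deviate from that stereotypical response. The package
extracts the spatial projections along which a reference group of
typical readers (chronological-age controls, CAC) is maximally
inter-correlated, scores every participant's congruency with that
group, and aggregates the scores into group-discrimination metrics
with permutation-based inference.

## Model

For participant $s$ and one task condition, the baseline-corrected
sFRP epochs are horizontally concatenated into $X_s \in
\mathbb{R}^{D \times N}$ ($D$ channels, $N = T \cdot F$ samples).
Cross-covariances between participants $i, j$ are

$$R_{ij} = \tfrac{1}{N} X_i X_j^\top ,$$

and for a reference group $\mathcal{S}$ of size $S$ the pooled
between- and within-subject covariances are

$$R_b = \frac{1}{S(S-1)} \sum_{i \neq j} R_{ij}, \qquad
  R_w = \frac{1}{S} \sum_{i} R_{ii}.$$

A spatial filter $w$ scores the group congruency ratio
$\rho(w) = (w^\top R_b w)/(w^\top R_w w)$; its maximizers are the
eigenvectors of the pencil $(R_b, R_w)$,

$$(R_w^{-1} R_b)\, w_k = \lambda_k w_k,$$

with $\lambda_k = \rho(w_k)$ sorted descending. A participant's
congruency with the group along component $k$ is the RRNC score

$$\mathrm{RRNC}_{s,k} =
  \frac{w_k^\top R_{sb}\, w_k}{w_k^\top R_{sw}\, w_k}, \qquad
  R_{sb} = \tfrac{1}{S}\sum_i (R_{si} + R_{is}), \quad
  R_{sw} = \tfrac{1}{S}\sum_i (R_{ss} + R_{ii}).$$

The denominator is the pooled within-covariance of the subject and the
group; it normalizes the between-covariance numerator the same way
$\rho$ is normalized, so a participant identical to every group member
scores exactly 1 and an independent participant scores 0 in
expectation. Spatial filters are not interpretable as topographies;
the forward model $a_k = R_w w_k / (w_k^\top R_w w_k)$ is, and is what
the package exports for scalp maps. Temporal profiles are grand
averages of $w_k^\top \mathrm{sFRP}(t)$.

### Numerical realization

* **Whitening.** $R_b$ is symmetrized and the pencil solved as the
  symmetric eigenproblem $R_w^{-1/2} R_b R_w^{-1/2}$, guaranteeing
  real eigenvalues.
* **Shrinkage.** Average-referenced data make $R_w$ rank $D-1$;
  $R_w \leftarrow (1-\gamma) R_w + \gamma\,(\mathrm{tr}\,R_w / D)\,I$
  with $\gamma = 0.05$ by default. $\gamma$ is a configuration knob;
  the exported eigenvalue spectra make its effect visible.
* **Common-mode guard.** The average-reference common mode has exactly
  zero variance in both $R_b$ and raw $R_w$. With small reference
  groups $R_b$ acquires negative eigenvalues and the common mode
  ($\lambda = 0$) would otherwise enter the top $K$ with an undefined
  0/0 score; the solver ranks only directions carrying raw
  within-subject variance.
* **Sign and scale.** Filters are unit-norm with the sign fixed so the
  largest-magnitude forward-model entry is positive.
* **Normalizer.** $N$ is used as the covariance normalizer; any
  constant cancels in every ratio the method computes.

## Preprocessing and epoching conventions

Recordings are re-referenced to the average channel, high-passed at
0.5 Hz (4th-order Butterworth, zero-phase, realized as cascaded
biquads; per-channel DC is removed exactly beforehand since the
zero-phase filter pads with zeros) and notch-filtered at 50 and 100 Hz
(2 Hz-wide band-stops). Each condition segment spans 2 s before the
stimulus onset to 2 s after the trial end and is baseline-corrected by
the channel means of $[-200, 0)$ ms.

Epochs use the half-open window $[-200, 500)$ ms: sample offsets $k$
with $-0.2 f_s \le k < 0.5 f_s$, an unambiguous integer count at any
rate (179 samples at 256 Hz; baseline sub-window 51 samples). Fixation
onsets are mapped to the nearest EEG sample. Epochs whose window
crosses a segment boundary are dropped and counted. Because $R_{ij}$
requires equal column counts, every participant is truncated to the
group-wide minimum epoch count per condition, keeping the earliest
epochs; the truncation count is reported in the run manifest.

## Group metrics

**Cumulative metric.** $\text{C-RRNC}_s = \sum_{k=1}^{\hat K}
\mathrm{RRNC}_{s,k}$ with $\hat K = 3$, the knee of the eigenvalue
spectrum; the exported `lambdas.csv` provides the knee diagnostics.
Feature vectors for this metric follow the leave-self-out rule: a
reference-group member is scored against components extracted from the
remaining members.

**LASSO-weighted metric.** A sparse ($\ell_1$-penalized) logistic
regression on the top $K = 10$ congruency scores, under
leave-one-participant-out cross-validation that is *fully nested*: for
each held-out participant, component extraction, every training
participant's features, feature standardization, and penalty selection
(stratified 5-fold inner cross-validation minimizing binomial
deviance) are all computed on the cohort with the held-out participant
removed. The nesting matters: with a single shared reference group the
held-out participant's data leak into the training features, and null
cohorts showed a substantial optimistic AUC bias until the scheme was
nested. Inner folds are assigned by deterministic stratified
round-robin so the whole pipeline is reproducible without consuming
RNG state.

The reported decision value is the linear predictor $x^\top \beta$
*without* the training-fold intercept. Under leave-one-out the
intercept equals the training-fold log-prevalence, which moves
opposite to the held-out label and injects a label-dependent offset
into otherwise uninformative scores; dropping it leaves the ranking
information untouched and makes the null behavior clean (an all-zero
coefficient fit scores everyone identically, AUC 0.5).

The penalized path is solved by a compiled IRLS/coordinate-descent
routine (`lasso_logistic_path`) with warm starts and saturation-based
path stopping; the permutation test refits it hundreds of thousands of
times, which is why it is compiled. Its coefficients are cross-checked
against an established penalized-regression package in the test suite.

**Inference.** AUC is computed by the Mann–Whitney midrank identity
(probability a random control outranks a random case, ties counted
one half). The permutation test permutes group labels and re-runs the
entire nested pipeline — component extraction from the permuted
reference set onward — per permutation;
$p = (1 + \#\{\mathrm{AUC}_\pi \ge \mathrm{AUC}\}) / (n_\pi + 1)$.
The default is 1,000 permutations; publication-grade inference
would typically use 10,000. Group-by-grade effects use a two-way ANOVA with Type II sums
of squares (robust to mild imbalance); the four task conditions form a
2×2 within-subject design (modality: rime vs. visual; confusability:
confusable vs. non-confusable) analyzed by univariate repeated-measures
ANOVA with participant error strata.

## The synthetic cohort

The study's dataset is not deposited, so the package ships a
first-class generator of co-registered EEG and fixation streams
(`cohort_config()`, `generate_cohort()`):

* **Fixation trains.** Inter-fixation intervals are Gamma distributed
  (strictly positive, right-skewed, as reading fixations are) with
  mean 350 ms and CV 0.3 by default, quantized to the 1 kHz eye-tracker
  grid; one fixation per letter over a five-row, ten-column matrix.
  The durations of the four condition segments vary per participant
  around `letters_per_matrix * mean_ifi` (CV 0.15), as self-paced
  reading does.
* **Planted sources.** Three Gaussian-envelope waveforms (100 ms / 4 µV,
  170 ms / −3 µV, 300 ms / 2 µV) patterned on the visual
  evoked-response sequence, mixed through orthonormal unit spatial
  vectors shared by all participants — this shared mixing is what
  makes the cohort congruent. Group membership scales the source gain
  (`congruency_gain`) and the per-fixation Gaussian latency jitter
  (`latency_jitter_sd`, 12 ms default, rounded to the EEG grid); grade
  may optionally modulate gain to plant a grade effect.
* **Noise.** Gaussian, spatially correlated through an exchangeable
  correlation (0.3) across channels, temporally white, 5 µV SD. The
  method operates on broadband epochs, so temporal noise color is not
  modeled.
* **Events.** Condition start (stimulus onset) and end markers are
  embedded in the recording's event table; the fixation log carries
  absolute timestamps on the shared clock, and alignment happens the
  same way it would with real co-registered data (condition windows
  from the EEG markers).

What the generator deliberately does *not* emulate: ocular and
myogenic artifacts, saccadic spike potentials, overlap-corrected
deconvolution of adjacent fixation responses (adjacent epochs overlap,
as in real reading — the analysis sees that overlap), realistic scalp
topographies tied to a head model, and condition-specific neural
differences. Passing tests on this cohort therefore demonstrate the
estimator's correctness and power under controlled congruency
differences, not robustness to real-world artifact structure.

## Validation problem sizes

The test suite validates, among others: eigensolver agreement with an
adaptive random-search maximization of $\rho$ (100 random pencils at
$D = 4$, 10⁵ candidate vectors each); recovery of a single planted
source's mixing vector by the top forward model ($|r| \ge 0.95$,
$\lambda_1/\lambda_2 \ge 3$; 12 controls, 32 channels); RRNC endpoint
values; discrimination of a 15-vs-15 cohort with control gain 1.0
vs. case gain 0.5 (AUC ≥ 0.80); permutation calibration on 50 null
cohorts (4 per group, 12 channels, 20 letters per matrix, 200
permutations each — sizes chosen once for the full-refit permutation
cost); exact leave-one-out hygiene (bit-identical bases and training
folds under perturbation of the held-out participant); and bit-level
run-to-run reproducibility. The acceptance script analyzes a
12-vs-12, 32-channel, four-condition cohort with 199 permutations per
condition.

## Known limitations

* RRNC scores are ratios of covariance quadratic forms, not bounded
  Pearson correlations; the printed-ratio form of $\rho$ (no square
  root in the denominator) is implemented as published.
* The nested classifier needs at least four reference-group members.
* With few reference members, eigenvalue spectra are strongly overfit
  ($\lambda_1$ inflation); the leave-one-out protocol protects the
  scores but not the spectra themselves.
* Per-condition processing is independent; the repeated-measures
  ANOVA is the only stage that sees all four conditions jointly.
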