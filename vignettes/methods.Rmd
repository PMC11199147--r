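---
title: "Methods: single-unit tuning and population decoding of internal speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-unit tuning and population decoding of internal speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(innerspeech)
```

## The task and data model

The package analyses single-unit recordings from a cued word-production
task. Each trial walks through six fixed phases — an inter-trial interval
(ITI, 2 s), a cue (1.5 s, auditory or written), a first delay (D1, 0.5 s),
an internal-speech phase (1.5 s) in which the participant says the cued
word silently, a second delay (D2, 0.5 s), and a vocalized-speech phase
(1.5 s). The vocabulary contains six lexical words and two pseudowords
(battlefield, cowboy, python, spoon, swimming, telephone, bindip, nifzig),
the pseudowords probing phonetic rather than semantic encoding. Units come
from two areas with very different expected behaviour: supramarginal gyrus
(SMG), where single units are word-selective, and primary somatosensory
cortex (S1), which modulates during overt speech but carries no word
identity.

All times are seconds, trial-relative, zero at ITI onset, with half-open
phase intervals `[onset, offset)`. Trials on which the participant spoke
during the internal phase or vocalized the wrong word are kept in the
archive and removed only at analysis time (`exclude_error_trials()`), so
the stored data remain a complete record. The on-disk session archive is a
directory of plain-text files — `config.json`, `trials.csv`, `units.csv`
and a long-format `spikes.csv` — chosen over a binary container so that
archives stay diffable, language-neutral and round-trip bit-exactly for
labels and to full double precision for spike times.

## The synthetic-session generator

Real sessions of this task are not required by any analysis here; instead
`sample_population()` and `simulate_session()` generate sessions with
known ground truth, and every downstream stage is validated by parameter
recovery. The generator is deliberately minimal:

* each unit is an inhomogeneous Poisson process whose rate is piecewise
  constant within phases: a baseline (gamma-distributed across units,
  default mean 5, SD 2 spikes/s — typical cortical single-unit rates),
  plus an additive word-by-phase gain for tuned units, plus an additive
  cue-modality gain during the cue phase;
* tuned SMG-like units receive gain `|N(4, 1.5)|` spikes/s on a random
  subset of words (each word with probability 0.5, at least one) in the
  phases where they are tuned; default tuned fractions are 0.3 (cue), 0.3
  (internal) and 0.5 (speech), echoing the observed ordering in which
  vocalized speech recruits the most units;
* S1-like units receive one word-*agnostic* gain, in the speech phase
  only — they are loud but uninformative about word identity;
* on auditory trials the audio onset is drawn uniformly from 200–650 ms
  after cue onset and cue-phase gains begin at audio onset;
* rates are additive (not multiplicative) so that effect sizes are
  directly interpretable in spikes/s against baseline; sums below zero are
  clipped at zero and the clips counted;
* trial order is a single seeded permutation of the full
  words x modalities x repetitions list (8 repetitions per word and
  modality by default, 16 for single-modality sessions emulating the
  longer protocol).

What the generator does *not* emulate: within-phase response dynamics
(onset transients, ramps), spike-history structure (refractoriness,
bursting), correlated noise across units, and electrode nonstationarity.
Passing tests therefore certify the *analysis machinery* — estimator
correctness, calibration, leakage-freedom, recovery of injected structure
— not that real SMG data will reach any particular accuracy.

## Firing-rate estimation

Rates are spike counts in 50-ms bins divided by the bin width, then
smoothed with a normalized Gaussian kernel. The kernel "width" of 50 ms is
interpreted as the Gaussian standard deviation — the most common
convention — truncated at ±4 SD and renormalized; the choice is isolated
in one constant. Edges use reflection padding so constant signals pass
through unchanged and no spurious rate dips appear at trial boundaries.
Smoothing is applied to the whole trial before any phase slicing, and
audio-onset alignment (`align_to_audio_onset()`) happens after smoothing:
alignment re-sorts cue-phase bins per trial, and smoothing first keeps the
kernel acting on contiguous physical time. Because per-trial shifts
differ, the trailing `max(shift)` cue bins fall outside common coverage
and are trimmed from all trials to keep the tensor rectangular.

## Word tuning

A unit's tuning is defined against its own ITI baseline through the
indicator regression

FR = Σ_w β_w X_w + β_0,

fit per unit either per 50-ms bin or on phase-averaged rates. A
W-indicator design with a free intercept is rank-deficient, so each fit is
augmented with the same trials' ITI rates as reference observations (all
indicators zero). With balanced data this anchors β_0 to the mean ITI rate
and makes β_w exactly the firing-rate change from baseline for word *w*
(the package verifies this against a normal-equations oracle).

The t-statistic divides β_w by its standard error. One numerical choice
matters here: task phases differ in duration (0.5-s delays vs the 2-s
ITI), so phase-averaged rates have unequal sampling variance across the
two sides of the contrast, and a fully pooled residual variance is
anti-conservative in the short phases (simulations with zero effect size
showed 11–20% of units flagged at the nominal 5%). The package therefore
pools the residual variance across word cells *within* the phase — exactly
the regression model's own variance, with W·(n−1) degrees of freedom — and
combines it with the ITI reference variance in Welch form with
Welch–Satterthwaite degrees of freedom. Under zero-effect simulations this
calibrates the per-phase flag rate to ≈5%; the acceptance suite checks it
across 200 null sessions. Per-word p-values are Benjamini–Hochberg
adjusted within each unit's W coefficients (the FDR family is per unit and
per bin/phase), and a unit is *tuned* when at least one adjusted p-value
is below 0.05. Degenerate (zero-variance) units are reported untuned with
p = 1 rather than dropped.

The Kruskal–Wallis alternative asks a different question — whether rates
*differ between words*, with no baseline involved — through
`stats::kruskal.test`, adjusted across units within each phase. Session
summaries average the tuned percentage across sessions with the Student-t
95% interval (multiplier `qt(0.975, n−1)`), and rest-vs-action phase
pairs — (ITI, cue), (D1, internal), (D2, speech) — are compared by paired
two-tailed t-tests with paired Cohen's d defined as mean(difference) /
SD(difference), the simplest convention consistent with a paired design.

## Word decoding

Phase-wise decoding uses phase-averaged rates (trials x units, one matrix
per phase). In each leave-one-out fold, the *entire* pipeline is refit on
the training trials: data are centered, PCA components are kept up to the
smallest count whose cumulative variance share strictly exceeds 95%, and a
linear discriminant model with one mean per word, a single shared
covariance and equal priors is fit in that space. The held-out trial never
touches the centering, the rotation, or the covariance (a property test
corrupts held-out features and asserts the fold model is unchanged). When
the pooled covariance is ill-conditioned (training rows per residual
degree of freedom not exceeding the feature count) it is shrunk toward a
scaled identity with the analytic Ledoit–Wolf intensity; posterior ties
break deterministically toward the earliest class in the configured word
order. When both cue modalities are present their trials are pooled into
one decoding set, matching how the offline analyses concatenate the two
cue types.

Significance uses shuffle nulls: the full LOO classification is repeated
with labels permuted within the session (class counts preserved), 100
times for offline analyses; accuracy above the null's 97.5th/99.5th
percentile is graded P &lt; 0.05 / P &lt; 0.01. For balanced classes the
null mean sits at the analytic chance level 100/W% (12.5% for eight words,
25% for four) — the acceptance suite requires recovery of both.

Cross-phase decoding reuses the same LOO folds: the fold model is trained
on the training phase's rows of the training trials and applied to each
test phase's row of the held-out trial. This makes train-on-A/test-on-A
*exactly* equal to within-phase LOO decoding and rules out same-trial
leakage by construction. The online protocol is simulated faithfully but
offline: a decoder trained on the internal-phase rates of an initial
written-cue block classifies each trial of a run once, the run is added to
the training set, and the decoder is retrained (simple accumulation, no
recency weighting — the protocol adds newly recorded data and says no
more). The accounting report converts training set size to seconds of
internal-speech data per word (16 trials x 1.5 s = 24 s); online-style
shuffle grading uses 1,000 repetitions when enabled.

## Demixed PCA

The trial tensor `X[n, t, c, w, k]` (neurons x time x cue modality x word
x repetition) must be balanced; error trials are therefore replaced by the
average firing rate of the cell's remaining k−1 valid trials rather than
discarded. The tensor is decomposed exactly into a per-neuron mean, a
timing term, grouped cue terms, grouped word terms, a grouped cue x word
interaction and trial-to-trial noise, by classical factorial-ANOVA nested
averaging; pure task terms are grouped with their time interactions since
every component is expected to vary with time. Reconstruction is exact to
machine precision and the parts are mutually orthogonal under the balanced
design, so variance shares (reported per marginalization, with noise) sum
to one.

Encoders F and decoders D minimize ‖X_φ − F·D·X‖² + μ‖F·D‖² with
μ = (λ‖X‖)², where X is the trial-averaged, per-neuron mean-centered data
matrix and ‖·‖ the Frobenius norm (the norm is otherwise unspecified;
Frobenius makes μ scale with total signal energy). The solution is the
closed-form reduced-rank ridge: full-rank ridge solve, then rank-q
truncation through the SVD of the fitted values, implemented with a
symmetric pseudoinverse so λ = 0 remains defined on rank-deficient data.
At λ = 0 with all structure in one marginalization the decoder subspace
coincides with the PCA subspace — the package's analytic cross-check.
Encoder columns are orthonormal with scale absorbed into D (the product is
what the loss sees). q defaults to 3 components per marginalization —
plots typically use only the top component, and 3 leaves headroom without
inviting rank problems in small populations. λ is selected by tenfold CV
with folds stratified within (modality, word) cells (capped at the
repetition count when k &lt; 10), scoring held-out marginalization
reconstruction error summed over marginalizations.

One caveat for interpreting variance shares: with k repetitions, the
trial-averaged noise does not vanish and a share of roughly (W−1)/(W·k) of
pure noise lands in the word marginalization. "Near zero" word variance
for S1-like populations is therefore assessed at k = 16 against that
floor, and relative to the SMG-like share, rather than as an absolute
zero.

## Problem sizes and reproducibility

The test and acceptance suites use synthetic sessions of 8–16 repetitions
x 8 words with 10–40 units — enough for every statistical property to be
measured at useful precision while keeping full runs lightweight.
Calibration checks use 200 zero-effect sessions (2,000 unit-phase
decisions per phase); chance-level recovery uses 100 label shuffles per
the offline protocol. All randomness flows from explicit seeds; the
pipeline derives one seed per stage from a master seed by a fixed counter
scheme, so toggling a stage never perturbs the others.

## Known limitations

* The generator's piecewise-constant rates cannot test latency estimation
  or within-phase dynamics; none is attempted.
* Sorted versus multiunit activity is carried only as a metadata label;
  all unit ids are treated uniformly.
* dPCA variance shares are not noise-corrected (see the caveat above) and
  no significance testing of dPCA components is provided.
* The online simulation is a faithful protocol replay, not a real-time
  system: no hardware loop, feedback rendering or audio capture.
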