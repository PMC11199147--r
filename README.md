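# innerspeech

Single-unit tuning and population decoding of internal (silent) speech.

Microelectrode recordings in human supramarginal gyrus (SMG) show that
single neurons modulate their firing when a participant merely *thinks* a
word, and that the thought word can be decoded from the population —
while primary somatosensory cortex (S1) is active only during overt
vocalization and carries no word identity. This package implements, as
tested and reusable R code, the complete single-unit analysis chain
behind such a result, for anyone working with trial-structured
electrophysiology of a cued word-production task:

* a validated session model (task configuration, trial table, per-unit
  spike timestamps) with a plain-text CSV+JSON archive and error-trial
  handling;
* a synthetic-session generator — inhomogeneous Poisson units with known
  word-by-phase gain structure — so that every stage is verifiable by
  parameter recovery;
* firing-rate estimation: 50-ms binning, Gaussian smoothing (50-ms SD
  kernel), audio-onset alignment, phase averaging;
* word tuning: per-unit indicator regression against the ITI baseline,
  `FR = Σ_w β_w X_w + β_0` with `β_0` anchored to the mean ITI rate and
  `β_w` the rate change from baseline for word *w*; t = β/SE with
  FDR-adjusted p-values (tuned ⇔ some adjusted p < 0.05); a
  Kruskal–Wallis alternative; session summaries with Student-t confidence
  intervals; rest-vs-action phase comparisons; tuning-overlap statistics;
* word decoding: PCA features (components up to >95% cumulative
  variance) + linear discriminant analysis with a shared covariance and
  equal priors, leave-one-out cross-validation, shuffle-label
  significance (accuracy above the null's 97.5th/99.5th percentile ⇒
  P < 0.05 / P < 0.01), cross-phase generalization, and a simulated
  closed-loop online decoder with incremental retraining;
* demixed PCA: exact marginalization of the trial tensor
  `X[n, t, c, w, k]` into timing / cue-modality / word / interaction /
  noise parts, reduced-rank ridge encoder–decoder fits minimizing
  `‖X_φ − F_φ D_φ X‖² + μ‖F_φ D_φ‖²` with `μ = (λ‖X‖)²`, tenfold-CV
  selection of λ, variance ledger and decoder-axis projections;
* a one-call pipeline (`run_pipeline()`) with deterministic per-stage
  seeding and a plain-text report, plus a thin CLI wrapper in
  `inst/scripts/run_pipeline.R`.

See `vignettes/methods.Rmd` for the statistical model, the numerical
choices and their rationale, and known limitations.

## Worked example

Simulate one SMG-like session (30 units, 8 repetitions of 8 words,
written cue), then run tuning, decoding and dPCA:

```r
library(innerspeech)

cfg   <- task_config()                      # phases, words, 50-ms bins
pop   <- sample_population(population_spec(n_units = 30), cfg, seed = 1)
sim   <- simulate_session(pop, cfg, n_reps = 8,
                          cue_modalities = "written", seed = 2)
rates <- smooth_rates(bin_spike_counts(sim$spikes, sim$trials, cfg),
                      cfg$kernel_width)

tuning <- fit_word_regression(rates, sim$trials, "per_phase")
round(100 * colMeans(tuning$tuned), 1)
#>      ITI      cue       D1 internal       D2   speech
#>      0.0     30.0      6.7     36.7      3.3     53.3

pr <- phase_average(rates, sim$trials)
loo_cv_decode(pr, "internal", classes = cfg$words)
#> LOO decoding [internal]: 50.0% (64 trials, 30 units)

sh <- shuffle_significance(pr, "internal", n_shuffles = 100, seed = 3,
                           classes = cfg$words)
#> null mean 12.5%, 99.5th pct 22.7%, grade P<0.01

tens <- build_balanced_tensor(rates, sim$trials)
vp   <- variance_and_projections(fit_dpca(tens, lambda = 1e-6), tens)
round(vp$variance_shares, 3)
#>   timing      cue     word cue_word    noise
#>    0.035    0.000    0.133    0.000    0.832
```

Reading the output: about a third of the units are word-tuned during
internal speech and half during vocalized speech, while the rest phases
sit at the false-positive floor; the eight words are decoded from the
internal-speech phase at 50% against a 12.5% chance level (the shuffle
null mean), far above the null's 99.5th percentile; and the word
marginalization carries the dominant task-related share of population
variance. An S1-like population (`population_spec(area = "S1", ...)`)
instead yields chance-level word decoding in every phase and a word
variance share at the noise floor.

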