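---
title: "Word-property analysis of verbal fluency: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Word-property analysis of verbal fluency: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluprop)
```

## The problem

Verbal fluency tasks ask a participant to produce as many words as possible
in one minute, constrained by an initial phoneme (phonemic fluency) or a
semantic category such as animals (semantic fluency). The standard score —
the count of valid responses — is sensitive to many dementias but not
specific to any of them. `fluprop` implements a complementary
*word-property* analysis: every uttered word is decomposed into six
psycholinguistic variables, and each variable's distribution over a
participant's output becomes a feature vector for group-level statistics,
subject-level classification and brain–behavior correlation. In
Alzheimer's-type profiles the interesting signal is a drift toward the most
accessible regions of the lexicon: words that are more frequent, less
granular (conceptually coarser) and phonologically better connected.

## Word properties

For a word form the package resolves:

* **frequency** — log10 occurrences per million tokens, taken from a
  user-supplied lexicon table (e.g. an EsPal export);
* **granularity** — the number of edges on the shortest hypernym path from
  the word's concept node to the taxonomy root `"entity"`. We count *edges*
  rather than "nodes between" because the latter is ill-defined for direct
  children of the root; a direct child has granularity 1. Polysemy is
  resolved by the minimum depth over senses (deterministic and requiring no
  disambiguation model); `granularity(..., senses = "max"/"first")` switches
  the rule.
* **phonological neighborhood** — the number of lexicon entries whose
  phoneme sequence differs by exactly one substitution, insertion or
  deletion (no transpositions). Entries lacking phonemes are compared on
  graphemes, announced once per lexicon; Spanish-like grapheme–phoneme
  regularity makes this fallback serviceable.
* **length** — number of phonemes;
* **familiarity**, **imageability** — 1–7 normative ratings from the
  lexicon.

Lookups are keyed on lowercased, accent-stripped forms since orthographic
mismatch between transcripts and lexicons is the dominant failure mode.
Words missing a value for some property are ignored *for that property
only*; missingness is tallied per participant so that group comparability
of missing data can itself be tested with the same ANCOVA machinery.

Each property is summarised per participant by seven distributional
statistics: mean, median, SD (n−1), min, max, moment skewness
(g1 = m3/m2^1.5) and excess kurtosis (g2 = m4/m2² − 3). The
bias-uncorrected moment estimators are the simplest convention; skewness
and kurtosis are undefined (missing) below n = 3 or at zero variance. Six
properties × seven statistics give the 42-column feature block; by default
both tasks' responses are pooled before summarisation (42 columns total,
matching the multivariate classifier input), while
`task_mode = "per_task"` yields 42 per task for the task-resolved group
statistics.

## Scoring and trimming

Validity flags follow the standard instructions: repetitions (exact
normalized duplicates within participant × task), tokens containing
digits, and a study-specific list of invalid tokens (proper names and
morphological family variants are examiner judgments in real studies, so
they enter as a list rather than an automated language model).
Unintelligible markers are excluded from *all* property analysis.
The primary featurization keeps valid and invalid (intelligible) words;
robustness variants drop invalid words, and additionally drop word-level
values beyond 3 SDs of the participant group's values. The trimming SD is
computed leaving the candidate value out — with the plain group SD a
single gross outlier inflates the scale enough to mask itself (e.g. 100
among {1,1,1,1} sits within 1.8 plain SDs but is removed under
leave-one-out).

## Group statistics

Each outcome (valid counts, per-task property means) enters a 2 × 2 mixed
ANCOVA: group (between) × task (within), with additive sex, age and
education covariates and no covariate × factor interactions. The model is
fitted by its exact two-stratum decomposition: between-subject effects on
subject task-means (Type III via model comparison), within-subject effects
on task differences, where additive between-subject covariates cancel
algebraically. Partial eta squared is computed from the stratum sums of
squares (SS_effect / (SS_effect + SS_error)), never back-derived from F.
Sum-to-zero contrasts keep main effects interpretable with unbalanced
groups. Post-hoc cell contrasts use Tukey–Kramer studentized-range
p-values with pooled-SD Cohen's d; the classical procedure ignores the
within-subject dependence of task cells, which is acceptable for the
descriptive role post-hocs play here.

## Classification

Subject-level discrimination uses iterated stratified 5-fold
cross-validation: per iteration a fresh random partition preserving label
proportions; per fold a min–max scaler and a K-nearest-neighbor imputer
(K = 5, uniform weights, nan-Euclidean distance over mutually observed
coordinates) fitted on the training folds only and applied to the test
fold (test values clipped to [0, 1]); then an L2 logistic model with the
pinned defaults — penalty strength C = 1, fitted unpenalized intercept, no
internal standardization — so behavior does not drift with library
defaults. Fitting scaler and imputer inside the training folds is the
leakage-free choice; out-of-fold probabilities are pooled within each
iteration before computing AUC (stabler than per-fold AUCs at n ≈ 60).
Importances are mean absolute coefficients over all fold-level models;
per-subject output scores are averaged over iterations. One classifier is
run per property (7 features) plus one on all 42.

## Correlations

Executive-outcome batteries use Spearman correlations of each
group-discriminating measure with IFS scores, pooling one patient group
with controls to widen variance, and Benjamini–Hochberg FDR within each
battery (a battery is one `correlation_battery()` call, mirroring
per-analysis correction). The `auto` policy chooses Pearson only when
Shapiro–Wilk retains normality for *both* variables at α = 0.05 —
the conservative reading. Partial correlations residualize both variables
on the controls (ranks first for the Spearman variant), with degrees of
freedom n − 2 − k.

## EEG connectivity

Recordings are band-passed (default beta, 13–30 Hz) and cut into 1000-ms
segments. The default filter is a zero-phase frequency-domain mask with
raised-cosine 2-Hz transitions rather than a forward–backward IIR: the
mask adds no start-up transient, so an in-band periodic component passes
exactly and the analytic identity "constant phase difference ⇒ PLV = 1"
holds to machine precision (~1e-15), which the validation suite asserts at
1e-12. A forward–backward Butterworth (`filter_type = "butterworth"`)
remains available; its transients leave the same identity accurate only to
~1e-5 even after 400 ms of edge exclusion. Instantaneous phase comes from
the FFT analytic signal; the first and last 100 ms of each segment are
excluded from PLV to suppress residual edge effects.

PLV for a channel pair is the modulus of the time-averaged complex
exponential of the phase difference, averaged over segments — 0 for
unrelated phases, 1 for perfect locking, invariant to amplitude scaling.

Group comparison uses a cluster-based permutation test: per-edge two-sample
t-tests (pooled variance by default; Welch optional), edges significant at
p_con = 0.05 form a sensor graph whose connected components are clusters
scored by edge count. Clusters are formed from all supra-threshold edges
regardless of t sign (some implementations split by sign; with a planted
one-directional effect the two coincide). The null distribution of the
*maximum* cluster size over label permutations controls the family-wise
error; p-values use the (count + 1)/(n_perm + 1) convention so they are
never exactly zero at finite permutations. Per-subject mean PLV over a
significant cluster's edges feeds the correlation battery.

## Synthetic data

Because no participant data ship with clinical studies of this kind, every
stage is validated on synthetic cohorts with plantable effects.

* **Lexicon** — Zipf rank-frequency log frequencies over a configurable
  vocabulary (default 2000 words); familiarity and imageability are
  *linearly* coupled to standardized log frequency with a configurable
  correlation matrix (defaults 0.6 and 0.3), so sample Pearson correlations
  match the spec regardless of the frequency marginal; phoneme sequences
  are random consonant–vowel strings of length 2–9; the taxonomy is a
  uniform-attachment random tree (log-depth profiles, comparable to noun
  hierarchies); property values are deleted completely at random (default
  5%) to exercise the missing-data policy and the imputer.
* **Cohort** — group sizes, covariate and MoCA/IFS distributions default to
  a typical three-group dementia cohort (AD 32, bvFTD 32, HC 27; ages in
  the low-to-mid 70s; MoCA ≈ 15/18/26). Each patient draws a latent
  severity (mean 1, SD 0.3) that scales the count deficit, tilts word
  sampling, and drives cognitive scores (link 0.7). Words are sampled
  without replacement proportional to corpus frequency times
  exp(severity × Σ βp·zp(word)); each βp is calibrated by exact
  exponential-tilt inversion so the planted shift of the per-participant
  property mean equals the spec's effect size in units of the control
  group's between-participant SD (σ_word/√k for k-word lists). Default
  AD-like effects: frequency +0.8 SD in both tasks, granularity −0.6,
  neighborhood +0.8 in the semantic task only; the bvFTD-like group gets
  only a count deficit. Control response counts default to 14 (phonemic)
  and 19 (semantic) words, SD 4 — typical one-minute norms.
* **EEG** — every channel mixes a weak band-limited global source; a
  planted sensor cluster shares a stronger source whose mixing is reduced
  (default 50%) in the affected group. PLV rises monotonically with the
  mixing coefficient, so the cluster test should flag the planted set.

What the generator does *not* emulate: real lexical statistics (no
linguistically meaningful Spanish forms), serial-position and clustering
structure of fluency output, examiner adjudication noise, volume
conduction or artifacts in EEG. Passing the validation suite therefore
demonstrates that the *algorithms* behave as specified under known truth,
not that effect sizes transfer to clinical data.

## Numerical and design choices

* Exponential-tilt calibration solves m(β) − m(0) = target by
  `uniroot` on the π-weighted tilted mean; correlated properties spill
  planted shifts into their correlates (as real lexicons would), so
  importance-ranking validation uses an uncorrelated-property lexicon.
* Ridge logistic fits use `glmnet` at the single λ = 1/n matching C = 1,
  convergence threshold 1e-10, so fixed-seed runs are bit-reproducible.
* Degenerate inputs resolve to missing values (empty sequences, zero
  variance) rather than errors wherever a downstream summary can absorb
  them; hard errors are reserved for contract violations (unknown groups,
  non-consecutive positions, bands at or above Nyquist, fewer than two
  subjects per group).
* All randomness flows from explicit seeds; the pipeline derives stage
  seeds from one root seed.

## Validation problem sizes

The shipped suite calibrates type-I error of the group ANCOVA on 1000 null
cohorts of n = 30/group (rejection rate asserted in [0.03, 0.07]), checks
the null classifier AUC over 200 iterations on permuted labels
([0.4, 0.6]), and estimates the cluster test's family-wise error over 500
replicates of 16-channel, 10-vs-10 null connectivity sets at 200
permutations (asserted at-or-below the nominal 5%, as max-statistic
permutation control guarantees). Power checks use 200 replicates of the
default AD-like cohort (group-effect power > 0.8 for the 0.8 SD frequency
shift). These sizes were chosen so the whole suite reproduces the
calibration properties with small Monte-Carlo error on a single CPU.

## Limitations

Granularity depends entirely on the supplied taxonomy's shape; depths are
not comparable across taxonomies. The Tukey post-hocs treat group × task
cells as independent samples. The classifier pins "default" logistic
hyperparameters explicitly; results from libraries with other defaults
(different regularization, solvers with internal scaling) will differ in
the third decimal. Multiword responses and lemmatization are out of scope:
the lexicon key must match the transcript token after normalization.
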