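---
title: "Serum ESI-MS profiling with LOOCV/PCV classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum ESI-MS profiling with LOOCV/PCV classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seroclass)
```

## The model

`seroclass` implements a serum mass-peak profiling classifier for binary
clinical comparisons.  Its statistical object is not a single biomarker
but the *joint shift* of many unit-mass peaks between two groups: each
sample is reduced to a vector of normalized peak areas, each peak is
tested for a group difference, and a held-out sample is scored by the
fraction of discriminating peaks on which it resembles each group.  The
procedure assumes:

* peak areas on the unit-mass grid carry group signal after local
  normalization (absolute intensity is not comparable across
  injections, so only within-segment relative abundance is used);
* an absent peak is an informative zero — in a locally normalized
  spectrum the absence of signal at an m/z is a measurement, not
  missing data;
* samples are exchangeable within groups (no batch/run-order structure
  is modeled), and replicates differ from their sample's true profile
  only by multiplicative instrument noise.

## Preprocessing

1. **Nominal binning** (`nominal_bin`).  Acquired points are summed
   into unit-m/z bins at half-up-rounded m/z; the default grid is
   400–2000 inclusive (1601 bins), configurable for instruments with a
   narrower range.
2. **Segment normalization** (`segment_normalize`).  Each
   non-overlapping 25-m/z segment is scaled to a summed intensity of
   100 (`target_sum`).  All-zero segments are left as zeros: the scale
   factor is undefined there, and leaving them untouched preserves the
   mass-conservation bookkeeping.  The operation is idempotent, and the
   total normalized intensity equals 100 × (number of live segments).
3. **Centroiding** (`centroid_areas`).  The vector is partitioned at
   valleys — zero bins, plus strict local minima where an equal-valued
   plateau contributes its leftmost bin (a deterministic tie-break).  A
   valley bin opens the run to its right, so every bin belongs to
   exactly one run and the summed peak areas equal the summed spectrum
   intensity.  Each positive run becomes one peak keyed by the half-up
   rounded intensity-weighted mean m/z; peaks whose centers round to
   the same key are merged.
4. **Replicate averaging** (`average_replicates`).  The area at each
   m/z is the arithmetic mean over replicates with absent peaks counted
   as zero; means of zero are dropped.  Any replicate count ≥ 1 is
   accepted with a warning when it is not the conventional 3.

Whether centroiding should precede or follow normalization is not
determined by the platform's description; this package normalizes first
and then centroids, which makes peak areas directly comparable across
samples without a second scaling pass.

## Peak selection and PCV classification

For a cohort with groups A and B, every m/z observed anywhere in the
data is tested with an unequal-variance Welch *t*-test; the one-tailed p
is taken in the direction of the observed mean difference (p = two-tailed
/ 2), since no per-peak direction is pre-registered.  A peak is retained
iff `p < alpha` (default 0.05) **and** the larger group mean is at least
`floor_fraction` (default 0.003) of the maximum group-mean peak area
over all m/z — a dataset-level relative-abundance floor; letting either
group mean satisfy the floor keeps down-regulated peaks.  Degenerate
columns (zero variance in both groups) are skipped when the means are
equal and treated as p = 0 when they differ.

Each retained peak's **PCV** is the arithmetic midpoint of its two group
means — the platform's "midpoint" valuation, recorded here as an
interpretation since no closed formula accompanies the name.  A sample's
area strictly above the PCV classifies that peak to the higher-mean
group; at or below, to the other group (the boundary deliberately goes
to the lower group, making the rule deterministic).  The sample's score
`pct_a` is the percentage of peaks classified to group A; `pct_a +
pct_b = 100`.

`run_loocv` repeats this with each sample left out in turn, so no
sample's own areas influence the peak set or thresholds it is scored
against.  `build_full_pcv_set` uses all samples and is the reference for
blinded/external assignment.

## Distribution-level metrics

With group A the higher-scoring group on the % classified scale:

* multiplier `M = (mean_A − mean_B) / (SD_A + SD_B)`;
* cut-off lines `mean_A − M·SD_A` and `mean_B + M·SD_B`, which coincide
  algebraically when M is self-computed and generally cross when the
  true-pathology M is reused on randomized labels;
* Cohen's `d = (mean_A − mean_B) / sqrt((SD_A² + SD_B²)/2)` (RMS-SD
  pooling, which reproduces the published summary-table effect sizes);
* power from the noncentral *t* with noncentrality
  `d·sqrt(n_A n_B/(n_A+n_B))`, df `n_A+n_B−2`, two-sided alpha 0.05;
* confusion counts: a group A sample is TP at or above the A line and FN
  at or below the B line; a group B sample is TN/FP symmetrically.  When
  the lines are strictly crossed a sample between them counts in both
  categories at once (the randomized regime); with coincident or
  separated lines each sample counts once, and a sample exactly on a
  coincident line counts as correctly classified.  The same boundary
  logic makes `assign_external` tally an exactly-on-line external sample
  as "indeterminate" — a measure-zero event for continuous spectra.

The distribution-level Welch test is two-tailed by default (`tails`),
since unlike the peak-level tests no direction is specified for the
group comparison.

## Randomization control

`balanced_permutation` shuffles group labels within sex × age-tertile
strata — a reproducible surrogate for manually balancing a random
relabeling by gender and age — preserving group sizes exactly and sex
composition per group whenever the strata permit.  Strata too small to
permute (size < 2) trigger relaxation to sex-only strata, then to a
single stratum, each with a warning.  `run_randomized_loocv` repeats the
LOOCV on the relabeled cohort with each fold's peak list truncated or
extended to the true run's count (ranked by ascending p, relaxing the
significance threshold as needed — the minimal deterministic rule
consistent with matching the counts, applied per fold) and reuses the
true multiplier for the cut-off lines.

## Synthetic cohorts

Real patient sera for this platform are not publicly deposited, so
`simulate_cohort` generates the study conditions: triplicate unit-mass
spectra over 400–2000 for 15 vs 14 samples (the mild-AD-vs-control
sizes; a 16-vs-14 preset mirrors the moderate comparison), with
demographics drawn from the published ranges (ages 56–90 / 59–84,
5/15 and 7/14 male fractions).

The intensity model is log-normal throughout: non-negativity is
guaranteed and instrument noise in ESI is multiplicative.  Signal bins
(default `peak_density` 0.15 of the grid) sit on an every-other-m/z
lattice so each is an isolated valley-to-valley peak; their baseline
log-means are drawn once from N(`baseline_log_mean`, `baseline_log_sd`)
and shared across groups.  Between-sample biological variation is
log-normal with CV `sample_cv` (default 0.25 — a typical serum
biomolecule CV); the spec of the planted effect, `effect_delta`, is the
group A log-mean shift in units of the between-sample log-SD, which is
why a between-sample CV exists as an explicit parameter separate from
the replicate CV.  Replicate noise (CV `replicate_cv`, default 0.10) is
mean-one log-normal, so triplicate averaging is unbiased.  Defaults of
100 planted peaks at `effect_delta = 2` give per-peak Welch *t* values
near 5 and a % classified separation of ~8 pooled SDs — the regime in
which the platform attains 100% sensitivity and specificity.

What the generator does **not** emulate: isotope envelopes and charge
states, correlated peak families from shared peptides, run-order drift,
batch effects, and heavy-tailed contamination.  Passing tests on this
generator therefore demonstrate the correctness and internal calibration
of the algorithms, not clinical performance on real sera.

## Numerical choices

* Half-up rounding everywhere a printed convention exists (bin keys,
  centroid keys, hit ratios to one decimal, tally percentages to
  integers) via `round_half_up`, avoiding R's round-half-to-even.
* Welch statistics are computed from the explicit formula (needed in
  summary-statistics mode and for the vectorized per-m/z sweep);
  zero-variance cases are resolved deterministically (t = 0, p = 1 or
  0.5 for equal means; p = 0 otherwise).
* Peak-selection ties in the randomized count-matched ranking are broken
  by ascending m/z.
* All stochastic components run under `with_seed`, which restores the
  caller's RNG stream; a single seed makes the entire pipeline
  bit-reproducible.

## Known limitations

* **Null calibration.**  The group-level Welch *t* on LOOCV % classified
  scores is anticonservative under a label-exchangeable null: the scores
  of different samples are dependent because every sample participates
  in the peak selection and PCV midpoints of all other folds.  On the
  null preset the measured type-I rate is roughly 3–5× nominal (about
  16–24% at alpha 0.05 across seed banks), and an independent minimal
  re-implementation on plain Gaussian data shows the same inflation, so
  it is a property of the procedure itself.  This is precisely why the
  randomization control matters: inference about a separation should
  lean on the randomized-label comparison, not the nominal p value
  alone.
* Problem sizes in the test suite are chosen for a laptop-scale run:
  full-grid cohorts (1601 bins, 29 samples, triplicates) for the
  simulation checks, 50-seed null and 20-seed randomization banks,
  reduced grids (80–400 bins) for moment and property tests, and
  1000-instance oracle sweeps for the Welch/centroid/classification
  equivalences.
* Multiple-testing correction across peak t-tests is deliberately
  absent; LOOCV plus randomization is the platform's overfitting
  control.
* Cross-instrument assignment assumes identical preprocessing; no batch
  correction is attempted.
* The hit-table filter's one-decimal rounding before the 1.5× comparison
  matters only for ratios in [1.45, 1.5); no packaged row falls in that
  band, so the convention is untestable against the published tables.
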