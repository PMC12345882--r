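---
title: "Batch-robust LC-MS authentication: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch-robust LC-MS authentication: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bucketforest)
```

## The problem

Untargeted LC-MS metabolomics can, in principle, answer several food-authentication
questions from one measurement: where was this apple grown, was it produced
organically, which variety is it?  The obstacle is that LC-MS is not very
robust across processing batches: retention times drift as columns age,
instrument sensitivity changes between measurement days, and the usual
peak-correspondence step produces a feature list that is only valid within one
batch.  Data measured months apart therefore cannot normally be pooled into a
single classifier.

`bucketforest` implements the bucketing answer to this problem, together with
the downstream classification and feature-selection machinery:

1. **Bucketing.** Each sample's centroided peak list is summed onto a *fixed*
   grid of retention-time × m/z cells (default 20 s × 2 Da), anchored at
   configured minima rather than at data minima.  Every sample from every
   batch lands in the same feature space.
2. **Total-intensity normalization.**  Each sample's bucket vector is divided
   by its total, removing any global per-sample sensitivity factor.
3. **Class-weighted random forest**, evaluated by the out-of-bag (OOB) error.
4. **Boruta-style all-relevant selection** of the buckets carrying each
   authentication question's signal.
5. **Exclusive-intersection (UpSet) analysis** of the selected sets across
   questions, to see whether the questions draw on the same or different
   parts of the data.

Because the cohort the method was developed on is not public, the package
carries a first-class synthetic cohort generator that emulates its
statistical structure; everything downstream is tested against that
generator's planted ground truth.

## Bucketing model

A `bucket_grid(rt_width, mz_width, rt_range, mz_range)` covers its ranges
with `ceiling(span/width)` cells per axis.  Cells are half-open `[lo, hi)`
with the final cell closed at the top, so every in-range value belongs to
exactly one cell; out-of-range peaks are *flagged and counted*, never
silently dropped.  A peak at `(rt, mz)` maps to bucket
`(floor((rt - rt_min)/rt_width), floor((mz - mz_min)/mz_width))`, 0-based,
serialized as `"rtIdx_mzIdx"`.

Defaults: 20 s × 2 Da buckets, retention window 0–810 s (a 13.5-min method),
m/z window 50–1700 Da.  The bucket sizes are the values the approach was
optimized to; the recording windows depend on the instrument and are always
configurable.

Two properties matter and are enforced by tests:

* **Scale invariance.** Multiplying all of a sample's intensities by any
  `c > 0` leaves the normalized vector unchanged — this is the mechanism
  that absorbs day-to-day sensitivity drift.
* **Structural batch independence.** The column id set is fully determined
  by the grid.  Dropping buckets that are empty in every sample
  (`drop_all_empty = TRUE`) is allowed but the kept-bucket list is recorded
  in the serialized sidecar, so new samples can be projected onto exactly
  the same columns later.

## Classification model

`train_forest()` grows a classification forest (default 5000 trees, Gini
splits, `mtry = floor(sqrt(p))`, minimum node size 1 — deliberately no
tuning, which keeps the OOB error an honest performance estimate).  Class
imbalance is compensated through case weights `w_i = 1/(K n_c)`: used as
per-draw bootstrap sampling probabilities they make the expected class
composition of every tree's bootstrap uniform (`1/K` per class).

Tree growing is delegated to ranger, whose `case.weights` implements
exactly this per-draw weighted bootstrap.  The package does not re-grow
trees by hand; instead it makes the sampling contract *auditable*: every
bootstrap is recorded (`keep.inbag`), and a property test verifies on the
recorded bootstraps of 5000 trees that a 10-vs-90 cohort is drawn
half-and-half in expectation (±0.02).  OOB bookkeeping is implemented in
the package from the recorded in-bag counts plus per-tree votes: a sample's
OOB prediction is the majority vote over the trees whose bootstrap excluded
it, ties broken deterministically by class (factor level) order, and
samples that appeared in every bootstrap are flagged rather than dropped.
A cross-check test requires ≥ 98 % agreement with ranger's own OOB
predictions (the residual is exactly the tie-break).

Confusion matrices are reported rows = predicted, columns = true.  Accuracy
is `100·trace/total` and per-class sensitivity `100·correct/class total`,
both printed at one decimal with halves rounded away from zero — the
convention of the published tables this package recomputes.

## All-relevant variable selection

`boruta_select()` iterates up to `max_runs = 100` times.  Per run, every
still-active feature gets a *shadow*: a copy permuted across samples, which
keeps the marginal distribution but destroys any label association.  An
inner forest is trained on the augmented matrix and a real feature scores a
*hit* if its importance exceeds the **maximum** shadow importance.  After
each run, hit counts are tested against Binomial(runs, ½), one-sided in
each direction, Bonferroni-corrected over the initial feature count at
`p = 0.01`: significantly many hits ⇒ *confirmed*; significantly few ⇒
*rejected* and removed from later runs.  Whatever is undecided at the run
cap stays *tentative* and is **excluded** from the selected set passed to
intersection analysis.

The importance backend defaults to `"impurity_corrected"` — the
bias-corrected (actual impurity reduction) Gini importance, which is
unbiased under the null and is what ranger computes natively; a
`"permutation"` backend (mean OOB accuracy decrease under per-feature
permutation) is available and equally supported by the decision logic.  The
backend is recorded in every result.  Inner forests default to 500 trees:
importance *ranking* stabilizes far earlier than the classification forest
needs, and selection trains one forest per run.

Two behaviors of this procedure are worth knowing.  First, it is
*all-relevant*, not minimal-optimal: duplicated informative features are
both confirmed.  Second, at small n a noise feature whose chance sample
correlation with the label is unusually high is, in-sample, genuinely
relevant and can be confirmed; the null-simulation test therefore bounds
the *mean* confirmed count over replicates (≤ 3× the nominal level) rather
than demanding zero.

## The synthetic cohort generator

`cohort_design()` defaults describe a 193-sample, 8-day cohort whose label
structure mirrors the study conditions exactly: 117 German / 76 non-German
samples; 79 North / 38 South German region labels; 113 conventional / 40
organic production labels (153 labeled); 9/11/12/12/28/8 samples across six
varieties (80 labeled).

* **Compound library.** 150 background compounds plus planted markers per
  layer (12 for origin, region and production; 24 for variety — the
  question with six classes draws on the largest marker set, matching the
  observation that most selected variables in real data belong to the
  variety issue).  Positions are uniform over m/z 100–1000 Da and RT
  30–780 s; base intensities log-normal (sdlog 1).  Markers alternate
  between 3-fold up- and down-modulation in their class.
* **Batch effects per day.** An RT shift uniform in ±10 s (half a bucket —
  large enough that peaks near boundaries change buckets between days), an
  RT stretch within ±0.5 %, a global sensitivity factor (log-normal,
  sigma 0.3), and per-compound response factors (log-normal, sigma 0.3)
  modelling ionization-efficiency drift.  The last component is essential:
  total-intensity normalization *exactly cancels* any global per-sample
  factor, so a scalar day effect cannot dominate the normalized data; the
  per-compound drift is what makes measurement day the leading variance —
  which it demonstrably is: on the default cohort, PC1 of the bucketed
  matrix tracks day (R² > 0.9) and none of the class labels.
* **Noise.** Per-peak multiplicative log-normal noise (sigma 0.3) and 5 %
  peak dropout — conventional magnitudes for untargeted LC-MS; the study
  itself reports no within-class variance model, so these are package
  choices, not calibrated values.
* **Label assignment.** Sub-layer labels are assigned stratified across
  origin classes with an independent random order per layer, so *no layer
  is confounded with another* and day is assigned round-robin within class
  so *no layer is confounded with day* (a `confound_day_with` switch
  exists for negative controls).  This deliberately departs from the real
  cohort, where region is nested inside Germany: with nested labels a
  region marker is genuinely informative about origin, and an all-relevant
  selector *must* select it, making cross-issue overlap a property of the
  label geometry rather than of the method.  Decorrelating the layers
  makes the planted marker sets the sole source of overlap, which is what
  the intersection analysis is meant to measure.  Marker sharing between
  layers, when wanted, is introduced explicitly via `marker_overlap`.

What the generator does **not** emulate: chromatographic peak shapes,
isotope patterns and adducts (one peak per compound), correlated compound
families, and the real study's within-class biological variance.  Passing
tests on this cohort therefore demonstrate that the pipeline's logic is
correct under its assumed data structure — not that the published
real-data accuracies are reproducible, which they cannot be without the
non-public raw data.

## Numerical choices

* Half-open bucket intervals, top edge closed; boundary behavior is pinned
  by tests (`rt = 20 s` with 20-s buckets is index 1; `rt = rt_max` is the
  final bucket).
* Row normalization tolerance 1e-9 (tested); an all-zero sample is left
  all-zero with a warning.
* OOB vote ties break toward the earlier class level; never-OOB samples are
  flagged `NA` and excluded from confusion totals, with the count reported.
* Percentages are rounded half-away-from-zero at one decimal at the
  reporting boundary only; internal computation is unrounded.
* PCA is column-mean-centered without unit-variance scaling (buckets are
  already on one normalized scale); requesting more components than the
  rank reduces `k` with a warning.
* All randomness flows from explicit integer seeds; sub-seeds are derived
  with a fixed affine map so one master seed reproduces an entire pipeline
  run bit-for-bit.

## Problem sizes used in the tests

The packaged test-suite and the acceptance script run the full default
cohort (193 samples, ~400 occupied buckets) end to end with the default
5000-tree classification forests and 500-tree selection forests; the
statistical property tests (chance-level OOB, bootstrap balance, type-I
control over 20 replicates, oracle comparisons over 50–100 random
instances) use 40–150 samples and 5–51 features, sizes at which the tested
distributions are already tight.

## Known limitations

* Variety classification on the default synthetic cohort is the
  lowest-powered issue (six classes, 80 samples, 4 markers per class):
  its OOB accuracy fluctuates roughly between 55 % and 90 % across seeds,
  and marker recovery is partial.  This mirrors the small-class caveat any
  real cohort of this shape carries.
* The pipeline consumes centroided, retention-time-aligned peak lists;
  peak detection, alignment and centroiding are upstream concerns.
* mzML support covers centroided data only; profile spectra are rejected,
  not centroided.
* Model transfer across laboratories/instruments is out of scope.
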