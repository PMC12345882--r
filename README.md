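# bucketforest

Batch-robust bucketing of LC-MS peak data with random-forest authentication
and all-relevant feature selection.

## The problem

Untargeted LC-MS metabolomics is sensitive enough to answer several food
authentication questions at once — geographical origin, production method,
taxonomic variety — but its feature lists are normally only comparable
*within* one processing batch: retention times drift, sensitivity changes
between measurement days, and peak-correspondence produces a batch-specific
feature set.  `bucketforest` implements the bucketing strategy that removes
this restriction, and everything downstream of it:

* **Bucketing** — every centroided peak list is summed onto one fixed
  retention-time × m/z grid (default 20 s × 2 Da cells, half-open intervals,
  grid anchored at configured minima).  A sample measured in any batch gets
  the same feature vector structure.  Each vector is **normalized by its
  total bucket intensity**, cancelling global per-sample sensitivity drift:
  for bucket $b$ of sample $i$,

  $$x_{ib} = \frac{\sum_{p \in b} I_{ip}}{\sum_{b'} \sum_{p \in b'} I_{ip}}.$$

* **Classification** — a random forest (5000 trees, Gini splits,
  $\mathrm{mtry}=\lfloor\sqrt{p}\rfloor$, node size 1, no tuning) with
  inverse-class-size case weights $w_i = 1/(K\,n_{c(i)})$ used as per-draw
  bootstrap probabilities, so each tree's bootstrap is class-balanced in
  expectation.  Performance is the out-of-bag (OOB) error, aggregated
  in-package from recorded per-tree bootstraps.

* **Variable selection** — Boruta-style all-relevant selection: permuted
  *shadow* copies of all features join the matrix, a feature scores a hit
  when its importance (bias-corrected impurity by default) beats the best
  shadow, and hits are tested against Binomial(runs, ½) with Bonferroni
  correction at p = 0.01 over up to 100 runs, yielding
  confirmed / tentative / rejected decisions.

* **Reporting** — accuracy and per-class sensitivity from confusion
  matrices, PCA batch diagnostics, and exclusive-intersection (UpSet-style)
  counts of the variables selected for different authentication questions.

* **Synthetic cohorts** — a generator for multi-batch cohorts with planted
  per-layer marker compounds, day-wise retention-time/sensitivity batch
  effects, log-normal noise and dropout, mirroring a 193-sample apple
  cohort (117/76 by origin, 79/38 by region, 113/40 by production,
  9/11/12/12/28/8 by variety).  It provides the ground truth the test
  suite scores the pipeline against.

Written tidyverse-style: data frames in, tibbles out, `tidy()`/`glance()`
methods for fitted objects, `autoplot()` for result types.

## Worked example

Recompute the headline metrics of the published apple confusion matrices
shipped with the package:

```r
library(bucketforest)

cm <- reference_confusion("origin")
cm
#> <confusion_matrix> rows = predicted, columns = true
#>            German non-German
#> German        112          8
#> non-German      5         68
confusion_metrics(cm)
#> # A tibble: 2 × 4
#>   class          n sensitivity accuracy
#>   <chr>      <int>       <dbl>    <dbl>
#> 1 German       117        95.7     93.3
#> 2 non-German    76        89.5     93.3
```

93.3 % of samples sit on the diagonal; 95.7 % of true German and 89.5 % of
true non-German samples are recognized.

Simulate a multi-batch cohort, bucket it, classify one issue and select its
relevant buckets:

```r
cohort <- generate_cohort(cohort_design(seed = 2026))
cohort
#> <ms_cohort> 193 samples, 38440 peaks, 8 days, seed 2026

grid <- bucket_grid(rt_width = 20, mz_width = 2,
                    rt_range = c(0, 810), mz_range = c(100, 1000))
fm <- build_matrix(cohort, grid, drop_all_empty = TRUE)
fm
#> <feature_matrix> 193 samples x 372 buckets (+ day, origin, region,
#>   production, variety), 0 out-of-range peak(s)

fit <- train_forest(fm, "origin", rf_config(n_trees = 1000, seed = 1))
fit
#> <rf_fit> layer 'origin': 193 samples, 2 classes, 1000 trees, mtry 19
#>   OOB accuracy: 100.0%

sel <- boruta_select(fm, "origin",
                     selection_config(rf = rf_config(n_trees = 300), seed = 1))
sel
#> <boruta_result> layer 'origin': 23 confirmed, 5 tentative, 344 rejected
#>   (100 run(s), backend impurity_corrected)
```

The planted origin markers land among the 23 confirmed buckets; tentative
features are excluded from selected sets.  `run_pipeline(pipeline_config())`
chains all four issues (each on its labeled subset: 193 / 117 / 153 / 80
samples) and finishes with the exclusive intersections of the selected sets;
`autoplot()` on the intersection report draws the UpSet-style summary, and
`pca_scores(fm)` with `autoplot()` shows that measurement day, not any class
label, dominates the first principal components.

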