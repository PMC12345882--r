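#' Configure the end-to-end authentication pipeline
#'
#' Bundles the bucket grid, the classification-forest and selection
#' configurations, the synthetic cohort design (used when no measured
#' cohort is supplied) and the list of authentication issues.  Each issue
#' is one label layer; its sample subset is "every sample with a label in
#' that layer" unless a custom filter function (taking the samples table,
#' returning a logical vector) is supplied.
#'
#' The master `seed` is propagated to the design, the forests and the
#' selections (offset per stage and issue), so one integer reproduces the
#' whole run.
#'
#' @param grid A [bucket_grid()].
#' @param rf An [rf_config()].
#' @param selection A [selection_config()].
#' @param design A [cohort_design()] for simulated input.
#' @param issues Character vector of layer names, or a named list mapping
#'   layer name to a filter function.
#' @param drop_all_empty Drop buckets empty in every sample (recorded in
#'   the serialized kept-bucket list).
#' @param output_dir Optional directory for [write_pipeline_result()].
#' @param seed Master integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(grid = bucket_grid(),
                            rf = rf_config(),
                            selection = selection_config(),
                            design = cohort_design(),
                            issues = names(design$layers),
                            drop_all_empty = TRUE,
                            output_dir = NULL,
                            seed = 1L) {
  if (is.character(issues)) issues <- set_names(vector("list", length(issues)), issues)
  if (length(issues) == 0 || is.null(names(issues))) abort("issues must be named")
  unknown <- setdiff(names(issues), names(design$layers))
  if (length(unknown) > 0 && !is.null(design))
    abort(sprintf("issue layer(s) not in the design: %s", paste(unknown, collapse = ", ")))
  seed <- as.integer(seed)
  design$seed <- seed
  rf$seed <- derive_seed(seed, 1L)
  selection$seed <- derive_seed(seed, 2L)
  structure(list(grid = grid, rf = rf, selection = selection, design = design,
                 issues = issues, drop_all_empty = drop_all_empty,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every section is optional; omitted values fall back to the package
#' defaults.  Recognized top-level keys: `grid`, `rf`, `selection`,
#' `design` (scalar fields of [cohort_design()] plus per-layer class
#' counts), `issues`, `drop_all_empty`, `output_dir`, `seed`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- do.call(bucket_grid, y$grid %||% list())
  rf <- do.call(rf_config, y$rf %||% list())
  sel_args <- y$selection %||% list()
  if (!is.null(sel_args$rf)) sel_args$rf <- do.call(rf_config, sel_args$rf)
  selection <- do.call(selection_config, sel_args)
  des_args <- y$design %||% list()
  # layers set to null in the YAML stay dropped; counts lists become vectors
  for (cnt in grep("_counts$", names(des_args), value = TRUE)) {
    if (is.null(des_args[[cnt]])) des_args[cnt] <- list(NULL)
    else des_args[[cnt]] <- unlist(des_args[[cnt]])
  }
  design <- do.call(cohort_design, des_args)
  pipeline_config(grid = grid, rf = rf, selection = selection, design = design,
                  issues = y$issues %||% names(design$layers),
                  drop_all_empty = y$drop_all_empty %||% TRUE,
                  output_dir = y$output_dir, seed = y$seed %||% 1L)
}

issue_subset <- function(samples, layer, filter_fn = NULL) {
  keep <- if (is.null(filter_fn)) !is.na(samples[[layer]]) else filter_fn(samples)
  if (!any(keep)) abort(sprintf("issue '%s': subset rule excludes all samples", layer))
  keep
}

fm_rows <- function(fm, idx) {
  new_feature_matrix(as_tibble(fm)[idx, , drop = FALSE], attr(fm, "grid"),
                     attr(fm, "buckets"), attr(fm, "meta_cols"),
                     attr(fm, "n_out_of_range"))
}

#' Run the full authentication analysis
#'
#' Executes, in order: cohort simulation (unless `cohort` is supplied) →
#' bucketing into the standardized feature matrix → per issue, on that
#' issue's labeled subset: class-weighted random forest with OOB
#' evaluation, confusion-matrix metrics and Boruta-style variable selection
#' → exclusive intersections of the selected sets across issues.  Any stage
#' failure aborts with the stage named.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional measured input: an `ms_cohort` or a list with
#'   `peaks` and `samples` (e.g. from [read_peaklists()]); when `NULL` the
#'   configured design is simulated.
#' @return A `pipeline_result` list: `feature_matrix`, `issues` (named
#'   list, each with `n`, `fit`, `confusion`, `metrics`, `selection`),
#'   `intersections`, `log` (per-stage sample/feature counts), `config`,
#'   `config_hash`, `seed`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- with_stage("simulate", cohort %||% generate_cohort(config$design))

  fm <- with_stage("bucket", build_matrix(
    cohort$peaks, config$grid, metadata = cohort$samples,
    drop_all_empty = config$drop_all_empty
  ))
  log <- tibble(stage = "bucket", issue = NA_character_,
                n_samples = nrow(fm), n_features = length(fm_buckets(fm)))

  issues <- imap(config$issues, function(filter_fn, layer) {
    keep <- with_stage(paste0("subset:", layer),
                       issue_subset(as_tibble(fm), layer, filter_fn))
    sub <- fm_rows(fm, keep)
    rf_cfg <- config$rf
    rf_cfg$seed <- derive_seed(config$seed, 10L + match(layer, names(config$issues)))
    fit <- with_stage(paste0("train:", layer), train_forest(sub, layer, rf_cfg))
    cm <- oob_confusion(fit)
    sel_cfg <- config$selection
    sel_cfg$seed <- derive_seed(config$seed, 20L + match(layer, names(config$issues)))
    sel <- with_stage(paste0("select:", layer), boruta_select(sub, layer, sel_cfg))
    log <<- bind_rows(log, tibble(stage = "issue", issue = layer,
                                  n_samples = sum(keep),
                                  n_features = length(fm_buckets(fm))))
    list(n = sum(keep), fit = fit, confusion = cm,
         metrics = confusion_metrics(cm), selection = sel)
  })

  intersections <- with_stage("intersect", exclusive_intersections(
    map(issues, ~ selected_features(.x$selection))
  ))

  res <- structure(list(
    feature_matrix = fm, issues = issues, intersections = intersections,
    log = log, config = config, config_hash = rlang::hash(config),
    seed = config$seed
  ), class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_result(res, config$output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed ", x$seed, ", config ", substr(x$config_hash, 1, 8), "\n", sep = "")
  for (nm in names(x$issues)) {
    iss <- x$issues[[nm]]
    cat(sprintf("  %-11s n = %3d  OOB accuracy %5.1f%%  confirmed %d\n",
                nm, iss$n, accuracy(iss$confusion),
                length(selected_features(iss$selection))))
  }
  cat("  union of selected sets:", attr(x$intersections, "union_size"), "variables\n")
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Per issue: confusion CSV, metrics JSON, selection CSV and selected-set
#' ids; plus the feature matrix (CSV + sidecar), the intersection report
#' (CSV + JSON) and a run manifest.  The seed and the configuration hash
#' are embedded in every JSON artifact, so reruns are bit-reproducible.
#'
#' @param res A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_pipeline_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(seed = res$seed, config_hash = res$config_hash)
  write_feature_matrix(res$feature_matrix, file.path(dir, "feature_matrix.csv"),
                       seed = res$seed)
  for (nm in names(res$issues)) {
    iss <- res$issues[[nm]]
    write_confusion(iss$confusion, file.path(dir, sprintf("confusion_%s.csv", nm)))
    jsonlite::write_json(
      c(stamp, list(issue = nm, n = iss$n,
                    accuracy = accuracy(iss$confusion),
                    sensitivity = set_names(as.list(iss$metrics$sensitivity),
                                            iss$metrics$class))),
      file.path(dir, sprintf("metrics_%s.json", nm)), auto_unbox = TRUE, digits = NA)
    write_selection(iss$selection, file.path(dir, sprintf("selection_%s.csv", nm)),
                    file.path(dir, sprintf("selected_%s.txt", nm)))
  }
  readr::write_csv(mutate(as_tibble(res$intersections),
                          issues = map_chr(.data$issues, paste, collapse = "+")),
                   file.path(dir, "intersections.csv"), progress = FALSE)
  jsonlite::write_json(c(stamp, list(
    union_size = attr(res$intersections, "union_size"),
    set_sizes = as.list(attr(res$intersections, "set_sizes")),
    log = res$log
  )), file.path(dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
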