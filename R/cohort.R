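#' Describe a synthetic multi-batch LC-MS cohort
#'
#' A cohort design fixes everything the generator needs: how many samples
#' carry which class label in each of the four authentication layers
#' (country-level origin, region, production method, taxonomic variety), the
#' compound library (background compounds plus marker compounds planted per
#' layer), the measurement-noise model and the day-wise batch-effect model.
#' The defaults mirror a real multi-batch apple cohort: 193 samples split
#' 117/76 by origin, 79/38 by region, 113/40 by production method (153
#' labeled) and 9/11/12/12/28/8 across six varieties (80 labeled).
#'
#' Label layers are assigned to samples independently of each other
#' (stratified across origin classes), so that by default no layer is
#' confounded with another and the marker sets planted for different layers
#' stay statistically disjoint — cross-issue feature-selection overlap is
#' then controlled by `marker_overlap` alone.
#'
#' @param origin_counts,region_counts,production_counts,variety_counts Named
#'   integer vectors of per-class sample counts.  `origin_counts` defines the
#'   cohort size; the other layers may label a subset of samples (unlabeled
#'   samples get `NA`).  Pass `NULL` to drop a layer.
#' @param n_background Number of background (non-marker) compounds.
#' @param n_markers Markers planted per layer; scalar or named per layer.
#' @param marker_overlap Named numeric vector of overlap fractions between
#'   layer pairs, names `"layerA:layerB"`; that fraction of the pair's
#'   markers is carried by shared compounds annotated for both layers.
#'   Default: no overlap, marker sets pairwise disjoint.
#' @param effect_size Multiplicative fold-change applied to a marker compound
#'   in its marker classes; markers alternate between up- (`effect_size`)
#'   and down-modulation (`1/effect_size`).
#' @param mz_range,rt_range Ranges (Da, seconds) compounds are placed in.
#' @param run_span Recorded retention-time window in seconds; shifted peaks
#'   are clipped to it.
#' @param intensity_meanlog,intensity_sdlog Log-normal parameters of compound
#'   base intensities (arbitrary units).
#' @param noise_sigma Per-peak multiplicative log-normal noise sigma.
#' @param dropout Per-peak dropout probability.
#' @param n_days Number of measurement days (batches).
#' @param rt_shift_max Maximum absolute day-wise retention-time shift (s).
#' @param rt_stretch_max Maximum absolute deviation of the day-wise
#'   retention-time stretch factor from 1.
#' @param scale_sigma Log-normal sigma of the day-wise global sensitivity
#'   factor (cancelled by total-intensity normalization downstream).
#' @param sensitivity_sigma Log-normal sigma of the day-by-compound response
#'   factors; this is the batch component that survives normalization and
#'   makes measurement day the dominant variance in the bucketed data.
#' @param confound_day_with `NULL` (default, day assigned round-robin within
#'   class so no layer is confounded with day) or a layer name whose classes
#'   are measured on disjoint day blocks, for negative-control experiments.
#' @param seed Integer seed recorded in the design and used for everything
#'   the generator draws.
#' @return A `cohort_design` object (a validated list).
#' @seealso [generate_cohort()], [generate_library()]
#' @export
cohort_design <- function(origin_counts = c(German = 117, `non-German` = 76),
                          region_counts = c(North = 79, South = 38),
                          production_counts = c(conventional = 113, organic = 40),
                          variety_counts = c(Boskoop = 9, Braeburn = 11, `Cripps Pink` = 12,
                                             Elstar = 12, Gala = 28, Jonagold = 8),
                          n_background = 150,
                          n_markers = c(origin = 12, region = 12,
                                        production = 12, variety = 24),
                          marker_overlap = NULL,
                          effect_size = 3,
                          mz_range = c(100, 1000),
                          rt_range = c(30, 780),
                          run_span = c(0, 810),
                          intensity_meanlog = log(1e5),
                          intensity_sdlog = 1,
                          noise_sigma = 0.3,
                          dropout = 0.05,
                          n_days = 8,
                          rt_shift_max = 10,
                          rt_stretch_max = 0.005,
                          scale_sigma = 0.3,
                          sensitivity_sigma = 0.3,
                          confound_day_with = NULL,
                          seed = 1L) {
  layers <- list(origin = origin_counts, region = region_counts,
                 production = production_counts, variety = variety_counts)
  layers <- layers[!vapply(layers, is.null, logical(1))]
  if (length(layers) == 0L) abort("at least one label layer is required")
  if (is.null(names(layers[[1]]))) abort("class counts must be named vectors")
  if (length(n_markers) == 1L && is.null(names(n_markers))) {
    n_markers <- set_names(rep(n_markers, length(layers)), names(layers))
  }
  design <- structure(list(
    layers = layers,
    n_background = as.integer(n_background),
    n_markers = n_markers,
    marker_overlap = marker_overlap,
    effect_size = effect_size,
    mz_range = mz_range, rt_range = rt_range, run_span = run_span,
    intensity_meanlog = intensity_meanlog, intensity_sdlog = intensity_sdlog,
    noise_sigma = noise_sigma, dropout = dropout,
    n_days = as.integer(n_days),
    rt_shift_max = rt_shift_max, rt_stretch_max = rt_stretch_max,
    scale_sigma = scale_sigma, sensitivity_sigma = sensitivity_sigma,
    confound_day_with = confound_day_with,
    seed = as.integer(seed)
  ), class = "cohort_design")
  validate_design(design)
  design
}

validate_design <- function(design) {
  ly <- design$layers
  n <- sum(ly[[1]])
  for (nm in names(ly)) {
    counts <- ly[[nm]]
    if (any(counts < 1)) abort(sprintf("layer '%s' has a class with zero samples", nm))
    if (is.null(names(counts)) || anyDuplicated(names(counts)))
      abort(sprintf("layer '%s' needs unique class names", nm))
    if (sum(counts) > n)
      abort(sprintf("layer '%s' labels more samples (%d) than the cohort holds (%d)",
                    nm, sum(counts), n))
  }
  if (diff(design$mz_range) <= 0 || diff(design$rt_range) <= 0 || diff(design$run_span) <= 0)
    abort("configuration error: mz/rt ranges must be nonempty")
  if (design$rt_range[1] < design$run_span[1] || design$rt_range[2] > design$run_span[2])
    abort("configuration error: rt_range must lie within run_span")
  if (design$dropout < 0 || design$dropout > 1) abort("dropout must be in [0, 1]")
  if (any(design$n_markers < 0) || design$n_background < 0) abort("library sizes must be nonnegative")
  if (design$effect_size < 0) abort("effect_size must be nonnegative")
  if (!is.null(design$marker_overlap)) {
    if (any(design$marker_overlap < 0 | design$marker_overlap > 1))
      abort("marker_overlap fractions must be in [0, 1]")
    pair_layers <- unlist(strsplit(names(design$marker_overlap), ":", fixed = TRUE))
    if (!all(pair_layers %in% names(design$layers)))
      abort("marker_overlap names must be 'layerA:layerB' over existing layers")
  }
  if (!is.null(design$confound_day_with) &&
      !design$confound_day_with %in% names(design$layers))
    abort("confound_day_with must name an existing layer")
  invisible(design)
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> ", sum(x$layers[[1]]), " samples, ", x$n_days, " days, seed ",
      x$seed, "\n", sep = "")
  for (nm in names(x$layers)) {
    cat("  ", nm, ": ", paste0(names(x$layers[[nm]]), "=", x$layers[[nm]], collapse = ", "),
        " (", x$n_markers[[nm]], " markers)\n", sep = "")
  }
  invisible(x)
}

# -- compound library ---------------------------------------------------------

new_marker_tbl <- function(layer = character(), class = character(), effect = numeric()) {
  tibble(layer = layer, class = class, effect = effect)
}

generate_library_impl <- function(design) {
  draw_positions <- function(n, role, prefix) {
    tibble(
      compound_id = sprintf("%s%03d", prefix, seq_len(n)),
      mz = runif(n, design$mz_range[1], design$mz_range[2]),
      rt = runif(n, design$rt_range[1], design$rt_range[2]),
      base_intensity = rlnorm(n, design$intensity_meanlog, design$intensity_sdlog),
      role = role
    )
  }
  bg <- draw_positions(design$n_background, "background", "bg")
  bg$marker <- rep(list(new_marker_tbl()), nrow(bg))

  marker_tbls <- imap(design$layers, function(counts, layer) {
    k <- design$n_markers[[layer]]
    if (k == 0L) return(NULL)
    m <- draw_positions(k, "marker", paste0("mk_", substr(layer, 1, 3)))
    classes <- names(counts)
    m$marker <- map(seq_len(k), function(j) {
      eff <- if (j %% 2L == 1L) design$effect_size else 1 / design$effect_size
      new_marker_tbl(layer, classes[(j - 1L) %% length(classes) + 1L], eff)
    })
    m
  })
  marker_tbls <- marker_tbls[!vapply(marker_tbls, is.null, logical(1))]

  # merge the leading markers of paired layers into shared compounds
  if (!is.null(design$marker_overlap)) {
    for (pair in names(design$marker_overlap)) {
      ab <- strsplit(pair, ":", fixed = TRUE)[[1]]
      a <- ab[1]; b <- ab[2]
      f <- design$marker_overlap[[pair]]
      k <- round(f * min(nrow(marker_tbls[[a]]), nrow(marker_tbls[[b]])))
      if (k > 0) {
        for (j in seq_len(k)) {
          marker_tbls[[a]]$marker[[j]] <-
            dplyr::bind_rows(marker_tbls[[a]]$marker[[j]], marker_tbls[[b]]$marker[[j]])
        }
        marker_tbls[[b]] <- marker_tbls[[b]][-seq_len(k), , drop = FALSE]
      }
    }
  }
  lib <- dplyr::bind_rows(c(list(bg), unname(marker_tbls)))
  attr(lib, "run_span") <- design$run_span
  attr(lib, "layers") <- design$layers
  lib
}

#' Generate the compound library of a cohort design
#'
#' Draws background and marker compounds (m/z, retention time, base
#' intensity) and annotates each marker with the label layer, the classes it
#' is modulated in, and its fold-change.  Deterministic in the design seed.
#'
#' @param design A [cohort_design()].
#' @return A tibble with one row per compound: `compound_id`, `mz`, `rt`,
#'   `base_intensity`, `role` (`"background"`/`"marker"`), and `marker`, a
#'   list-column of `(layer, class, effect)` tibbles (zero rows for
#'   background compounds, more than one row only for compounds shared
#'   between layers under `marker_overlap`).
#' @export
generate_library <- function(design) {
  validate_design(design)
  withr::with_seed(design$seed, generate_library_impl(design))
}

# -- batch effects ------------------------------------------------------------

#' Day-wise batch effect
#'
#' One measurement day's systematic distortion: an additive retention-time
#' shift, a multiplicative retention-time stretch, a global sensitivity
#' factor, and (optionally) per-compound response factors modelling
#' ionization-efficiency drift.  `batch_effect()` with no arguments is the
#' identity (no distortion).
#'
#' @param day Integer batch index.
#' @param rt_shift Additive retention-time offset in seconds.
#' @param rt_stretch Multiplicative retention-time factor near 1.
#' @param intensity_scale Global sensitivity factor, > 0.
#' @param sensitivity Optional numeric vector of per-compound response
#'   factors (recycled 1 if `NULL`).
#' @return A `batch_effect` list.
#' @export
batch_effect <- function(day = 1L, rt_shift = 0, rt_stretch = 1,
                         intensity_scale = 1, sensitivity = NULL) {
  if (intensity_scale <= 0) abort("intensity_scale must be > 0")
  structure(list(day = as.integer(day), rt_shift = rt_shift, rt_stretch = rt_stretch,
                 intensity_scale = intensity_scale, sensitivity = sensitivity),
            class = "batch_effect")
}

generate_batch_effects_impl <- function(design, n_compounds) {
  map(seq_len(design$n_days), function(d) {
    batch_effect(
      day = d,
      rt_shift = runif(1, -design$rt_shift_max, design$rt_shift_max),
      rt_stretch = runif(1, 1 - design$rt_stretch_max, 1 + design$rt_stretch_max),
      intensity_scale = rlnorm(1, 0, design$scale_sigma),
      sensitivity = rlnorm(n_compounds, 0, design$sensitivity_sigma)
    )
  })
}

# -- one sample ---------------------------------------------------------------

#' Generate one sample's centroided peak list
#'
#' Emits one peak per non-dropped compound at
#' `rt' = rt * rt_stretch + rt_shift` (clipped to the run span) with
#' intensity `base * effect * intensity_scale * sensitivity * noise`, where
#' `effect` is the compound's fold-change if it is a marker for one of the
#' sample's class labels and 1 otherwise, and `noise` is a multiplicative
#' log-normal draw.  Uses the current RNG state; seed the session (or call
#' through [generate_cohort()]) for reproducibility.
#'
#' @param library Compound library from [generate_library()].
#' @param labels Named list or vector mapping layer to class (`NA` allowed
#'   for unlabeled layers).  Unknown classes are an error.
#' @param effects A [batch_effect()].
#' @param noise_sigma Per-peak multiplicative log-normal sigma.
#' @param dropout Per-peak dropout probability.
#' @param run_span Length-2 numeric; retention times are clipped to it.
#' @return A tibble of peaks: `mz` (Da), `rt` (s), `intensity`, ordered by
#'   retention time.
#' @export
generate_sample <- function(library, labels, effects = batch_effect(),
                            noise_sigma = 0, dropout = 0,
                            run_span = attr(library, "run_span") %||% c(0, Inf)) {
  labels <- as.list(labels)
  known <- attr(library, "layers")
  if (!is.null(known)) {
    for (nm in names(labels)) {
      lab <- labels[[nm]]
      if (!is.na(lab) && nm %in% names(known) && !lab %in% names(known[[nm]]))
        abort(sprintf("unknown class '%s' for layer '%s'", lab, nm))
    }
  }
  n <- nrow(library)
  eff <- map_dbl(library$marker, function(mk) {
    if (nrow(mk) == 0L) return(1)
    hit <- map_chr(mk$layer, function(l) {
      if (is.null(labels[[l]]) || is.na(labels[[l]])) NA_character_ else labels[[l]]
    })
    prod(ifelse(!is.na(hit) & hit == mk$class, mk$effect, 1))
  })
  kept <- runif(n) >= dropout
  noise <- exp(rnorm(n, 0, noise_sigma))
  sens <- effects$sensitivity %||% rep(1, n)
  out <- tibble(
    mz = library$mz,
    rt = pmin(pmax(library$rt * effects$rt_stretch + effects$rt_shift,
                   run_span[1]), run_span[2]),
    intensity = library$base_intensity * eff * effects$intensity_scale * sens * noise
  )
  out[kept, , drop = FALSE] |> arrange(.data$rt, .data$mz)
}

# -- label assignment ---------------------------------------------------------

# spread a sub-layer's labels evenly across origin classes, with fresh random
# within-class order per layer so different layers stay decorrelated
assign_sublayer <- function(origin, counts) {
  n <- length(origin)
  pos <- numeric(n)
  for (cl in unique(origin)) {
    idx <- sample(which(origin == cl))
    pos[idx] <- (seq_along(idx) - 0.5) / length(idx)
  }
  ord <- order(pos, origin)
  lab <- rep(NA_character_, n)
  lab[ord[seq_len(sum(counts))]] <- rep(names(counts), counts)
  lab
}

assign_days <- function(samples, design) {
  lab_cols <- intersect(names(design$layers), names(samples))
  key <- do.call(paste, c(lapply(samples[lab_cols], function(x) ifelse(is.na(x), "zz", x)),
                          sep = "|"))
  ord <- order(key)
  day <- integer(nrow(samples))
  if (is.null(design$confound_day_with)) {
    day[ord] <- (seq_len(nrow(samples)) - 1L) %% design$n_days + 1L
  } else {
    ord <- order(samples[[design$confound_day_with]], key)
    day[ord] <- ceiling(seq_len(nrow(samples)) * design$n_days / nrow(samples))
  }
  day
}

# -- whole cohort -------------------------------------------------------------

#' Generate a synthetic multi-batch cohort of peak lists
#'
#' Draws the compound library, assigns class labels per layer (stratified so
#' layers are mutually decorrelated), assigns measurement days round-robin
#' within class, draws day-wise batch effects, and emits one centroided peak
#' list per sample.  Byte-identical across runs with the same design.
#'
#' @param design A [cohort_design()].
#' @return An `ms_cohort` list: `peaks` (tibble `sample_id`, `mz`, `rt`,
#'   `intensity`), `samples` (tibble `sample_id`, `day`, one column per label
#'   layer), `library`, `batch_effects`, and the `design` (seed included).
#' @examples
#' design <- cohort_design(
#'   origin_counts = c(A = 6, B = 6), region_counts = NULL,
#'   production_counts = NULL, variety_counts = NULL,
#'   n_background = 20, n_markers = 3, n_days = 2, seed = 42
#' )
#' cohort <- generate_cohort(design)
#' dplyr::count(cohort$samples, origin)
#' @export
generate_cohort <- function(design) {
  validate_design(design)
  withr::with_seed(design$seed, {
    lib <- generate_library_impl(design)
    n <- sum(design$layers[[1]])
    samples <- tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      origin = rep(names(design$layers[[1]]), design$layers[[1]])
    )
    names(samples)[2] <- names(design$layers)[1]
    base_layer <- samples[[2]]
    for (nm in names(design$layers)[-1]) {
      samples[[nm]] <- assign_sublayer(base_layer, design$layers[[nm]])
    }
    samples$day <- assign_days(samples, design)
    batches <- generate_batch_effects_impl(design, nrow(lib))
    peaks <- map(seq_len(n), function(i) {
      labels <- as.list(samples[i, names(design$layers), drop = FALSE])
      pk <- generate_sample(lib, labels, effects = batches[[samples$day[i]]],
                            noise_sigma = design$noise_sigma,
                            dropout = design$dropout,
                            run_span = design$run_span)
      pk$sample_id <- samples$sample_id[i]
      pk
    }) |> purrr::list_rbind() |> relocate("sample_id")
    samples <- relocate(samples, "sample_id", "day")
    structure(list(peaks = peaks, samples = samples, library = lib,
                   batch_effects = batches, design = design),
              class = "ms_cohort")
  })
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat("<ms_cohort> ", nrow(x$samples), " samples, ", nrow(x$peaks), " peaks, ",
      x$design$n_days, " days, seed ", x$design$seed, "\n", sep = "")
  invisible(x)
}

#' Ground-truth bucket locations of planted marker compounds
#'
#' Day-wise retention-time shifts can place one compound in different RT
#' buckets on different days, so a marker's ground truth is the set of
#' buckets it can occupy across the cohort's batch effects.  Used to score
#' feature selection against the planted signal.
#'
#' @param cohort An `ms_cohort`.
#' @param grid A [bucket_grid()].
#' @return A tibble with one row per (marker compound, layer, bucket):
#'   `compound_id`, `layer`, `bucket`.
#' @export
marker_buckets <- function(cohort, grid) {
  lib <- cohort$library
  mk <- lib[lib$role == "marker", , drop = FALSE]
  if (nrow(mk) == 0L) return(tibble(compound_id = character(), layer = character(),
                                    bucket = character()))
  span <- cohort$design$run_span
  purrr::list_rbind(map(cohort$batch_effects, function(be) {
    rt <- pmin(pmax(mk$rt * be$rt_stretch + be$rt_shift, span[1]), span[2])
    asg <- assign_bucket(mk$mz, rt, grid)
    tibble(compound_id = mk$compound_id, bucket = asg$bucket,
           layer = map(mk$marker, ~ unique(.x$layer)))
  })) |>
    tidyr::unnest("layer") |>
    filter(!is.na(.data$bucket)) |>
    distinct(.data$compound_id, .data$layer, .data$bucket)
}
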