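#' Define a fixed retention-time by m/z bucket grid
#'
#' The grid is the standardized feature space: every sample, from any
#' processing batch, is mapped onto the same rectangular cells of the
#' RT x m/z plane.  Cells are half-open `[lo, hi)` on both axes, with the
#' final cell closed at the top edge so the range boundaries belong to a
#' bucket.  The grid is anchored at the configured minima, never at data
#' minima — data-driven anchoring would break cross-batch comparability.
#'
#' @param rt_width Bucket width in seconds (default 20).
#' @param mz_width Bucket width in Da (default 2).
#' @param rt_range Retention-time span in seconds covered by the grid.
#' @param mz_range Mass span in Da covered by the grid.
#' @return A `bucket_grid` object with `n_rt` and `n_mz` cells per axis
#'   (`ceiling(span / width)`).
#' @examples
#' grid <- bucket_grid(rt_width = 20, mz_width = 2,
#'                     rt_range = c(0, 810), mz_range = c(50, 1700))
#' grid$n_rt * grid$n_mz  # total buckets
#' @export
bucket_grid <- function(rt_width = 20, mz_width = 2,
                        rt_range = c(0, 810), mz_range = c(50, 1700)) {
  if (rt_width <= 0 || mz_width <= 0) abort("bucket widths must be > 0")
  if (diff(rt_range) <= 0 || diff(mz_range) <= 0) abort("grid ranges must be nonempty")
  structure(list(
    rt_width = rt_width, mz_width = mz_width,
    rt_range = rt_range, mz_range = mz_range,
    n_rt = as.integer(ceiling(diff(rt_range) / rt_width)),
    n_mz = as.integer(ceiling(diff(mz_range) / mz_width))
  ), class = "bucket_grid")
}

#' @export
print.bucket_grid <- function(x, ...) {
  cat(sprintf("<bucket_grid> %d x %d buckets (%g s x %g Da), rt [%g, %g] s, mz [%g, %g] Da\n",
              x$n_rt, x$n_mz, x$rt_width, x$mz_width,
              x$rt_range[1], x$rt_range[2], x$mz_range[1], x$mz_range[2]))
  invisible(x)
}

bucket_id <- function(rt_idx, mz_idx) {
  ifelse(is.na(rt_idx) | is.na(mz_idx), NA_character_, paste0(rt_idx, "_", mz_idx))
}

all_bucket_ids <- function(grid) {
  # ordered rt-major to give a fixed, grid-determined column order
  as.vector(t(outer(seq_len(grid$n_rt) - 1L, seq_len(grid$n_mz) - 1L, bucket_id)))
}

axis_index <- function(v, lo, hi, width, n) {
  idx <- floor((v - lo) / width)
  idx[v == hi] <- n - 1L            # top edge belongs to the final bucket
  idx[v < lo | v > hi] <- NA_integer_
  as.integer(idx)
}

#' Assign peaks to grid buckets
#'
#' Vectorized floor arithmetic under the half-open convention: a peak at
#' `(mz, rt)` falls into `(floor((rt - rt_min)/rt_width),
#' floor((mz - mz_min)/mz_width))`, 0-based on both axes.  Peaks outside the
#' grid ranges are flagged with `NA` indices, never silently dropped.
#'
#' @param mz,rt Numeric vectors of equal length (Da, seconds).
#' @param grid A [bucket_grid()].
#' @return A tibble with `rt_idx`, `mz_idx` (0-based, `NA` when out of
#'   range), `bucket` (id string `"rtIdx_mzIdx"`) and `in_range`.
#' @examples
#' grid <- bucket_grid(rt_range = c(0, 810), mz_range = c(100, 1000))
#' assign_bucket(mz = 101.3, rt = 25, grid)  # bucket "1_0"
#' @export
assign_bucket <- function(mz, rt, grid) {
  stopifnot(length(mz) == length(rt))
  rt_idx <- axis_index(rt, grid$rt_range[1], grid$rt_range[2], grid$rt_width, grid$n_rt)
  mz_idx <- axis_index(mz, grid$mz_range[1], grid$mz_range[2], grid$mz_width, grid$n_mz)
  tibble(rt_idx = rt_idx, mz_idx = mz_idx,
         bucket = bucket_id(rt_idx, mz_idx),
         in_range = !is.na(rt_idx) & !is.na(mz_idx))
}

#' Sum a peak list onto the bucket grid
#'
#' Every in-range peak's intensity is added to its bucket; buckets receiving
#' no peaks hold 0.  The number of out-of-range peaks is reported as an
#' attribute (and they are excluded from the sums).
#'
#' @param peaks A tibble/data frame with columns `mz`, `rt`, `intensity`.
#' @param grid A [bucket_grid()].
#' @return A named numeric vector over all grid buckets (names
#'   `"rtIdx_mzIdx"`, rt-major order) with attribute `n_out_of_range`.
#' @export
bucket_peaklist <- function(peaks, grid) {
  ids <- all_bucket_ids(grid)
  vec <- set_names(numeric(length(ids)), ids)
  if (nrow(peaks) == 0L) {
    warn("empty peak list: returning the all-zero bucket vector")
    attr(vec, "n_out_of_range") <- 0L
    return(vec)
  }
  if (any(peaks$intensity < 0)) abort("negative peak intensities signal upstream corruption")
  asg <- assign_bucket(peaks$mz, peaks$rt, grid)
  inr <- asg$in_range
  sums <- tapply(peaks$intensity[inr], asg$bucket[inr], sum)
  vec[names(sums)] <- as.numeric(sums)
  attr(vec, "n_out_of_range") <- sum(!inr)
  vec
}

#' Normalize a bucket vector by its total intensity
#'
#' Divides every bucket by the sum over all buckets, making the feature
#' vector invariant to any global per-sample sensitivity factor — the
#' mechanism that compensates day-to-day instrument drift.  An all-zero
#' vector is returned unchanged with a warning.
#'
#' @param x Nonnegative numeric vector.
#' @return `x / sum(x)` (or `x` if the sum is zero).
#' @examples
#' normalize_total(c(2, 3, 5))
#' @export
normalize_total <- function(x) {
  if (any(x < 0)) abort("negative bucket intensities signal upstream corruption")
  s <- sum(x)
  if (s == 0) {
    warn("all-zero vector: returning unchanged")
    return(x)
  }
  x / s
}

#' Build the standardized feature matrix of a cohort
#'
#' Buckets every sample onto the shared grid, sums intensities per bucket,
#' normalizes each sample by its total bucket intensity, and returns a tidy
#' samples x buckets table with the label columns up front.  The bucket
#' column set is fully determined by the grid (plus, if
#' `drop_all_empty = TRUE`, the recorded kept-bucket list), so matrices
#' built from different batches share one structure.
#'
#' @param x An `ms_cohort`, or a peaks tibble (`sample_id`, `mz`, `rt`,
#'   `intensity`).
#' @param grid A [bucket_grid()].
#' @param metadata Optional samples tibble (joined by `sample_id`); taken
#'   from the cohort when `x` is an `ms_cohort`.
#' @param drop_all_empty Drop buckets empty in every sample (identically for
#'   all samples); the kept-bucket list is recorded so new samples can be
#'   projected onto the same columns.
#' @param keep_buckets Optional explicit kept-bucket id list (e.g. from a
#'   previously serialized matrix) to project onto instead of recomputing.
#' @return A `feature_matrix`: a tibble with `sample_id`, any metadata
#'   columns, then one numeric column per kept bucket; attributes `grid`,
#'   `buckets` (kept ids), `meta_cols` and `n_out_of_range`.
#' @export
build_matrix <- function(x, grid, metadata = NULL, drop_all_empty = FALSE,
                         keep_buckets = NULL) {
  if (inherits(x, "ms_cohort")) {
    metadata <- metadata %||% x$samples
    peaks <- x$peaks
  } else {
    peaks <- x
  }
  stopifnot(all(c("sample_id", "mz", "rt", "intensity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) abort("negative peak intensities signal upstream corruption")

  asg <- assign_bucket(peaks$mz, peaks$rt, grid)
  n_oor <- sum(!asg$in_range)
  sample_ids <- unique(peaks$sample_id)

  long <- tibble(sample_id = peaks$sample_id, bucket = asg$bucket,
                 intensity = peaks$intensity) |>
    filter(!is.na(.data$bucket)) |>
    summarise(intensity = sum(.data$intensity), .by = c("sample_id", "bucket"))

  ids <- all_bucket_ids(grid)
  keep <- if (!is.null(keep_buckets)) {
    if (!all(keep_buckets %in% ids)) abort("keep_buckets contains ids outside the grid")
    keep_buckets
  } else if (drop_all_empty) {
    ids[ids %in% unique(long$bucket)]
  } else ids

  mat <- matrix(0, nrow = length(sample_ids), ncol = length(keep),
                dimnames = list(sample_ids, keep))
  long <- filter(long, .data$bucket %in% keep)
  mat[cbind(match(long$sample_id, sample_ids), match(long$bucket, keep))] <- long$intensity

  totals <- rowSums(mat)
  if (any(totals == 0)) warn(sprintf("%d sample(s) have no in-range peaks; rows left all-zero",
                                     sum(totals == 0)))
  mat[totals > 0, ] <- mat[totals > 0, , drop = FALSE] / totals[totals > 0]

  out <- tibble(sample_id = sample_ids)
  meta_cols <- character()
  if (!is.null(metadata)) {
    missing_meta <- setdiff(sample_ids, metadata$sample_id)
    if (length(missing_meta) > 0)
      abort(sprintf("samples missing from metadata: %s",
                    paste(head(missing_meta, 5), collapse = ", ")))
    out <- left_join(out, metadata, by = "sample_id")
    meta_cols <- setdiff(names(metadata), "sample_id")
  }
  out <- bind_cols(out, as_tibble(mat))
  new_feature_matrix(out, grid, keep, meta_cols, n_oor)
}

new_feature_matrix <- function(tbl, grid, buckets, meta_cols, n_out_of_range = 0L) {
  structure(tbl, class = c("feature_matrix", class(tibble())),
            grid = grid, buckets = buckets, meta_cols = meta_cols,
            n_out_of_range = n_out_of_range)
}

#' Extract the numeric bucket values of a feature matrix
#'
#' @param fm A `feature_matrix` from [build_matrix()].
#' @return A numeric matrix (samples x buckets) with sample ids as row
#'   names and bucket ids as column names.
#' @export
fm_values <- function(fm) {
  buckets <- attr(fm, "buckets")
  m <- as.matrix(as.data.frame(fm)[, buckets, drop = FALSE])
  rownames(m) <- fm$sample_id
  m
}

#' Bucket ids kept in a feature matrix
#' @param fm A `feature_matrix`.
#' @return Character vector of bucket ids (format `"rtIdx_mzIdx"`).
#' @export
fm_buckets <- function(fm) attr(fm, "buckets")

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d buckets (+ %s), %d out-of-range peak(s)\n",
              nrow(x), length(attr(x, "buckets")),
              if (length(attr(x, "meta_cols"))) paste(attr(x, "meta_cols"), collapse = ", ")
              else "no metadata",
              attr(x, "n_out_of_range")))
  NextMethod()
}
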