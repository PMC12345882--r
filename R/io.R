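#' Read centroided peak lists with sample metadata
#'
#' Reads one peak table per sample — CSV with columns `mz` (Da), `rt`
#' (seconds), `intensity`, or centroided mzML — and joins the metadata
#' table by `sample_id` (taken from the file base name).  A sample missing
#' from the metadata is a hard error naming the sample; malformed CSV rows
#' are reported with their line numbers.
#'
#' @param paths Character vector of peak-table files.
#' @param metadata A metadata tibble (`sample_id`, `day`, label columns) or
#'   the path of a metadata CSV.
#' @param format `"csv"` or `"mzml"`.
#' @return A list with `peaks` (tibble `sample_id`, `mz`, `rt`,
#'   `intensity`) and `samples` (the metadata rows in file order).
#' @export
read_peaklists <- function(paths, metadata, format = c("csv", "mzml")) {
  format <- match.arg(format)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  ids <- sub("\\.(csv|mzML|mzml)$", "", basename(paths))
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing) > 0)
    abort(sprintf("sample(s) present in data but absent from metadata: %s",
                  paste(missing, collapse = ", ")))
  peaks <- map2(paths, ids, function(p, id) {
    pk <- if (format == "csv") read_peak_csv(p) else read_mzml(p)
    pk$sample_id <- id
    relocate(pk, "sample_id")
  }) |> purrr::list_rbind()
  list(peaks = peaks,
       samples = metadata[match(ids, metadata$sample_id), , drop = FALSE])
}

#' Read one peak-table CSV (columns mz, rt, intensity)
#' @param path File path.
#' @return A tibble with `mz`, `rt`, `intensity`.
#' @export
read_peak_csv <- function(path) {
  pk <- readr::read_csv(path, col_types = readr::cols(
    mz = readr::col_double(), rt = readr::col_double(),
    intensity = readr::col_double()
  ), progress = FALSE)
  probs <- readr::problems(pk)
  if (nrow(probs) > 0)
    abort(sprintf("malformed rows in %s (lines %s)", path,
                  paste(unique(probs$row), collapse = ", ")))
  if (!all(c("mz", "rt", "intensity") %in% names(pk)))
    abort(sprintf("%s lacks mz/rt/intensity columns", path))
  pk[, c("mz", "rt", "intensity")]
}

#' Read a metadata CSV (sample_id, day, label columns; empty = unknown)
#' @param path File path.
#' @return A tibble with `NA` for empty label fields.
#' @export
read_metadata <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    day = readr::col_integer(), .default = readr::col_character()
  ), na = c("", "NA"), progress = FALSE)
}

#' Write a cohort as per-sample peak CSVs plus a metadata CSV
#'
#' @param cohort An `ms_cohort` (or a list with `peaks` and `samples`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths (metadata last).
#' @export
write_peaklists <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- map_chr(unique(cohort$peaks$sample_id), function(id) {
    p <- file.path(dir, paste0(id, ".csv"))
    readr::write_csv(cohort$peaks[cohort$peaks$sample_id == id,
                                  c("mz", "rt", "intensity")], p, progress = FALSE)
    p
  })
  meta_path <- file.path(dir, "metadata.csv")
  readr::write_csv(cohort$samples, meta_path, na = "", progress = FALSE)
  invisible(c(paths, meta_path))
}

#' Read a centroided mzML file into a peak table
#'
#' Requires the mzR package.  Retention times are taken in seconds as
#' stored by mzR; each spectrum's peaks inherit its retention time.
#' Profile-mode (non-centroided) spectra are an error, not silently
#' centroided.
#'
#' @param path mzML file.
#' @return A tibble with `mz`, `rt`, `intensity`.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    abort("reading mzML requires the mzR package")
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  if (any(!is.na(hdr$centroided) & !hdr$centroided))
    abort(sprintf("%s contains non-centroided spectra; centroid upstream", path))
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  purrr::list_rbind(map2(pk, hdr$retentionTime, function(m, rt) {
    tibble(mz = unname(m[, 1]), rt = rt, intensity = unname(m[, 2]))
  })) |> arrange(.data$rt, .data$mz)
}

#' Write a peak table as centroided mzML
#'
#' Peaks sharing one retention time become one pseudo-spectrum, so the
#' (mz, rt, intensity) triples round-trip exactly through
#' [read_mzml()].  Requires the mzR package.
#'
#' @param peaks A tibble with `mz`, `rt`, `intensity`.
#' @param path Output mzML file.
#' @return Invisibly, `path`.
#' @export
write_mzml <- function(peaks, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    abort("writing mzML requires the mzR package")
  peaks <- arrange(peaks, .data$rt, .data$mz)
  rts <- unique(peaks$rt)
  spectra <- map(rts, function(r) {
    s <- peaks[peaks$rt == r, ]
    cbind(mz = s$mz, intensity = s$intensity)
  })
  hdr <- purrr::list_rbind(map2(spectra, seq_along(spectra), function(s, i) {
    tibble(
      seqNum = i, acquisitionNum = i, msLevel = 1L, polarity = 1L,
      peaksCount = nrow(s), totIonCurrent = sum(s[, 2]),
      retentionTime = rts[i], basePeakMZ = s[which.max(s[, 2]), 1],
      basePeakIntensity = max(s[, 2]), collisionEnergy = 0, ionisationEnergy = 0,
      lowMZ = min(s[, 1]), highMZ = max(s[, 1]),
      precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
      precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
      mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
      injectionTime = 0, filterString = NA_character_,
      spectrumId = sprintf("scan=%d", i), centroided = TRUE,
      ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
      isolationWindowLowerOffset = NA_real_, isolationWindowUpperOffset = NA_real_,
      scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_
    )
  }))
  mzR::writeMSData(spectra, file = path, header = as.data.frame(hdr))
  invisible(path)
}

#' Serialize a feature matrix as CSV plus a JSON sidecar
#'
#' The CSV holds the samples x buckets table (metadata columns included);
#' the sidecar (`<path>.json`) records the grid parameters, the kept-bucket
#' list, the metadata columns and an optional seed, so the standardized
#' structure can be restored exactly and new samples projected onto it.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV output path.
#' @param seed Optional integer recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(fm, path, seed = NULL) {
  readr::write_csv(as_tibble(fm), path, na = "", progress = FALSE)
  grid <- attr(fm, "grid")
  sidecar <- list(
    grid = grid[c("rt_width", "mz_width", "rt_range", "mz_range")],
    buckets = attr(fm, "buckets"),
    meta_cols = attr(fm, "meta_cols"),
    n_out_of_range = attr(fm, "n_out_of_range"),
    seed = seed
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Restore a feature matrix written by [write_feature_matrix()]
#' @param path CSV path (the `<path>.json` sidecar must sit beside it).
#' @return A `feature_matrix` with grid and kept-bucket attributes restored.
#' @export
read_feature_matrix <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- bucket_grid(rt_width = sidecar$grid$rt_width, mz_width = sidecar$grid$mz_width,
                      rt_range = sidecar$grid$rt_range, mz_range = sidecar$grid$mz_range)
  meta_cols <- sidecar$meta_cols %||% character()
  tbl <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), day = readr::col_integer(),
    .default = readr::col_guess()
  ), na = c("", "NA"), progress = FALSE)
  for (mc in setdiff(meta_cols, "day")) tbl[[mc]] <- as.character(tbl[[mc]])
  new_feature_matrix(tbl[, c("sample_id", meta_cols, sidecar$buckets)], grid,
                     sidecar$buckets, meta_cols,
                     sidecar$n_out_of_range %||% 0L)
}

#' Write a confusion matrix as CSV (rows = predicted, columns = true)
#' @param cm A `confusion_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_confusion <- function(cm, path) {
  m <- unclass(as.matrix(cm))
  attr(m, "n_unscored") <- NULL
  tbl <- bind_cols(tibble(predicted = rownames(m)),
                   as_tibble(m, .name_repair = "minimal"))
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a confusion matrix written by [write_confusion()]
#' @param path CSV path.
#' @return A `confusion_matrix`.
#' @export
read_confusion <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    predicted = readr::col_character(), .default = readr::col_integer()
  ), progress = FALSE)
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl$predicted
  confusion_matrix(m)
}

#' Write a selection result as CSV, and its selected set as plain ids
#'
#' @param x A `boruta_result`.
#' @param path CSV output (feature, decision, hits, runs, decision_iter).
#' @param selected_path Optional path for the newline-delimited confirmed
#'   bucket ids consumed by intersection analysis.
#' @return Invisibly, `path`.
#' @export
write_selection <- function(x, path, selected_path = NULL) {
  readr::write_csv(as_tibble(x), path, na = "", progress = FALSE)
  if (!is.null(selected_path)) writeLines(selected_features(x), selected_path)
  invisible(path)
}

#' Published confusion matrices of the apple authentication cohort
#'
#' Out-of-bag confusion matrices reported for a 193-sample apple cohort
#' classified by geographical origin (German / non-German), region within
#' Germany (North / South), production method (conventional / organic) and
#' six taxonomic varieties.  Shipped as plain CSV under
#' `inst/extdata/reference_confusion/`; used as worked-example input for
#' [accuracy()], [sensitivity()] and [confusion_metrics()].
#'
#' @param issue One of `"origin"`, `"region"`, `"production"`, `"variety"`.
#' @return A `confusion_matrix` (rows = predicted, columns = true).
#' @examples
#' accuracy(reference_confusion("origin"))  # 93.3
#' @export
reference_confusion <- function(issue = c("origin", "region", "production", "variety")) {
  issue <- match.arg(issue)
  read_confusion(system.file("extdata", "reference_confusion",
                             paste0(issue, ".csv"), package = "bucketforest",
                             mustWork = TRUE))
}
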