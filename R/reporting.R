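#' Overall accuracy of a confusion matrix
#'
#' `100 * trace / total`, reported in percent at one decimal (halves up),
#' matching how authentication studies print it.
#'
#' @param cm A `confusion_matrix` (rows = predicted, columns = true) or a
#'   square count matrix.
#' @param digits Decimal places (default 1).
#' @return Accuracy in percent.
#' @examples
#' cm <- confusion_matrix(matrix(c(112, 5, 8, 68), 2, 2,
#'   dimnames = list(c("German", "non-German"), c("German", "non-German"))))
#' accuracy(cm)  # 93.3
#' @export
accuracy <- function(cm, digits = 1) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix")
  round_half_up(100 * sum(diag(cm)) / total, digits)
}

#' Per-class sensitivity (recall) of a confusion matrix
#'
#' For one class: the percentage of its true members predicted as it,
#' `100 * cm[class, class] / column total`.
#'
#' @param cm A `confusion_matrix` (rows = predicted, columns = true).
#' @param class Class name (must be a column of `cm`).
#' @param digits Decimal places (default 1).
#' @return Sensitivity in percent.
#' @export
sensitivity <- function(cm, class, digits = 1) {
  cm <- as.matrix(cm)
  if (!class %in% colnames(cm)) abort(sprintf("class '%s' absent from confusion matrix", class))
  total <- sum(cm[, class])
  if (total == 0) abort(sprintf("class '%s' has no true samples", class))
  round_half_up(100 * cm[class, class] / total, digits)
}

#' Summary metrics of a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @param digits Decimal places (default 1).
#' @return A `metric_report` tibble: one row per class with `n` (true
#'   members) and `sensitivity`, plus the overall `accuracy` repeated for
#'   convenience.
#' @export
confusion_metrics <- function(cm, digits = 1) {
  m <- as.matrix(cm)
  out <- tibble(
    class = colnames(m),
    n = as.integer(colSums(m)),
    sensitivity = map_dbl(colnames(m), ~ sensitivity(cm, .x, digits)),
    accuracy = accuracy(cm, digits)
  )
  structure(out, class = c("metric_report", class(tibble())))
}

#' PCA scores for batch diagnostics
#'
#' Column-mean-centered (unscaled) principal components of the bucket
#' values, for checking whether samples group by measurement day rather
#' than by class.  Total-intensity-normalized buckets are already on a
#' common scale, so no unit-variance scaling is applied.
#'
#' @param fm A `feature_matrix` (or numeric matrix).
#' @param k Number of components (reduced to the matrix rank, with a
#'   warning, if too large).
#' @param subset Optional logical/integer row subset (e.g. one
#'   authentication issue's samples).
#' @return A `pca_scores` tibble: `sample_id`, metadata columns, `PC1..PCk`;
#'   attribute `explained` holds the explained-variance fractions.
#' @export
pca_scores <- function(fm, k = 2, subset = NULL) {
  is_fm <- inherits(fm, "feature_matrix")
  x <- if (is_fm) fm_values(fm) else as.matrix(fm)
  meta <- if (is_fm) {
    as_tibble(fm)[, c("sample_id", attr(fm, "meta_cols")), drop = FALSE]
  } else {
    tibble(sample_id = rownames(x) %||% as.character(seq_len(nrow(x))))
  }
  if (!is.null(subset)) {
    x <- x[subset, , drop = FALSE]
    meta <- meta[subset, , drop = FALSE]
  }
  if (nrow(x) < 2) abort("need >= 2 samples for PCA")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (k > rank) {
    warn(sprintf("k = %d exceeds rank %d; using k = %d", k, rank, rank))
    k <- rank
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  explained <- pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)
  out <- bind_cols(meta, as_tibble(scores))
  structure(out, class = c("pca_scores", class(tibble())),
            explained = explained)
}

#' Exclusive intersections of selected-variable sets (UpSet counts)
#'
#' For every nonempty subset `S` of the issue names, counts the variables
#' selected for all issues in `S` and for none outside `S`.  The counts
#' partition the union of all selected sets.
#'
#' @param sets Named list of character vectors (one selected set per
#'   authentication issue).
#' @return An `intersection_report` tibble: `issues` (list-column of issue
#'   names), `label` (`"a & b"`), `degree`, `count`, sorted by degree then
#'   decreasing count; attribute `union_size`.
#' @examples
#' exclusive_intersections(list(A = c("1", "2"), B = c("2", "3")))
#' @export
exclusive_intersections <- function(sets) {
  if (length(sets) < 1 || is.null(names(sets))) abort("need a named list of >= 1 set")
  issues <- names(sets)
  members <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) members %in% s,
                       logical(length(members)))
  if (length(members) == 1L) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, issues))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(issues)))[-1, , drop = FALSE]
  names(subsets) <- issues
  counts <- apply(subsets, 1, function(pat) {
    if (length(members) == 0L) return(0L)
    sum(apply(membership, 1, function(row) all(row == pat)))
  })
  out <- tibble(
    issues = map(seq_len(nrow(subsets)), ~ issues[as.logical(unlist(subsets[.x, ]))]),
    label = map_chr(.data$issues, paste, collapse = " & "),
    degree = lengths(.data$issues),
    count = as.integer(counts)
  ) |> arrange(.data$degree, dplyr::desc(.data$count))
  structure(out, class = c("intersection_report", class(tibble())),
            union_size = length(members), set_sizes = lengths(sets))
}
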