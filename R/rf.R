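#' Random-forest configuration
#'
#' Mirrors the model configuration used throughout: 5000 trees, `mtry` at
#' its default `floor(sqrt(p))`, minimum node size 1, no tuning, and
#' per-sample case weights compensating class imbalance.  The weights act as
#' per-draw bootstrap sampling probabilities, so each tree's bootstrap is
#' expected to be class-balanced.
#'
#' @param n_trees Number of trees (default 5000).
#' @param mtry Candidate features per split; `NULL` means `floor(sqrt(p))`
#'   at fit time.
#' @param min_node_size Minimal terminal node size (default 1).
#' @param case_weight_mode `"inverse_class"` (default; weight
#'   `1 / (K * n_class)`, so each class carries total weight `1/K`) or
#'   `"uniform"`.
#' @param seed Integer seed for tree growing and bootstrap draws.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 5000, mtry = NULL, min_node_size = 1,
                      case_weight_mode = c("inverse_class", "uniform"),
                      seed = 1L) {
  if (n_trees < 1) abort("n_trees must be >= 1")
  if (min_node_size < 1) abort("min_node_size must be >= 1")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 case_weight_mode = match.arg(case_weight_mode),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Class-imbalance-compensating case weights
#'
#' In `"inverse_class"` mode sample `i` of class `c` gets
#' `w_i = 1 / (K * n_c)` with `K` classes, so every class's total weight is
#' `1/K` and the weights sum to 1; used as per-draw bootstrap probabilities
#' this makes the expected bootstrap composition class-balanced.
#'
#' @param labels Vector/factor of class labels (>= 2 nonempty classes in
#'   inverse mode).
#' @param mode `"inverse_class"` or `"uniform"`.
#' @return Numeric weights, one per sample, summing to 1.
#' @examples
#' class_weights(c("A", "A", "A", "B"))
#' @export
class_weights <- function(labels, mode = c("inverse_class", "uniform")) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  if (anyNA(labels)) abort("labels must not contain NA")
  n <- length(labels)
  if (mode == "uniform") return(rep(1 / n, n))
  tab <- table(labels)
  if (length(tab) < 2) abort("need >= 2 classes for inverse-class weights")
  if (any(tab == 0)) abort("a class with zero samples signals a design error")
  k <- length(tab)
  as.numeric(1 / (k * tab[labels]))
}

#' Train a class-weighted random forest and evaluate it out-of-bag
#'
#' Grows `n_trees` classification trees (Gini impurity, `mtry` random
#' candidate features per split, nodes grown down to `min_node_size`), each
#' on a bootstrap of size `n` drawn with replacement with probability
#' proportional to the case weights.  Every tree's bootstrap is recorded;
#' out-of-bag (OOB) predictions are aggregated in-package from the recorded
#' in-bag counts and per-tree votes: a sample's OOB prediction is the
#' majority vote over the trees whose bootstrap excluded it, ties broken by
#' class order (factor level order of the labels).  Samples drawn into every
#' bootstrap are flagged (`NA` prediction), not dropped.
#'
#' Tree growing is delegated to ranger; the sampling contract and the OOB
#' bookkeeping live here and are verifiable from the returned in-bag matrix.
#'
#' @param fm A `feature_matrix` (or plain tibble with bucket columns).
#' @param layer Name of the label column to classify.
#' @param config An [rf_config()].
#' @return An `rf_fit` with elements `oob` (tibble: `sample_id`, `truth`,
#'   `estimate`, `n_oob_trees`), `votes` (OOB vote-fraction matrix),
#'   `inbag` (samples x trees bootstrap counts), `classes`, `weights`,
#'   `config`, `layer`, and the underlying `forest`.
#' @seealso [oob_confusion()], [tidy.rf_fit()], [glance.rf_fit()]
#' @export
train_forest <- function(fm, layer, config = rf_config()) {
  x <- if (inherits(fm, "feature_matrix")) {
    fm_values(fm)
  } else {
    num <- vapply(fm, is.numeric, logical(1)) & !names(fm) %in% c("day", layer)
    as.matrix(as.data.frame(fm)[, num, drop = FALSE])
  }
  labels <- fm[[layer]]
  if (is.null(labels)) abort(sprintf("no label column '%s'", layer))
  if (anyNA(labels)) abort(sprintf("layer '%s' has unlabeled samples; subset first", layer))
  y <- factor(labels)
  if (nlevels(y) < 2) abort(sprintf("layer '%s' has a single class", layer))
  if (ncol(x) < 1) abort("need at least one feature")
  mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(x))))
  if (mtry < 1 || mtry > ncol(x)) abort("mtry must be in [1, p]")
  w <- class_weights(y, config$case_weight_mode)

  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = config$n_trees, mtry = mtry,
    min.node.size = config$min_node_size,
    splitrule = "gini",
    case.weights = w, replace = TRUE, sample.fraction = 1,
    keep.inbag = TRUE, seed = config$seed, num.threads = 1
  )

  inbag <- do.call(cbind, fit$inbag.counts)          # n x trees bootstrap record
  tree_pred <- predict(fit, data = x, predict.all = TRUE,
                       num.threads = 1)$predictions  # n x trees class indices
  oob_mask <- inbag == 0
  k <- nlevels(y)
  votes <- vapply(seq_len(k), function(cl) rowSums((tree_pred == cl) & oob_mask),
                  numeric(nrow(x)))
  n_oob <- rowSums(oob_mask)
  frac <- votes
  frac[n_oob > 0, ] <- votes[n_oob > 0, , drop = FALSE] / n_oob[n_oob > 0]
  colnames(frac) <- levels(y)
  # majority vote; max.col "first" = ties to the earlier class level
  est <- factor(levels(y)[max.col(votes, ties.method = "first")], levels = levels(y))
  est[n_oob == 0] <- NA
  if (any(n_oob == 0))
    warn(sprintf("%d sample(s) appeared in every bootstrap and have no OOB prediction",
                 sum(n_oob == 0)))

  sample_ids <- fm$sample_id %||% rownames(x) %||% as.character(seq_len(nrow(x)))
  structure(list(
    oob = tibble(sample_id = sample_ids, truth = y, estimate = est, n_oob_trees = n_oob),
    votes = frac, inbag = inbag, classes = levels(y), weights = w,
    mtry = mtry, config = config, layer = layer, forest = fit
  ), class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("<rf_fit> layer '%s': %d samples, %d classes, %d trees, mtry %d\n",
              x$layer, nrow(x$oob), length(x$classes), x$config$n_trees, x$mtry))
  cat(sprintf("  OOB accuracy: %.1f%%\n", glance(x)$accuracy))
  invisible(x)
}

#' Out-of-bag confusion matrix
#'
#' Cross-tabulates OOB-predicted against true classes, oriented rows =
#' predicted, columns = true.  Samples without an OOB prediction are
#' excluded and counted in the `n_unscored` attribute, so the table total
#' equals the number of OOB-evaluable samples.
#'
#' @param x An `rf_fit`, or a tibble/list with `truth` and `estimate`.
#' @return A `confusion_matrix`: integer matrix, predicted x true.
#' @export
oob_confusion <- function(x) {
  oob <- if (inherits(x, "rf_fit")) x$oob else x
  ok <- !is.na(oob$estimate)
  m <- t(table(true = oob$truth[ok], predicted = oob$estimate[ok]))
  confusion_matrix(unclass(as.matrix(m)), n_unscored = sum(!ok))
}

#' Construct a confusion matrix (rows = predicted, columns = true)
#'
#' @param counts Square nonnegative integer matrix; row and column names are
#'   the classes in matching order.
#' @param n_unscored Samples excluded for lack of an OOB prediction.
#' @return A `confusion_matrix`.
#' @examples
#' confusion_matrix(matrix(c(112, 5, 8, 68), 2, 2,
#'   dimnames = list(c("German", "non-German"), c("German", "non-German"))))
#' @export
confusion_matrix <- function(counts, n_unscored = 0L) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) abort("confusion matrix must be square")
  if (any(counts < 0)) abort("confusion counts must be nonnegative")
  if (is.null(rownames(counts)) && !is.null(colnames(counts))) rownames(counts) <- colnames(counts)
  if (is.null(colnames(counts)) && !is.null(rownames(counts))) colnames(counts) <- rownames(counts)
  structure(counts, class = "confusion_matrix", n_unscored = as.integer(n_unscored))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = predicted, columns = true\n")
  print(unclass(x))
  invisible(x)
}
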