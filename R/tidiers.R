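#' Tidy an OOB-evaluated random forest
#'
#' One row per class: true-member count, OOB sensitivity (percent), and the
#' class's total case weight.
#'
#' @param x An `rf_fit`.
#' @param ... Unused.
#' @return A tibble with `class`, `n`, `sensitivity`, `class_weight`.
#' @export
tidy.rf_fit <- function(x, ...) {
  cm <- oob_confusion(x)
  metrics <- confusion_metrics(cm)
  wt <- tapply(x$weights, x$oob$truth, sum)
  tibble(class = metrics$class, n = metrics$n,
         sensitivity = metrics$sensitivity,
         class_weight = as.numeric(wt[metrics$class]))
}

#' One-row summary of an OOB-evaluated random forest
#'
#' @param x An `rf_fit`.
#' @param ... Unused.
#' @return A tibble with `layer`, `n`, `n_features`, `n_classes`,
#'   `n_trees`, `mtry`, `accuracy` (OOB, percent) and `n_unscored`.
#' @export
glance.rf_fit <- function(x, ...) {
  cm <- oob_confusion(x)
  tibble(layer = x$layer, n = nrow(x$oob),
         n_features = x$forest$num.independent.variables,
         n_classes = length(x$classes),
         n_trees = x$config$n_trees, mtry = x$mtry,
         accuracy = accuracy(cm),
         n_unscored = attr(cm, "n_unscored"))
}

#' Tidy a selection result
#'
#' @param x A `boruta_result`.
#' @param ... Unused.
#' @return The per-feature decision tibble (`feature`, `decision`, `hits`,
#'   `runs`, `decision_iter`).
#' @export
tidy.boruta_result <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a selection result
#'
#' @param x A `boruta_result`.
#' @param ... Unused.
#' @return A tibble with `layer`, `n_features`, `n_confirmed`,
#'   `n_tentative`, `n_rejected`, `n_runs`, `backend`.
#' @export
glance.boruta_result <- function(x, ...) {
  tab <- table(x$decision)
  tibble(layer = attr(x, "layer"), n_features = nrow(x),
         n_confirmed = as.integer(tab[["confirmed"]]),
         n_tentative = as.integer(tab[["tentative"]]),
         n_rejected = as.integer(tab[["rejected"]]),
         n_runs = attr(x, "n_runs"),
         backend = attr(x, "config")$backend)
}

#' Tidy a confusion matrix into long counts
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble with `predicted`, `true`, `count`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  m <- as.matrix(x)
  tidyr::expand_grid(predicted = rownames(m), true = colnames(m)) |>
    mutate(count = as.integer(m[cbind(.data$predicted, .data$true)]))
}

#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble(n = sum(as.matrix(x)), n_classes = ncol(as.matrix(x)),
         accuracy = accuracy(x), n_unscored = attr(x, "n_unscored") %||% 0L)
}
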