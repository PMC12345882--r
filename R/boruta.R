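#' All-relevant selection configuration
#'
#' Parameters of the Boruta-style shadow-feature selection: the decision
#' p-value (Bonferroni-corrected over the initial feature count), the run
#' cap, the importance backend of the inner forests, and the inner
#' random-forest configuration.  Inner forests default to 500 trees — enough
#' for stable importance ranking at feature-matrix sizes, far cheaper than
#' the final classification forests.
#'
#' @param p_value Two-sided binomial-test level (default 0.01).
#' @param max_runs Maximum shadow runs (default 100).
#' @param backend `"impurity_corrected"` (default; the bias-corrected
#'   impurity importance) or `"permutation"` (mean decrease in OOB accuracy
#'   under per-feature permutation).
#' @param rf An [rf_config()] for the inner forests.
#' @param seed Integer seed for shadow permutations and inner forests.
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_value = 0.01, max_runs = 100,
                             backend = c("impurity_corrected", "permutation"),
                             rf = rf_config(n_trees = 500),
                             seed = 1L) {
  if (p_value <= 0 || p_value >= 1) abort("p_value must be in (0, 1)")
  if (max_runs < 1) abort("max_runs must be >= 1")
  structure(list(p_value = p_value, max_runs = as.integer(max_runs),
                 backend = match.arg(backend), rf = rf, seed = as.integer(seed)),
            class = "selection_config")
}

#' Append permuted shadow copies of every feature
#'
#' Each real column gets a copy whose values are permuted across samples:
#' the shadow keeps the feature's marginal distribution but carries no label
#' association, providing the importance null that real features must beat.
#' Uses the current RNG state.
#'
#' @param x Numeric matrix (samples x features) or `feature_matrix`.
#' @return A numeric matrix with `2p` columns; shadow columns are named
#'   `shadow_<feature>` and flagged in the `is_shadow` attribute.
#' @export
shadow_augment <- function(x) {
  if (inherits(x, "feature_matrix")) x <- fm_values(x)
  if (ncol(x) < 1) abort("need at least one feature")
  shadows <- apply(x, 2, sample)
  if (!is.matrix(shadows)) shadows <- matrix(shadows, nrow = nrow(x))
  colnames(shadows) <- paste0("shadow_", colnames(x))
  aug <- cbind(x, shadows)
  attr(aug, "is_shadow") <- c(rep(FALSE, ncol(x)), rep(TRUE, ncol(x)))
  aug
}

#' Per-feature random-forest importance
#'
#' Fits one inner forest and returns its variable importance.  The
#' `"permutation"` backend is the mean decrease in OOB accuracy when the
#' feature is permuted, averaged over trees; `"impurity_corrected"` is the
#' bias-corrected (actual-impurity-reduction) Gini importance, which is
#' unbiased under the null and comparable across feature scales.
#'
#' @param x Numeric matrix (samples x features).
#' @param y Class labels (factor or coercible).
#' @param backend `"impurity_corrected"` or `"permutation"`.
#' @param config An [rf_config()] for the forest (its
#'   `case_weight_mode` is honoured).
#' @param seed Seed for this forest (defaults to `config$seed`).
#' @return Named numeric vector of importances, one per column of `x`; the
#'   backend is recorded in the `backend` attribute.
#' @export
rf_importance <- function(x, y, backend = c("impurity_corrected", "permutation"),
                          config = rf_config(n_trees = 500), seed = config$seed) {
  backend <- match.arg(backend)
  y <- factor(y)
  w <- class_weights(y, config$case_weight_mode)
  mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(x))))
  fit <- ranger::ranger(
    x = x, y = y, num.trees = config$n_trees, mtry = min(mtry, ncol(x)),
    min.node.size = config$min_node_size, splitrule = "gini",
    case.weights = w, importance = backend,
    seed = seed, num.threads = 1
  )
  imp <- fit$variable.importance
  attr(imp, "backend") <- backend
  imp
}

#' Boruta-style all-relevant feature selection
#'
#' Iterates up to `max_runs` times: permuted shadow copies of all still-active
#' features are appended, an inner forest is trained on the augmented
#' matrix, and every real feature whose importance exceeds the maximum
#' shadow importance scores a hit.  After each run, each undecided feature's
#' hit count is tested against Binomial(runs, 1/2), one-sided in each
#' direction at level `p_value` Bonferroni-corrected over the initial
#' feature count: significantly more hits confirms the feature,
#' significantly fewer rejects it (and removes it from later runs).
#' Features undecided at the run cap remain `tentative`; only `confirmed`
#' features enter the selected set.
#'
#' @param fm A `feature_matrix` (or numeric matrix with a separate `labels`
#'   argument via `layer`).
#' @param layer Label column to select against.
#' @param config A [selection_config()].
#' @return A `boruta_result`: tibble with `feature`, `decision`
#'   (`confirmed`/`tentative`/`rejected`), `hits`, `runs`, `decision_iter`;
#'   attributes record the config, layer, runs executed and the per-run
#'   cumulative hit history.
#' @seealso [selected_features()], [shadow_augment()], [rf_importance()]
#' @export
boruta_select <- function(fm, layer, config = selection_config()) {
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
  p <- ncol(x)
  features <- colnames(x) %||% as.character(seq_len(p))
  colnames(x) <- features

  decision <- rep("tentative", p)
  hits <- integer(p)
  runs_part <- integer(p)
  decision_iter <- rep(NA_integer_, p)
  alpha <- config$p_value / p     # Bonferroni over initially active features
  history <- list()

  withr::with_seed(config$seed, {
    for (run in seq_len(config$max_runs)) {
      active <- decision != "rejected"
      if (!any(active)) break
      aug <- shadow_augment(x[, active, drop = FALSE])
      imp <- rf_importance(aug, y, backend = config$backend, config = config$rf,
                           seed = derive_seed(config$seed, run))
      is_shadow <- attr(aug, "is_shadow")
      max_shadow <- max(imp[is_shadow])
      hit <- imp[!is_shadow] > max_shadow
      idx <- which(active)
      hits[idx] <- hits[idx] + hit
      runs_part[idx] <- runs_part[idx] + 1L
      history[[run]] <- hits

      undecided <- which(decision == "tentative")
      p_hi <- pbinom(hits[undecided] - 1L, runs_part[undecided], 0.5, lower.tail = FALSE)
      p_lo <- pbinom(hits[undecided], runs_part[undecided], 0.5)
      newly_conf <- undecided[p_hi < alpha]
      newly_rej <- undecided[p_lo < alpha]
      decision[newly_conf] <- "confirmed"
      decision[newly_rej] <- "rejected"
      decision_iter[c(newly_conf, newly_rej)] <- run
      if (!any(decision == "tentative")) break
    }
  })

  res <- tibble(
    feature = features,
    decision = factor(decision, levels = c("confirmed", "tentative", "rejected")),
    hits = hits, runs = runs_part, decision_iter = decision_iter
  )
  structure(res, class = c("boruta_result", class(tibble())),
            layer = layer, config = config,
            n_runs = length(history),
            history = do.call(rbind, history))
}

#' Features confirmed by a selection
#'
#' Tentative features are excluded: the selected set fed to intersection
#' analysis contains confirmed features only.
#'
#' @param x A `boruta_result`.
#' @return Character vector of confirmed feature (bucket) ids.
#' @export
selected_features <- function(x) {
  as.character(x$feature[x$decision == "confirmed"])
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$decision)
  cat(sprintf("<boruta_result> layer '%s': %d confirmed, %d tentative, %d rejected (%d run(s), backend %s)\n",
              attr(x, "layer"), tab[["confirmed"]], tab[["tentative"]], tab[["rejected"]],
              attr(x, "n_runs"), attr(x, "config")$backend))
  invisible(x)
}
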