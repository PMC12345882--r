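#' Plot PCA scores colored by a label, annotated by measurement day
#'
#' The standard batch diagnostic: if points with the same day number
#' cluster together regardless of color, measurement day dominates the
#' variance and unsupervised analysis of the classes is off the table.
#'
#' @param object A `pca_scores` tibble.
#' @param colour Column to color by (default the first metadata label).
#' @param label Column to print at each point (default `"day"` when
#'   present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_scores <- function(object,
                                colour = setdiff(names(object), c("sample_id", "day", "PC1", "PC2"))[1],
                                label = if ("day" %in% names(object)) "day" else NULL,
                                ...) {
  ev <- attr(object, "explained")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2])
    ) +
    ggplot2::theme_bw()
  if (!is.null(label)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data[[label]],
                                             colour = .data[[colour]]), size = 3)
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  }
  p
}

#' UpSet-style plot of exclusive intersections
#'
#' Bars give the number of variables selected for exactly the subset of
#' issues marked by the dot matrix underneath (single dots = variables
#' relevant to one issue only; connected dots = shared variables).
#'
#' @param object An `intersection_report`.
#' @param drop_empty Hide subsets with zero count (default `TRUE`).
#' @param ... Unused.
#' @return A patchwork of two ggplots (bars over dot matrix).
#' @export
autoplot.intersection_report <- function(object, drop_empty = TRUE, ...) {
  dat <- as_tibble(object)
  if (drop_empty) dat <- filter(dat, .data$count > 0)
  if (nrow(dat) == 0) abort("no nonempty intersections to plot")
  dat <- arrange(dat, .data$degree, dplyr::desc(.data$count))
  dat$pos <- factor(seq_len(nrow(dat)))
  issues <- unique(unlist(dat$issues))

  bars <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = .data$count)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Selected variables") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())

  dots <- tidyr::expand_grid(pos = dat$pos, issue = issues) |>
    mutate(on = map2(.data$pos, .data$issue,
                     ~ .y %in% dat$issues[[as.integer(.x)]]) |> unlist())
  matrixp <- ggplot2::ggplot(dots, ggplot2::aes(x = .data$pos,
                                                y = factor(.data$issue, levels = rev(issues)))) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$on), size = 3, colour = "grey25") +
    ggplot2::geom_line(data = filter(dots, .data$on),
                       ggplot2::aes(group = .data$pos), colour = "grey25") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.15), guide = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())

  patchwork::wrap_plots(bars, matrixp, ncol = 1, heights = c(2.5, 1))
}
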