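#' Plot an evaluation report
#'
#' Box (or point, for single-unit schemes) plot of per-unit AUC scores by
#' model.
#'
#' @param object A `pcmt_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcmt_evaluation <- function(object, ...) {
  dat <- object$auc_scores
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$model, y = .data$auc)) +
    ggplot2::labs(x = NULL, y = "AUC",
                  title = sprintf("Cross-validation AUC (%s)", object$scheme)) +
    ggplot2::theme_minimal()
  if (length(unique(dat$unit)) > 1) {
    p + ggplot2::geom_boxplot()
  } else {
    p + ggplot2::geom_point(size = 3)
  }
}

#' Plot a robustness report
#'
#' Mean observed-over-expected overlap ratio per expected-overlap level, one
#' line per model, with one standard error around the mean.
#'
#' @param object A `pcmt_robustness`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcmt_robustness <- function(object, ...) {
  dat <- object$ratios |>
    dplyr::group_by(.data$model, .data$level) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio),
                     se = sd(.data$ratio) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$level, y = .data$mean_ratio,
                                    colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_ratio - .data$se,
                                          ymax = .data$mean_ratio + .data$se)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Expected chance overlap", y = "Observed / expected overlap",
                  title = "Split-half feature robustness") +
    ggplot2::theme_minimal()
}

#' Plot a gene ranking
#'
#' Bar chart of the ranked mean absolute coefficients, faceted by subtype.
#'
#' @param object A `pcmt_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcmt_ranking <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$gene_id, .data$score),
                                    y = .data$score)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~subtype, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Mean |coefficient|",
                  title = "Top genes by mean absolute coefficient") +
    ggplot2::theme_minimal()
}

#' Plot per-test-sample selection sizes
#'
#' Boxplot of the number of selected training samples per threshold from a
#' [selection_summary()] table, the diagnostic behind choosing a threshold
#' grid.
#'
#' @param summary_tbl A tibble from [selection_summary()].
#' @return A ggplot object.
#' @export
plot_selection_sizes <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = factor(.data$threshold), y = .data$n_selected)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "PCC threshold", y = "Selected training samples") +
    ggplot2::theme_minimal()
}
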