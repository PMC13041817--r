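# ggplot2 views of classification results.

#' Plot the category distribution of a classified interaction list
#'
#' Stacked bar of subcategory counts within each category.
#'
#' @param object A `reconciled_tbl` from [classify_interactions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reconciled_tbl <- function(object, ...) {
  df <- dplyr::count(tibble::as_tibble(object), .data$category,
                     .data$subcategory)
  df$category <- factor(df$category, levels = CATEGORY_LEVELS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n,
                                   fill = .data$subcategory)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "interactions",
                  title = "Reconciliation categories") +
    ggplot2::theme_minimal()
}

#' Plot a reconciliation summary
#'
#' Normalized category distribution alongside baseline coverage.
#'
#' @param object A `reconciliation_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reconciliation_summary <- function(object, ...) {
  df <- object$counts
  df$category <- factor(df$category, levels = CATEGORY_LEVELS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction,
                                   fill = .data$subcategory)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "fraction of interactions",
                  title = "Normalized category distribution") +
    ggplot2::theme_minimal()
}

#' Bar plot of per-category precision/recall/F1
#'
#' @param object A `reconciliation_score` from [score_classification()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reconciliation_score <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_category,
                            c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Classification agreement") +
    ggplot2::theme_minimal()
}
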