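# Agreement scoring between predicted and expected classifications.

#' Score predicted classifications against a truth table
#'
#' One-vs-rest precision, recall and F1 per category, plus micro-accuracy
#' (fraction of rows whose predicted category equals the expected one).
#' Inputs are aligned by row and must have equal length.
#'
#' @param predicted Character vector of predicted categories, or a
#'   [classify_interactions()] result (its `category` column is used).
#' @param truth Character vector of expected categories, or a fixture
#'   truth table (pass the relevant `category_cs*` column).
#' @return A `reconciliation_score` object: list with `per_category`
#'   (tibble: category, n_expected, n_predicted, tp, precision, recall,
#'   f1) and `micro_accuracy`.
#' @export
#' @examples
#' score_classification(c("extension", "corroboration"),
#'                      c("extension", "contradiction"))
score_classification <- function(predicted, truth) {
  if (is.data.frame(predicted)) predicted <- predicted$category
  if (is.data.frame(truth)) truth <- truth[[1]]
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    abort(paste0("predicted (", length(predicted), ") and truth (",
                 length(truth), ") must have equal length"),
          class = "netreconcile_contract_error")
  }
  cats <- union(CATEGORY_LEVELS, union(unique(truth), unique(predicted)))
  per <- purrr::map_dfr(cats, function(cat) {
    tp <- sum(predicted == cat & truth == cat)
    np <- sum(predicted == cat)
    ne <- sum(truth == cat)
    precision <- if (np == 0) NA_real_ else tp / np
    recall <- if (ne == 0) NA_real_ else tp / ne
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
      NA_real_
    } else {
      2 * precision * recall / (precision + recall)
    }
    tibble(category = cat, n_expected = ne, n_predicted = np, tp = tp,
           precision = precision, recall = recall, f1 = f1)
  })
  structure(
    list(per_category = per,
         micro_accuracy = if (length(truth) == 0) NA_real_
                          else mean(predicted == truth),
         n = length(truth)),
    class = "reconciliation_score"
  )
}

#' @export
print.reconciliation_score <- function(x, ...) {
  cat("<reconciliation_score> micro-accuracy ",
      sprintf("%.3f", x$micro_accuracy), " over ", x$n, " rows\n", sep = "")
  print(x$per_category)
  invisible(x)
}

#' Per-category agreement metrics as a tibble
#'
#' @param x A `reconciliation_score`.
#' @param ... Unused.
#' @return Tibble of per-category precision/recall/F1.
#' @export
tidy.reconciliation_score <- function(x, ...) {
  x$per_category
}

#' One-row agreement overview
#'
#' @param x A `reconciliation_score`.
#' @param ... Unused.
#' @return One-row tibble with micro-accuracy and macro-averaged F1.
#' @export
glance.reconciliation_score <- function(x, ...) {
  tibble(n = x$n, micro_accuracy = x$micro_accuracy,
         macro_f1 = mean(x$per_category$f1, na.rm = TRUE))
}
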