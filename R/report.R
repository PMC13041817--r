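# Aggregation of classified interactions: category/subcategory
# distributions and baseline-coverage statistics.

CATEGORY_LEVELS <- c("corroboration", "contradiction", "flagged", "extension")

#' Summarize a classified interaction list
#'
#' Computes category and subcategory counts and fractions, and
#' baseline-edge coverage: a baseline edge counts as corroborated
#' (resp. contradicted) when at least one classified interaction of that
#' category matched it. By default (`coverage_mode = "path_edges"`)
#' path-mediated matches attribute coverage to every edge on the matched
#' path; `"edge_only"` restricts coverage to direct edge matches.
#'
#' @param classified A [classify_interactions()] result.
#' @param g The `baseline_graph` used for classification.
#' @param coverage_mode `"path_edges"` (default) or `"edge_only"`.
#' @return A `reconciliation_summary` object: list with `counts` (tibble:
#'   category, subcategory, n, fraction), `n_total`, `coverage` (tibble:
#'   corroborated/contradicted edge counts and percent of baseline edges),
#'   `coverage_mode`.
#' @export
summarize_classification <- function(classified, g,
                                     coverage_mode = c("path_edges",
                                                       "edge_only")) {
  coverage_mode <- match.arg(coverage_mode)
  n <- nrow(classified)

  counts <- classified |>
    dplyr::count(.data$category, .data$subcategory, name = "n") |>
    dplyr::arrange(factor(.data$category, levels = CATEGORY_LEVELS),
                   .data$subcategory)
  counts$fraction <- if (n == 0) numeric(0) else counts$n / n

  covered <- function(cat) {
    keep <- classified$category == cat
    if (coverage_mode == "edge_only") {
      keep <- keep & classified$matched_kind %in% c("edge", "reversed_edge")
    }
    unique(unlist(classified$matched_edge_ids[keep]))
  }
  corro_edges <- covered("corroboration")
  contra_edges <- covered("contradiction")
  ne <- g$n_edges
  coverage <- tibble(
    metric = c("corroborated", "contradicted"),
    n_edges = c(length(corro_edges), length(contra_edges)),
    pct_of_baseline = round(
      100 * c(length(corro_edges), length(contra_edges)) / max(ne, 1L), 1)
  )

  structure(
    list(counts = counts, n_total = n, coverage = coverage,
         coverage_mode = coverage_mode, n_baseline_edges = ne),
    class = "reconciliation_summary"
  )
}

#' @export
print.reconciliation_summary <- function(x, ...) {
  cat("<reconciliation_summary> ", x$n_total, " interactions\n", sep = "")
  cat_counts <- x$counts |>
    group_by(.data$category) |>
    summarise(n = sum(.data$n), .groups = "drop")
  for (i in seq_len(nrow(cat_counts))) {
    cat(sprintf("  %-14s %6d (%.1f%%)\n", cat_counts$category[i],
                cat_counts$n[i], 100 * cat_counts$n[i] / max(x$n_total, 1)))
  }
  cat(sprintf("  baseline coverage: %.1f%% corroborated, %.1f%% contradicted (of %d edges)\n",
              x$coverage$pct_of_baseline[1], x$coverage$pct_of_baseline[2],
              x$n_baseline_edges))
  invisible(x)
}

#' Tidy a reconciliation summary into a per-subcategory tibble
#'
#' @param x A `reconciliation_summary`.
#' @param ... Unused.
#' @return Tibble with category, subcategory, n, fraction.
#' @export
tidy.reconciliation_summary <- function(x, ...) {
  x$counts
}

#' One-row overview of a reconciliation summary
#'
#' @param x A `reconciliation_summary`.
#' @param ... Unused.
#' @return One-row tibble: totals per category plus baseline-coverage
#'   percentages.
#' @export
glance.reconciliation_summary <- function(x, ...) {
  per_cat <- setNames(rep(0L, length(CATEGORY_LEVELS)), CATEGORY_LEVELS)
  agg <- x$counts |>
    group_by(.data$category) |>
    summarise(n = sum(.data$n), .groups = "drop")
  per_cat[agg$category] <- agg$n
  tibble(
    n_total = x$n_total,
    n_corroboration = per_cat[["corroboration"]],
    n_contradiction = per_cat[["contradiction"]],
    n_flagged = per_cat[["flagged"]],
    n_extension = per_cat[["extension"]],
    pct_baseline_corroborated = x$coverage$pct_of_baseline[1],
    pct_baseline_contradicted = x$coverage$pct_of_baseline[2]
  )
}

#' Write a reconciliation summary as a delimited table
#'
#' @param x A `reconciliation_summary`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  counts <- x$counts
  counts$metric <- "count"
  cov <- tibble(category = "baseline_coverage",
                subcategory = x$coverage$metric,
                n = x$coverage$n_edges,
                fraction = x$coverage$pct_of_baseline / 100,
                metric = "coverage")
  readr::write_tsv(dplyr::bind_rows(counts, cov), path, progress = FALSE)
  invisible(path)
}
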