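# The reconciliation decision tree: assign each new interaction a category
# (corroboration / contradiction / flagged / extension) and subcategory
# relative to the baseline graph, under a classification scheme (CS1-CS3)
# and an attribute-inclusion strategy (CA0-CA4 or custom).
#
# Decision order (most specific match first):
#   (1) node membership  -> full / hanging extensions
#   (2) forward baseline edge (best parallel edge)
#   (3) reversed baseline edge (direction semantics differ by scheme)
#   (4) forward, else reversed, shortest baseline path (>= 2 edges)
#   (5) no connection -> internal extension (CS2 may flag direct rows)
# Self-loop interactions skip steps (3)-(5).

#' Reconciliation configuration
#'
#' @param scheme Classification scheme. `"CS1"` (default): a reversed edge
#'   with no further mismatch is flagged, one with additional mismatches is
#'   a contradiction; indirect interactions mismatching a baseline path are
#'   flagged; direct interactions aligning only with a path are extensions.
#'   `"CS2"`: like CS1 for reversed edges, but path-level mismatches become
#'   contradictions and path-aligned (or unconnected, see
#'   `direct_flag_mode`) direct interactions are flagged. `"CS3"`: inverts
#'   the reversed-edge rule (direction-only mismatch is a contradiction,
#'   direction plus further mismatches is flagged); otherwise follows CS1.
#' @param strategy An [attribute_strategy()]; default CA1 (compartment
#'   only).
#' @param max_path_len,max_paths Path-search limits (hops / enumerated
#'   paths), see [baseline_paths()].
#' @param sign_mode Path sign semantics, `"parity"` (net sign, default) or
#'   `"strict"` (every edge must carry the new sign); see
#'   [match_against_path()].
#' @param direct_flag_mode Governs CS2's flagging of direct interactions
#'   between connected-but-unlinked baseline nodes: `"always"` (default)
#'   flags them with or without a connecting path; `"path_only"` flags only
#'   when a path exists.
#' @return A `reconciler_config` object.
#' @export
reconciler_config <- function(scheme = c("CS1", "CS2", "CS3"),
                              strategy = attribute_strategy("CA1"),
                              max_path_len = 6L,
                              max_paths = 10L,
                              sign_mode = c("parity", "strict"),
                              direct_flag_mode = c("always", "path_only")) {
  scheme <- match.arg(scheme)
  sign_mode <- match.arg(sign_mode)
  direct_flag_mode <- match.arg(direct_flag_mode)
  stopifnot(inherits(strategy, "attribute_strategy"),
            max_path_len >= 2, max_paths >= 1)
  structure(
    list(scheme = scheme, strategy = strategy,
         max_path_len = as.integer(max_path_len),
         max_paths = as.integer(max_paths),
         sign_mode = sign_mode, direct_flag_mode = direct_flag_mode),
    class = "reconciler_config"
  )
}

#' @export
print.reconciler_config <- function(x, ...) {
  cat("<reconciler_config> scheme ", x$scheme, ", strategy ",
      x$strategy$name, " {", paste(x$strategy$included, collapse = ", "),
      "}, paths <= ", x$max_path_len, " hops (max ", x$max_paths,
      "), sign_mode ", x$sign_mode, "\n", sep = "")
  invisible(x)
}

mismatch_label <- function(m) {
  parts <- c(if (m$sign) "sign", if (m$direction) "direction",
             if (m$connection) "connection", m$attrs)
  if (length(parts) == 0) "" else paste(parts, collapse = "+")
}

short_key <- function(key) sub("\\|\\|.*$", "", key)

edge_desc <- function(g, id, reversed = FALSE) {
  e <- g$edges[id, ]
  paste0("edge#", id, " ", short_key(e$src_key), " -> ", short_key(e$tgt_key),
         " (", e$sign, ", ", e$connection, ")",
         if (reversed) " [reversed]" else "")
}

path_desc <- function(path, reversed = FALSE) {
  paste0("path ", paste(short_key(path$keys), collapse = " -> "),
         " (net ", path$net_sign, ")", if (reversed) " [reversed]" else "")
}

# Best-matching parallel edge: minimal mismatch burden with sign counted
# heaviest, ties broken by baseline input order.
best_parallel_edge <- function(new, edges, strategy, reversed = FALSE) {
  scores <- numeric(nrow(edges))
  sets <- vector("list", nrow(edges))
  for (j in seq_len(nrow(edges))) {
    m <- attribute_mismatches(new, edges[j, ], strategy, reversed = reversed)
    sets[[j]] <- m
    scores[j] <- 1000 * m$sign + length(m$attrs)
  }
  j <- which.min(scores)
  list(edge_id = edges$edge_id[j], mismatch = sets[[j]], row = edges[j, ])
}

# Corroboration subtype for a mismatch-free forward edge match: compare the
# fill pattern of the included attributes (compartment is endpoint-wise).
corroboration_subtype <- function(new, base, strategy) {
  slots <- list()
  for (a in strategy$included) {
    if (a == "compartment") {
      slots[["compartment.src"]] <- c(new$src_compartment, base$src_compartment)
      slots[["compartment.tgt"]] <- c(new$tgt_compartment, base$tgt_compartment)
    } else {
      slots[[a]] <- c(new[[a]], base[[a]])
    }
  }
  if (length(slots) == 0) {
    return("strong")
  }
  new_filled <- vapply(slots, function(s) !is_blank(s[1]), logical(1))
  base_filled <- vapply(slots, function(s) !is_blank(s[2]), logical(1))
  if (all(new_filled & base_filled)) {
    "strong"
  } else if (any(new_filled & !base_filled) && !any(base_filled & !new_filled)) {
    "specification"
  } else {
    "weak_missing"
  }
}

# Classify one interaction (as a plain named list of scalar fields).
classify_row <- function(new, g, cfg) {
  res <- list(category = NA_character_, subcategory = NA_character_,
              matched_kind = "none", matched_desc = "",
              mismatch = empty_mismatch(), edge_ids = integer(),
              path_keys = character())
  scheme <- cfg$scheme
  s_in <- has_node(g, new$src_key)
  t_in <- has_node(g, new$tgt_key)

  # (1) node membership
  if (!s_in && !t_in) {
    res$category <- "extension"; res$subcategory <- "full"
    return(res)
  }
  if (xor(s_in, t_in)) {
    res$category <- "extension"; res$subcategory <- "hanging"
    return(res)
  }

  self_loop <- new$src_key == new$tgt_key

  # (2) forward edge
  fwd <- find_edges(g, new$src_key, new$tgt_key)
  if (nrow(fwd) > 0) {
    best <- best_parallel_edge(new, fwd, cfg$strategy)
    m <- best$mismatch
    res$matched_kind <- "edge"
    res$matched_desc <- edge_desc(g, best$edge_id)
    res$mismatch <- m
    res$edge_ids <- best$edge_id
    if (m$sign) {
      res$category <- "contradiction"; res$subcategory <- "sign"
    } else if (length(m$attrs) > 0) {
      res$category <- "contradiction"; res$subcategory <- "attribute"
    } else if (m$connection) {
      res$category <- "corroboration"; res$subcategory <- "indirect"
    } else {
      res$category <- "corroboration"
      res$subcategory <- corroboration_subtype(new, best$row, cfg$strategy)
    }
    return(res)
  }

  if (self_loop) {
    # node present, no self-edge; reversed/path queries are meaningless
    res$category <- "extension"; res$subcategory <- "internal"
    return(res)
  }

  # (3) reversed edge
  rev <- find_edges(g, new$tgt_key, new$src_key)
  if (nrow(rev) > 0) {
    best <- best_parallel_edge(new, rev, cfg$strategy, reversed = TRUE)
    m <- best$mismatch
    m$direction <- TRUE
    extra <- m$sign || length(m$attrs) > 0
    res$matched_kind <- "reversed_edge"
    res$matched_desc <- edge_desc(g, best$edge_id, reversed = TRUE)
    res$mismatch <- m
    res$edge_ids <- best$edge_id
    if (scheme %in% c("CS1", "CS2")) {
      if (extra) {
        res$category <- "contradiction"; res$subcategory <- "direction"
      } else {
        res$category <- "flagged"; res$subcategory <- "direction"
      }
    } else { # CS3 inverts the reversed-edge rule
      if (extra) {
        res$category <- "flagged"; res$subcategory <- "direction"
      } else {
        res$category <- "contradiction"; res$subcategory <- "direction"
      }
    }
    return(res)
  }

  # (4) path: forward first, reversed as fallback
  key_seqs <- shortest_key_paths(g, new$src_key, new$tgt_key,
                                 cfg$max_path_len, cfg$max_paths)
  reversed <- FALSE
  if (length(key_seqs) == 0) {
    key_seqs <- shortest_key_paths(g, new$tgt_key, new$src_key,
                                   cfg$max_path_len, cfg$max_paths)
    reversed <- TRUE
  }
  if (length(key_seqs) > 0) {
    paths <- lapply(key_seqs, function(k) path_from_keys(g, k))
    if (new$connection == "direct") {
      # a direct claim aligning only with a multi-edge path
      res$matched_kind <- if (reversed) "reversed_path" else "path"
      res$matched_desc <- path_desc(paths[[1L]], reversed)
      res$edge_ids <- paths[[1L]]$edge_ids
      res$path_keys <- paths[[1L]]$keys
      if (scheme == "CS2") {
        res$category <- "flagged"; res$subcategory <- "direct_no_edge"
      } else {
        res$category <- "extension"; res$subcategory <- "internal"
      }
      return(res)
    }
    sets <- lapply(paths, function(p) {
      match_against_path(new, p, g, cfg$strategy, cfg$sign_mode,
                         reversed = reversed)
    })
    clean <- which(vapply(sets, mismatch_is_empty, logical(1)))
    if (!reversed && length(clean) > 0) {
      j <- clean[1L]
      res$category <- "corroboration"; res$subcategory <- "path"
      res$matched_kind <- "path"
      res$matched_desc <- path_desc(paths[[j]])
      res$mismatch <- sets[[j]]
      res$edge_ids <- paths[[j]]$edge_ids
      res$path_keys <- paths[[j]]$keys
      return(res)
    }
    burden <- vapply(sets, function(m) {
      1000 * m$sign + 100 * m$direction + length(m$attrs)
    }, numeric(1))
    j <- which.min(burden)
    res$matched_kind <- if (reversed) "reversed_path" else "path"
    res$matched_desc <- path_desc(paths[[j]], reversed)
    res$mismatch <- sets[[j]]
    res$edge_ids <- paths[[j]]$edge_ids
    res$path_keys <- paths[[j]]$keys
    if (scheme == "CS2") {
      res$category <- "contradiction"; res$subcategory <- "path"
    } else {
      res$category <- "flagged"; res$subcategory <- "path_mismatch"
    }
    return(res)
  }

  # (5) both endpoints known, no edge, no path either way
  if (new$connection == "direct" && scheme == "CS2" &&
      cfg$direct_flag_mode == "always") {
    res$category <- "flagged"; res$subcategory <- "direct_no_edge"
  } else {
    res$category <- "extension"; res$subcategory <- "internal"
  }
  res
}

#' Classify one interaction against the baseline graph
#'
#' @param new One-row canonical interaction tibble.
#' @param g A [build_graph()] result.
#' @param cfg A [reconciler_config()].
#' @return One-row classified tibble; see [classify_interactions()].
#' @export
classify_interaction <- function(new, g, cfg = reconciler_config()) {
  classify_interactions(new, g, cfg)
}

#' Classify an interaction list against the baseline graph
#'
#' Applies the reconciliation decision tree to every row, independently and
#' in input order. Every row receives exactly one category and one
#' subcategory. Categories: `corroboration` (subtypes `strong`,
#' `specification`, `weak_missing`, `indirect`, `path`), `contradiction`
#' (`sign`, `attribute`, `direction`, `path`), `flagged` (`direction`,
#' `path_mismatch`, `direct_no_edge`), `extension` (`full`, `hanging`,
#' `internal`).
#'
#' @param tbl Canonical interaction tibble (the new list).
#' @param g A [build_graph()] result (the baseline).
#' @param cfg A [reconciler_config()].
#' @return The input tibble plus columns `category`, `subcategory`,
#'   `matched_kind` (`edge`, `reversed_edge`, `path`, `reversed_path`,
#'   `none`), `matched_desc`, `mismatch_desc`, and the list columns
#'   `matched_edge_ids` (baseline edge ids backing the match; all path
#'   edges for path matches) and `mismatches` (the full mismatch set).
#'   Carries the config in the `"config"` attribute; class
#'   `reconciled_tbl`.
#' @export
#' @examples
#' base <- build_interaction_tbl(data.frame(
#'   Regulator = "LKB1", Target = "AMPK", Sign = "positive",
#'   `Connection Type` = "direct", check.names = FALSE), role = "baseline")
#' g <- build_graph(base)
#' newlist <- build_interaction_tbl(data.frame(
#'   Regulator = "LKB1", Target = "AMPK", Sign = "positive",
#'   `Connection Type` = "direct", check.names = FALSE))
#' classify_interactions(newlist, g)[, c("category", "subcategory")]
classify_interactions <- function(tbl, g, cfg = reconciler_config()) {
  n <- nrow(tbl)
  category <- character(n)
  subcategory <- character(n)
  matched_kind <- character(n)
  matched_desc <- character(n)
  mismatch_desc <- character(n)
  matched_edge_ids <- vector("list", n)
  mismatches <- vector("list", n)

  rows <- split_rows(tbl)
  for (i in seq_len(n)) {
    r <- classify_row(rows[[i]], g, cfg)
    category[i] <- r$category
    subcategory[i] <- r$subcategory
    matched_kind[i] <- r$matched_kind
    matched_desc[i] <- r$matched_desc
    mismatch_desc[i] <- mismatch_label(r$mismatch)
    matched_edge_ids[[i]] <- r$edge_ids
    mismatches[[i]] <- r$mismatch
  }

  out <- tbl
  out$category <- category
  out$subcategory <- subcategory
  out$matched_kind <- matched_kind
  out$matched_desc <- matched_desc
  out$mismatch_desc <- mismatch_desc
  out$matched_edge_ids <- matched_edge_ids
  out$mismatches <- mismatches
  attr(out, "config") <- cfg
  class(out) <- c("reconciled_tbl", class(tbl))
  out
}

# Fast row iterator: one named list of scalars per row.
split_rows <- function(tbl) {
  cols <- as.list(tbl)
  n <- nrow(tbl)
  lapply(seq_len(n), function(i) lapply(cols, `[[`, i))
}
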