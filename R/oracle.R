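# Independent brute-force reference classifier.
#
# Same contract as classify_interactions(), implemented from scratch on
# the raw baseline table: edges are found by scanning every row, paths by
# recursive enumeration of ALL simple paths, and mismatch rules are
# re-coded with plain loops. No graph index, no igraph, and no helper from
# the main classification path is used, so agreement between the two
# routes is a meaningful cross-check. Intended for small graphs only.

bf_blank <- function(x) {
  is.na(x) || x == "" || x == "nan" || x == "na" || x == "none" || x == "null"
}

bf_conflict <- function(a, b) !bf_blank(a) && !bf_blank(b) && a != b

bf_context_conflict <- function(a, b) {
  pm <- function(x) {
    if (bf_blank(x)) return(character())
    out <- character()
    for (part in strsplit(x, ";", fixed = TRUE)[[1]]) {
      kv <- strsplit(part, ":", fixed = TRUE)[[1]]
      if (length(kv) >= 2) {
        k <- trimws(kv[1])
        v <- trimws(paste(kv[-1], collapse = ":"))
        if (nzchar(k) && nzchar(v)) out[k] <- v
      }
    }
    out
  }
  ma <- pm(a)
  mb <- pm(b)
  for (k in names(ma)) {
    if (k %in% names(mb) && ma[[k]] != mb[[k]]) return(TRUE)
  }
  FALSE
}

# attribute mismatch names between a new row and one baseline row
bf_attr_names <- function(new, base, included, reversed) {
  out <- character()
  for (a in included) {
    hit <- FALSE
    if (a == "compartment") {
      if (reversed) {
        hit <- bf_conflict(new$src_compartment, base$tgt_compartment) ||
          bf_conflict(new$tgt_compartment, base$src_compartment)
      } else {
        hit <- bf_conflict(new$src_compartment, base$src_compartment) ||
          bf_conflict(new$tgt_compartment, base$tgt_compartment)
      }
    } else if (a == "context_other") {
      hit <- bf_context_conflict(new$context_other, base$context_other)
    } else {
      hit <- bf_conflict(new[[a]], base[[a]])
    }
    if (hit) out <- c(out, a)
  }
  out
}

# All simple paths src -> tgt with 2..max_len edges, as node-key
# sequences, by exhaustive depth-first enumeration. A path is a node
# sequence: parallel edges do not multiply paths; the representative edge
# of a hop is the lowest-numbered baseline row (bf_rep_rows).
bf_all_paths <- function(edges, src, tgt, max_len) {
  res <- list()
  recurse <- function(node, visited) {
    hops <- length(visited) - 1L
    if (node == tgt && hops >= 2L) {
      res[[length(res) + 1L]] <<- visited
      return()
    }
    if (hops >= max_len || (node == tgt && hops > 0L)) return()
    succ <- unique(edges$tgt_key[edges$src_key == node])
    for (nxt in succ) {
      if (!(nxt %in% visited)) recurse(nxt, c(visited, nxt))
    }
  }
  recurse(src, src)
  res
}

# representative baseline row per hop of a node-key sequence
bf_rep_rows <- function(edges, keys) {
  vapply(seq_len(length(keys) - 1L), function(i) {
    min(which(edges$src_key == keys[i] & edges$tgt_key == keys[i + 1L]))
  }, integer(1))
}

#' Brute-force reference classification
#'
#' Classifies new interactions against a (small) baseline interaction
#' table by exhaustive enumeration, sharing no code with
#' [classify_interactions()]. Used as the independent oracle in the test
#' suite. Refuses baselines with more than `max_nodes` nodes, since path
#' enumeration is exhaustive.
#'
#' @param tbl Canonical interaction tibble (new list).
#' @param baseline Canonical interaction tibble (baseline rows, not a
#'   graph object).
#' @param cfg A [reconciler_config()].
#' @param max_nodes Refusal threshold (default 12).
#' @return Tibble with `category` and `subcategory`, one row per input.
#' @export
brute_force_classify <- function(tbl, baseline, cfg = reconciler_config(),
                                 max_nodes = 12L) {
  node_keys <- unique(c(baseline$src_key, baseline$tgt_key))
  if (length(node_keys) > max_nodes) {
    abort(paste0("brute-force oracle refuses baselines with > ", max_nodes,
                 " nodes (got ", length(node_keys), ")"),
          class = "netreconcile_contract_error")
  }
  included <- cfg$strategy$included
  scheme <- cfg$scheme
  n <- nrow(tbl)
  category <- character(n)
  subcategory <- character(n)

  for (i in seq_len(n)) {
    new <- lapply(as.list(tbl), `[[`, i)
    s <- new$src_key
    t <- new$tgt_key
    s_in <- s %in% node_keys
    t_in <- t %in% node_keys

    if (!s_in && !t_in) {
      category[i] <- "extension"; subcategory[i] <- "full"; next
    }
    if (s_in != t_in) {
      category[i] <- "extension"; subcategory[i] <- "hanging"; next
    }

    # forward edges by linear scan
    fwd <- which(baseline$src_key == s & baseline$tgt_key == t)
    if (length(fwd) > 0) {
      best <- NULL
      best_score <- Inf
      for (j in fwd) {
        base <- lapply(as.list(baseline), `[[`, j)
        attrs <- bf_attr_names(new, base, included, reversed = FALSE)
        sc <- 1000 * (new$sign != base$sign) + length(attrs)
        if (sc < best_score) {
          best_score <- sc
          best <- list(base = base, attrs = attrs)
        }
      }
      base <- best$base
      if (new$sign != base$sign) {
        category[i] <- "contradiction"; subcategory[i] <- "sign"
      } else if (length(best$attrs) > 0) {
        category[i] <- "contradiction"; subcategory[i] <- "attribute"
      } else if (new$connection != base$connection) {
        category[i] <- "corroboration"; subcategory[i] <- "indirect"
      } else {
        # fill-pattern comparison over included attribute slots
        nf <- logical(0)
        bf <- logical(0)
        for (a in included) {
          if (a == "compartment") {
            nf <- c(nf, !bf_blank(new$src_compartment),
                    !bf_blank(new$tgt_compartment))
            bf <- c(bf, !bf_blank(base$src_compartment),
                    !bf_blank(base$tgt_compartment))
          } else {
            nf <- c(nf, !bf_blank(new[[a]]))
            bf <- c(bf, !bf_blank(base[[a]]))
          }
        }
        if (length(nf) == 0 || all(nf & bf)) {
          subcategory[i] <- "strong"
        } else if (any(nf & !bf) && !any(bf & !nf)) {
          subcategory[i] <- "specification"
        } else {
          subcategory[i] <- "weak_missing"
        }
        category[i] <- "corroboration"
      }
      next
    }

    if (s == t) { # self-loop without a self-edge
      category[i] <- "extension"; subcategory[i] <- "internal"; next
    }

    # reversed edges
    rev <- which(baseline$src_key == t & baseline$tgt_key == s)
    if (length(rev) > 0) {
      best_attrs <- NULL
      best_sign <- NA
      best_score <- Inf
      for (j in rev) {
        base <- lapply(as.list(baseline), `[[`, j)
        attrs <- bf_attr_names(new, base, included, reversed = TRUE)
        sc <- 1000 * (new$sign != base$sign) + length(attrs)
        if (sc < best_score) {
          best_score <- sc
          best_attrs <- attrs
          best_sign <- new$sign != base$sign
        }
      }
      extra <- best_sign || length(best_attrs) > 0
      flag_first <- scheme %in% c("CS1", "CS2")
      if ((extra && !flag_first) || (!extra && flag_first)) {
        category[i] <- "flagged"; subcategory[i] <- "direction"
      } else {
        category[i] <- "contradiction"; subcategory[i] <- "direction"
      }
      next
    }

    # paths: exhaustive enumeration, minimum length only, forward first
    pick_min <- function(paths) {
      if (length(paths) == 0) return(list())
      lens <- vapply(paths, length, integer(1)) - 1L
      paths <- paths[lens == min(lens)]
      keyseq <- vapply(paths, paste, character(1), collapse = " -> ")
      paths[order(keyseq)][seq_len(min(length(paths), cfg$max_paths))]
    }
    paths <- pick_min(bf_all_paths(baseline, s, t, cfg$max_path_len))
    reversed <- FALSE
    if (length(paths) == 0) {
      paths <- pick_min(bf_all_paths(baseline, t, s, cfg$max_path_len))
      reversed <- TRUE
    }

    if (length(paths) > 0) {
      if (new$connection == "direct") {
        if (scheme == "CS2") {
          category[i] <- "flagged"; subcategory[i] <- "direct_no_edge"
        } else {
          category[i] <- "extension"; subcategory[i] <- "internal"
        }
        next
      }
      any_clean <- FALSE
      if (!reversed) {
        for (keys in paths) {
          rows <- bf_rep_rows(baseline, keys)
          signs <- baseline$sign[rows]
          sign_bad <- if (cfg$sign_mode == "parity") {
            (sum(signs == "negative") %% 2 == 0) != (new$sign == "positive")
          } else {
            any(signs != new$sign)
          }
          attrs <- character()
          for (a in setdiff(included, "compartment")) {
            for (j in rows) {
              base <- lapply(as.list(baseline), `[[`, j)
              hit <- if (a == "context_other") {
                bf_context_conflict(new$context_other, base$context_other)
              } else {
                bf_conflict(new[[a]], base[[a]])
              }
              if (hit) { attrs <- c(attrs, a); break }
            }
          }
          if ("compartment" %in% included) {
            first <- lapply(as.list(baseline), `[[`, rows[1])
            last <- lapply(as.list(baseline), `[[`, rows[length(rows)])
            if (bf_conflict(new$src_compartment, first$src_compartment) ||
                bf_conflict(new$tgt_compartment, last$tgt_compartment)) {
              attrs <- c(attrs, "compartment")
            }
          }
          if (!sign_bad && length(attrs) == 0) { any_clean <- TRUE; break }
        }
      }
      if (any_clean) {
        category[i] <- "corroboration"; subcategory[i] <- "path"
      } else if (scheme == "CS2") {
        category[i] <- "contradiction"; subcategory[i] <- "path"
      } else {
        category[i] <- "flagged"; subcategory[i] <- "path_mismatch"
      }
      next
    }

    # nothing connects the two known endpoints
    if (new$connection == "direct" && scheme == "CS2" &&
        cfg$direct_flag_mode == "always") {
      category[i] <- "flagged"; subcategory[i] <- "direct_no_edge"
    } else {
      category[i] <- "extension"; subcategory[i] <- "internal"
    }
  }

  tibble(category = category, subcategory = subcategory)
}
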