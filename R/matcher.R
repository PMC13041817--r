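# Formal match conditions: element match, attribute-mismatch detection
# under an attribute-inclusion strategy, and path-level matching.

# Non-essential attributes eligible for comparison. Provenance fields
# (paper ids, evidence, reader score) are never compared.
NONESSENTIAL_ATTRS <- c("compartment", "mechanism", "cell_line",
                        "cell_type", "tissue", "organism", "context_other")
PROVENANCE_FIELDS <- c("paper_ids", "evidence", "score")

#' Attribute-inclusion strategy
#'
#' Selects which non-essential attributes participate in mismatch
#' detection. The named strategies are nested: `CA0` compares none, `CA1`
#' adds compartment, `CA2` adds mechanism, `CA3` adds cell line, and `CA4`
#' adds the remaining contextual attributes (cell type, tissue, organism,
#' and the free-form context map). `custom` takes an explicit subset.
#' Provenance fields can never be included.
#'
#' @param name One of `"CA0"`..`"CA4"` or `"custom"`.
#' @param included For `"custom"`: character vector drawn from
#'   `c("compartment", "mechanism", "cell_line", "cell_type", "tissue",
#'   "organism", "context_other")`.
#' @return An `attribute_strategy` object (list with `name`, `included`).
#' @export
#' @examples
#' attribute_strategy("CA2")
#' attribute_strategy("custom", c("mechanism", "organism"))
attribute_strategy <- function(name = c("CA1", "CA0", "CA2", "CA3", "CA4",
                                        "custom"),
                               included = NULL) {
  name <- match.arg(name)
  sets <- list(
    CA0 = character(),
    CA1 = "compartment",
    CA2 = c("compartment", "mechanism"),
    CA3 = c("compartment", "mechanism", "cell_line"),
    CA4 = NONESSENTIAL_ATTRS
  )
  if (name == "custom") {
    included <- unique(as.character(included %||% character()))
    bad <- setdiff(included, NONESSENTIAL_ATTRS)
    if (length(bad) > 0) {
      abort(paste0("unknown or non-comparable attribute(s) in custom strategy: ",
                   paste(bad, collapse = ", "),
                   " (provenance fields are never comparable)"),
            class = "netreconcile_config_error")
    }
  } else {
    included <- sets[[name]]
  }
  structure(list(name = name, included = included),
            class = "attribute_strategy")
}

#' @export
print.attribute_strategy <- function(x, ...) {
  cat("<attribute_strategy> ", x$name, ": {",
      paste(x$included, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Element match condition
#'
#' Two elements match iff their normalized identifiers are equal and their
#' element types are equal. This is the identity notion used for baseline
#' node keys, so it reduces to key equality.
#'
#' @param a,b Elements: lists (or one-row data frames) with `identifier`
#'   and `type` fields.
#' @return Logical scalar.
#' @export
#' @examples
#' element_match(list(identifier = "AMPK", type = "protein"),
#'               list(identifier = "ampk ", type = "protein"))
element_match <- function(a, b) {
  element_key(a$identifier, a$type) == element_key(b$identifier, b$type)
}

# Empty mismatch set.
empty_mismatch <- function() {
  list(sign = FALSE, direction = FALSE, connection = FALSE,
       attrs = character())
}

mismatch_is_empty <- function(m) {
  !m$sign && !m$direction && !m$connection && length(m$attrs) == 0
}

# Two attribute values conflict only when both are non-empty and unequal;
# a pair with >= 1 empty side never counts as a mismatch.
attr_conflict <- function(a, b) {
  !is_blank(a) && !is_blank(b) && a != b
}

# Context maps compare key-by-key; keys present on only one side are
# ignored (the empty-exclusion rule generalized to map entries).
context_conflict <- function(a, b) {
  ma <- parse_context_map(a)
  mb <- parse_context_map(b)
  shared <- intersect(names(ma), names(mb))
  any(ma[shared] != mb[shared])
}

#' Attribute mismatches between a new and a baseline interaction
#'
#' Applies the mismatch rules under an attribute-inclusion strategy:
#' a sign mismatch when the interaction signs differ; an included attribute
#' mismatches when both sides are non-empty and unequal (an empty side never
#' mismatches); `connection` records a direct/indirect disagreement (not an
#' attribute conflict). Compartments are compared per matched endpoint —
#' source-vs-source and target-vs-target, or crosswise when `reversed =
#' TRUE` pairs a reversed baseline edge. Provenance fields are never
#' inspected.
#'
#' @param new,base One-row canonical interaction tibbles (or equivalent
#'   lists).
#' @param strategy An [attribute_strategy()].
#' @param reversed Pair the baseline edge target-to-source (used when the
#'   caller matched a reversed edge).
#' @return Mismatch set: list with `sign`, `direction` (always `FALSE`
#'   here; set by the caller), `connection` (logical), `attrs` (character
#'   vector of mismatching attribute names, a subset of the strategy's
#'   included set).
#' @export
attribute_mismatches <- function(new, base, strategy = attribute_strategy("CA1"),
                                 reversed = FALSE) {
  m <- empty_mismatch()
  m$sign <- new$sign != base$sign
  m$connection <- new$connection != base$connection
  attrs <- character()
  for (a in strategy$included) {
    hit <- switch(
      a,
      compartment = {
        if (reversed) {
          attr_conflict(new$src_compartment, base$tgt_compartment) ||
            attr_conflict(new$tgt_compartment, base$src_compartment)
        } else {
          attr_conflict(new$src_compartment, base$src_compartment) ||
            attr_conflict(new$tgt_compartment, base$tgt_compartment)
        }
      },
      context_other = context_conflict(new$context_other, base$context_other),
      attr_conflict(new[[a]], base[[a]])
    )
    if (isTRUE(hit)) attrs <- c(attrs, a)
  }
  m$attrs <- attrs
  m
}

#' Match a new interaction against a baseline path
#'
#' Compares an interaction with a multi-edge baseline path. The sign check
#' depends on `sign_mode`: `"parity"` (default) compares the new sign with
#' the path's net sign (parity of negative edges); `"strict"` requires
#' every path edge to carry the new interaction's sign. Attribute
#' mismatches are the union over path edges of non-empty conflicting
#' included attributes; compartments are compared at the path's endpoints
#' (crosswise when the path is reversed). `direction` is set when the path
#' runs target-to-source.
#'
#' @param new One-row canonical interaction tibble.
#' @param path A `baseline_path` (see [baseline_paths()]).
#' @param g The `baseline_graph` the path came from.
#' @param strategy An [attribute_strategy()].
#' @param sign_mode `"parity"` or `"strict"`.
#' @param reversed Whether the path runs target-to-source.
#' @return Mismatch set as in [attribute_mismatches()].
#' @export
match_against_path <- function(new, path, g,
                               strategy = attribute_strategy("CA1"),
                               sign_mode = c("parity", "strict"),
                               reversed = FALSE) {
  sign_mode <- match.arg(sign_mode)
  m <- empty_mismatch()
  m$direction <- reversed
  m$sign <- if (sign_mode == "parity") {
    new$sign != path$net_sign
  } else {
    any(path$signs != new$sign)
  }
  edges <- g$edges[path$edge_ids, , drop = FALSE]
  attrs <- character()
  for (a in setdiff(strategy$included, "compartment")) {
    for (i in seq_len(nrow(edges))) {
      hit <- if (a == "context_other") {
        context_conflict(new$context_other, edges$context_other[i])
      } else {
        attr_conflict(new[[a]], edges[[a]][i])
      }
      if (isTRUE(hit)) {
        attrs <- c(attrs, a)
        break
      }
    }
  }
  if ("compartment" %in% strategy$included) {
    first <- edges[1L, ]
    last <- edges[nrow(edges), ]
    hit <- if (reversed) {
      attr_conflict(new$src_compartment, last$tgt_compartment) ||
        attr_conflict(new$tgt_compartment, first$src_compartment)
    } else {
      attr_conflict(new$src_compartment, first$src_compartment) ||
        attr_conflict(new$tgt_compartment, last$tgt_compartment)
    }
    if (isTRUE(hit)) attrs <- c(attrs, "compartment")
  }
  m$attrs <- intersect(strategy$included, unique(attrs))
  m
}
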