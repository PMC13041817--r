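# Synthetic fixture generator: baseline graphs and new-interaction lists
# with planted, ground-truth classifications for every decision-tree leaf.
#
# The baseline is assembled from dedicated per-plant motifs (so plants
# cannot interfere with one another) plus a disjoint random
# Erdos-Renyi-style background component that supplies realistic bulk.
# Truth labels are derived from a hand-coded per-leaf lookup, conditional
# on scheme and on whether the planted attribute is compared under the
# chosen strategy - independent of the classifier implementation.

FIXTURE_LEAVES <- c(
  "strong", "specification", "weak_missing", "indirect",
  "sign", "attribute", "direction", "direction_attr",
  "path_corroboration", "path_mismatch", "direct_path",
  "internal_indirect", "internal_direct", "hanging", "full"
)

#' Specification for a synthetic reconciliation fixture
#'
#' @param seed Integer RNG seed; identical spec + seed give an identical
#'   fixture.
#' @param counts Named list of planted-interaction counts, one knob per
#'   decision-tree leaf (see `FIXTURE_LEAVES` in the package source):
#'   `strong`, `specification`, `weak_missing`, `indirect` (corroboration
#'   leaves); `sign`, `attribute`, `direction`, `direction_attr`
#'   (edge-level contradiction / direction leaves); `path_corroboration`,
#'   `path_mismatch`, `direct_path` (path leaves); `internal_indirect`,
#'   `internal_direct`, `hanging`, `full` (extension leaves). Unnamed
#'   leaves default to `default_count`.
#' @param default_count Count used for leaves absent from `counts`.
#' @param n_background_nodes,n_background_edges Size of the random
#'   background component (directed, duplicate pairs allowed - the graph
#'   is a multigraph).
#' @param p_positive Probability that a background edge is positive
#'   (default 0.8, echoing activation-heavy curated networks).
#' @param attribute_fill Probability that each non-essential attribute of a
#'   background edge is populated.
#' @param duplicate_rate Probability that each new-list row is duplicated
#'   (duplicates keep their truth label).
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L,
                         counts = list(),
                         default_count = 2L,
                         n_background_nodes = 20L,
                         n_background_edges = 30L,
                         p_positive = 0.8,
                         attribute_fill = 0.6,
                         duplicate_rate = 0) {
  bad <- setdiff(names(counts), FIXTURE_LEAVES)
  if (length(bad) > 0) {
    abort(paste0("unknown fixture leaf knob(s): ", paste(bad, collapse = ", ")),
          class = "netreconcile_config_error")
  }
  full <- setNames(rep(as.integer(default_count), length(FIXTURE_LEAVES)),
                   FIXTURE_LEAVES)
  for (nm in names(counts)) full[[nm]] <- as.integer(counts[[nm]])
  if (any(full < 0)) {
    abort("planted counts must be >= 0", class = "netreconcile_config_error")
  }
  structure(
    list(seed = as.integer(seed), counts = as.list(full),
         n_background_nodes = as.integer(n_background_nodes),
         n_background_edges = as.integer(n_background_edges),
         p_positive = p_positive, attribute_fill = attribute_fill,
         duplicate_rate = duplicate_rate),
    class = "fixture_spec"
  )
}

fx_vocab <- list(
  compartment = c("cytoplasm", "nucleus", "plasma membrane", "mitochondria"),
  mechanism = c("phosphorylation", "ubiquitination", "binding",
                "transcription"),
  cell_line = c("hela", "mcf7", "a549"),
  cell_type = c("epithelial", "fibroblast"),
  tissue = c("lung", "breast", "liver"),
  organism = c("human", "mouse"),
  context_other = c("stimulus:egf", "stimulus:tnf", "timepoint:24h")
)

# One raw interaction row in dialect headers. Attribute values are already
# normalized-form strings.
fx_row <- function(src, tgt, sign = "positive", connection = "direct",
                   src_comp = "", tgt_comp = "", mechanism = "",
                   cell_line = "", cell_type = "", tissue = "",
                   organism = "", context = "", paper = "pmid:000001") {
  data.frame(
    `Regulator Name` = src, `Regulator Type` = "protein",
    `Regulator Compartment` = src_comp,
    `Regulated Name` = tgt, `Regulated Type` = "protein",
    `Regulated Compartment` = tgt_comp,
    Sign = sign, `Connection Type` = connection, Mechanism = mechanism,
    `Cell Line` = cell_line, `Cell Type` = cell_type,
    `Tissue Type` = tissue, Organism = organism, Context = context,
    `Paper IDs` = paper, Evidence = "synthetic evidence statement",
    Score = "1.0",
    check.names = FALSE
  )
}

# Fully-populated shared attribute block for plants that need identical
# attributes on both sides.
fx_full_attrs <- function() {
  list(src_comp = "cytoplasm", tgt_comp = "nucleus",
       mechanism = "phosphorylation", cell_line = "hela",
       cell_type = "epithelial", tissue = "lung", organism = "human",
       context = "stimulus:egf")
}

# Truth labels per leaf. `attr_on` says whether the planted attribute
# (compartment) is compared under the strategy in force.
fx_truth <- function(leaf, scheme, attr_on) {
  lab <- function(cat, sub) list(category = cat, subcategory = sub)
  switch(
    leaf,
    strong = lab("corroboration", "strong"),
    specification = if (attr_on) lab("corroboration", "specification")
                    else lab("corroboration", "strong"),
    weak_missing = if (attr_on) lab("corroboration", "weak_missing")
                   else lab("corroboration", "strong"),
    indirect = lab("corroboration", "indirect"),
    sign = lab("contradiction", "sign"),
    attribute = if (attr_on) lab("contradiction", "attribute")
                else lab("corroboration", "strong"),
    direction = if (scheme == "CS3") lab("contradiction", "direction")
                else lab("flagged", "direction"),
    direction_attr = if (!attr_on) {
      if (scheme == "CS3") lab("contradiction", "direction")
      else lab("flagged", "direction")
    } else {
      if (scheme == "CS3") lab("flagged", "direction")
      else lab("contradiction", "direction")
    },
    path_corroboration = lab("corroboration", "path"),
    path_mismatch = if (scheme == "CS2") lab("contradiction", "path")
                    else lab("flagged", "path_mismatch"),
    direct_path = if (scheme == "CS2") lab("flagged", "direct_no_edge")
                  else lab("extension", "internal"),
    internal_indirect = lab("extension", "internal"),
    internal_direct = if (scheme == "CS2") lab("flagged", "direct_no_edge")
                      else lab("extension", "internal"),
    hanging = lab("extension", "hanging"),
    full = lab("extension", "full")
  )
}

#' Generate a synthetic reconciliation fixture
#'
#' Builds a baseline interaction table and a new-interaction list by
#' controlled perturbation of planted motifs (exact copies, sign flips,
#' endpoint swaps, attribute edits, two-hop shortcuts, fresh node pairs),
#' together with a truth table giving the expected category and
#' subcategory under each classification scheme for the supplied attribute
#' strategy. The planted-attribute leaves perturb the compartment
#' attribute, so their truth depends on whether `"compartment"` is in the
#' strategy's included set (under CA0 they collapse to corroborations, as
#' recorded in the truth table).
#'
#' @param spec A [fixture_spec()].
#' @param strategy The [attribute_strategy()] the truth table is computed
#'   for (default CA1).
#' @return List with `baseline` and `new` (canonical interaction tibbles)
#'   and `truth` (tibble: `row`, `leaf`, and `category_cs1` /
#'   `subcategory_cs1` .. `_cs3`).
#' @export
#' @examples
#' fx <- generate_fixture(fixture_spec(seed = 7))
#' table(fx$truth$category_cs1)
generate_fixture <- function(spec, strategy = attribute_strategy("CA1")) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  attr_on <- "compartment" %in% strategy$included
  base_rows <- list()
  new_rows <- list()
  leaves <- character()

  plant <- function(leaf, idx) {
    u <- sprintf("%s%02da", leaf, idx)
    v <- sprintf("%s%02db", leaf, idx)
    w <- sprintf("%s%02dc", leaf, idx)
    A <- fx_full_attrs()
    switch(
      leaf,
      strong = list(
        base = do.call(fx_row, c(list(u, v), A)),
        new = do.call(fx_row, c(list(u, v), A))
      ),
      specification = list(
        base = fx_row(u, v),
        new = do.call(fx_row, c(list(u, v), A))
      ),
      weak_missing = list(
        base = do.call(fx_row, c(list(u, v), A)),
        new = fx_row(u, v)
      ),
      indirect = list(
        base = do.call(fx_row, c(list(u, v, connection = "direct"), A)),
        new = do.call(fx_row, c(list(u, v, connection = "indirect"), A))
      ),
      sign = list(
        base = do.call(fx_row, c(list(u, v, sign = "positive"), A)),
        new = do.call(fx_row, c(list(u, v, sign = "negative"), A))
      ),
      attribute = list(
        base = do.call(fx_row, c(list(u, v), A)),
        new = do.call(fx_row, c(list(u, v),
                                modifyList(A, list(src_comp = "mitochondria"))))
      ),
      direction = list(
        base = do.call(fx_row, c(list(v, u), A)),
        new = do.call(fx_row, c(list(u, v),
                                modifyList(A, list(src_comp = A$tgt_comp,
                                                   tgt_comp = A$src_comp))))
      ),
      direction_attr = list(
        base = do.call(fx_row, c(list(v, u), A)),
        # crosswise pairing: new source aligns with baseline target
        new = do.call(fx_row, c(list(u, v),
                                modifyList(A, list(src_comp = "mitochondria",
                                                   tgt_comp = A$src_comp))))
      ),
      path_corroboration = list(
        base = rbind(fx_row(u, w), fx_row(w, v)),
        new = fx_row(u, v, connection = "indirect")
      ),
      path_mismatch = list(
        base = rbind(fx_row(u, w, sign = "negative"), fx_row(w, v)),
        new = fx_row(u, v, connection = "indirect")
      ),
      direct_path = list(
        base = rbind(fx_row(u, w), fx_row(w, v)),
        new = fx_row(u, v, connection = "direct")
      ),
      internal_indirect = list(
        base = rbind(fx_row(u, w), fx_row(v, paste0(w, "2"))),
        new = fx_row(u, v, connection = "indirect")
      ),
      internal_direct = list(
        base = rbind(fx_row(u, w), fx_row(v, paste0(w, "2"))),
        new = fx_row(u, v, connection = "direct")
      ),
      hanging = list(
        base = fx_row(u, w),
        new = fx_row(u, v)
      ),
      full = list(
        base = NULL,
        new = fx_row(u, v)
      )
    )
  }

  for (leaf in FIXTURE_LEAVES) {
    k <- spec$counts[[leaf]]
    for (idx in seq_len(k)) {
      p <- plant(leaf, idx)
      if (!is.null(p$base)) base_rows[[length(base_rows) + 1L]] <- p$base
      new_rows[[length(new_rows) + 1L]] <- p$new
      leaves <- c(leaves, leaf)
    }
  }

  # disjoint random background component
  if (spec$n_background_edges > 0 && spec$n_background_nodes >= 2) {
    bg <- sprintf("bg%03d", seq_len(spec$n_background_nodes))
    for (i in seq_len(spec$n_background_edges)) {
      ends <- sample(bg, 2L)
      vals <- lapply(fx_vocab, function(v) {
        if (runif(1) < spec$attribute_fill) sample(v, 1L) else ""
      })
      base_rows[[length(base_rows) + 1L]] <- fx_row(
        ends[1L], ends[2L],
        sign = if (runif(1) < spec$p_positive) "positive" else "negative",
        connection = sample(c("direct", "indirect"), 1L),
        src_comp = vals$compartment,
        tgt_comp = if (runif(1) < spec$attribute_fill)
          sample(fx_vocab$compartment, 1L) else "",
        mechanism = vals$mechanism, cell_line = vals$cell_line,
        cell_type = vals$cell_type, tissue = vals$tissue,
        organism = vals$organism, context = vals$context_other
      )
    }
  }

  new_raw <- if (length(new_rows) > 0) do.call(rbind, new_rows) else
    fx_row("x", "y")[0, ]
  if (spec$duplicate_rate > 0 && nrow(new_raw) > 0) {
    dup <- which(runif(nrow(new_raw)) < spec$duplicate_rate)
    if (length(dup) > 0) {
      new_raw <- rbind(new_raw, new_raw[dup, , drop = FALSE])
      leaves <- c(leaves, leaves[dup])
    }
  }

  base_raw <- if (length(base_rows) > 0) do.call(rbind, base_rows) else
    fx_row("x", "y")[0, ]

  truth <- tibble(row = seq_along(leaves), leaf = leaves)
  for (scheme in c("CS1", "CS2", "CS3")) {
    labs <- lapply(leaves, fx_truth, scheme = scheme, attr_on = attr_on)
    truth[[paste0("category_", tolower(scheme))]] <-
      map_chr(labs, "category")
    truth[[paste0("subcategory_", tolower(scheme))]] <-
      map_chr(labs, "subcategory")
  }

  list(
    baseline = build_interaction_tbl(base_raw, role = "baseline",
                                     source_label = "fixture_baseline"),
    new = build_interaction_tbl(new_raw, role = "new_list",
                                source_label = "fixture_new"),
    truth = truth
  )
}

#' Write a fixture to disk
#'
#' Writes `baseline.tsv`, `new.tsv` and `truth.tsv` under `out_dir`.
#'
#' @param fx A [generate_fixture()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(fx, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_classified(fx$baseline, file.path(out_dir, "baseline.tsv"))
  write_classified(fx$new, file.path(out_dir, "new.tsv"))
  readr::write_tsv(fx$truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
  invisible(out_dir)
}

#' Random small reconciliation instance
#'
#' Draws a random directed multigraph over a small node pool and a random
#' new-interaction list over an overlapping pool (so membership, edge,
#' reversed-edge, path and no-connection cases all occur), with randomly
#' populated attributes. No truth labels: intended for cross-checking the
#' main classifier against [brute_force_classify()].
#'
#' @param seed Integer RNG seed.
#' @param n_nodes Baseline node-pool size (keep <= 12 for the oracle).
#' @param n_base Number of baseline edges.
#' @param n_new Number of new interactions.
#' @param p_positive Probability of a positive sign.
#' @param attribute_fill Probability each attribute is populated.
#' @return List with `baseline` and `new` canonical interaction tibbles.
#' @export
random_reconciliation_case <- function(seed, n_nodes = 8L, n_base = 12L,
                                       n_new = 10L, p_positive = 0.7,
                                       attribute_fill = 0.5) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  pool <- sprintf("v%02d", seq_len(n_nodes))
  outside <- sprintf("x%02d", 1:3) # occasionally outside the baseline
  rand_row <- function(src, tgt) {
    draw <- function(vals) if (runif(1) < attribute_fill) sample(vals, 1L) else ""
    fx_row(src, tgt,
           sign = if (runif(1) < p_positive) "positive" else "negative",
           connection = sample(c("direct", "indirect"), 1L),
           src_comp = draw(fx_vocab$compartment),
           tgt_comp = draw(fx_vocab$compartment),
           mechanism = draw(fx_vocab$mechanism),
           cell_line = draw(fx_vocab$cell_line),
           cell_type = draw(fx_vocab$cell_type),
           tissue = draw(fx_vocab$tissue),
           organism = draw(fx_vocab$organism),
           context = draw(fx_vocab$context_other))
  }
  base_raw <- do.call(rbind, lapply(seq_len(n_base), function(i) {
    ends <- sample(pool, 2L)
    rand_row(ends[1L], ends[2L])
  }))
  new_raw <- do.call(rbind, lapply(seq_len(n_new), function(i) {
    ends <- sample(c(pool, outside), 2L)
    rand_row(ends[1L], ends[2L])
  }))
  list(
    baseline = build_interaction_tbl(base_raw, role = "baseline",
                                     source_label = "random_baseline"),
    new = build_interaction_tbl(new_raw, role = "new_list",
                                source_label = "random_new")
  )
}
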