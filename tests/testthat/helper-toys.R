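# Shared builders for toy interaction tables.

# One raw interaction row with dialect headers.
h_row <- function(src, tgt, sign = "positive", connection = "direct",
                  src_type = "protein", tgt_type = "protein",
                  src_comp = "", tgt_comp = "", mechanism = "",
                  cell_line = "", cell_type = "", tissue = "",
                  organism = "", context = "", paper = "", score = "") {
  data.frame(
    `Regulator Name` = src, `Regulator Type` = src_type,
    `Regulator Compartment` = src_comp,
    `Regulated Name` = tgt, `Regulated Type` = tgt_type,
    `Regulated Compartment` = tgt_comp,
    Sign = sign, `Connection Type` = connection, Mechanism = mechanism,
    `Cell Line` = cell_line, `Cell Type` = cell_type,
    `Tissue Type` = tissue, Organism = organism, Context = context,
    `Paper IDs` = paper, Evidence = "", Score = score,
    check.names = FALSE
  )
}

# Canonical tibble from h_row() pieces.
h_tbl <- function(..., role = "baseline") {
  build_interaction_tbl(do.call(rbind, list(...)), role = role)
}

# Category + subcategory of a single new interaction under a scheme.
h_classify1 <- function(new_tbl, g, scheme = "CS1",
                        strategy = attribute_strategy("CA1"), ...) {
  cl <- classify_interactions(new_tbl, g,
                              reconciler_config(scheme, strategy, ...))
  paste(cl$category, cl$subcategory, sep = "/")
}

# The five worked direction/path scenarios used in the acceptance suite:
# each is a toy baseline plus one new interaction with the expected
# category/subcategory per scheme.
h_worked_examples <- function() {
  list(
    # reversed direct edge, same sign, no attribute conflict
    list(
      baseline = h_tbl(h_row("LKB1", "AMPK", "positive", "direct")),
      new = h_tbl(h_row("AMPK", "LKB1", "positive", "indirect"),
                  role = "new_list"),
      expect = c(CS1 = "flagged/direction", CS2 = "flagged/direction",
                 CS3 = "contradiction/direction")
    ),
    # reversed edge plus compartment mismatch on both endpoints
    list(
      baseline = h_tbl(h_row("LKB1", "AMPK", "positive", "direct",
                             src_comp = "cytoplasm", tgt_comp = "cytoplasm")),
      new = h_tbl(h_row("AMPK", "LKB1", "positive", "indirect",
                        src_comp = "nucleus", tgt_comp = "nucleus"),
                  role = "new_list"),
      expect = c(CS1 = "contradiction/direction",
                 CS2 = "contradiction/direction",
                 CS3 = "flagged/direction")
    ),
    # reversed edge with sign flip and location mismatches
    list(
      baseline = h_tbl(h_row("LKB1", "AMPK", "positive", "direct",
                             src_comp = "cytoplasm", tgt_comp = "cytoplasm")),
      new = h_tbl(h_row("AMPK", "LKB1", "negative", "direct",
                        src_comp = "nucleus", tgt_comp = "nucleus"),
                  role = "new_list"),
      expect = c(CS1 = "contradiction/direction",
                 CS2 = "contradiction/direction",
                 CS3 = "flagged/direction")
    ),
    # both nodes known, neither an edge nor a path, direct claim
    list(
      baseline = h_tbl(h_row("MYC", "E2F1"), h_row("GSK3B", "TERT")),
      new = h_tbl(h_row("MYC", "TERT", "positive", "direct"),
                  role = "new_list"),
      expect = c(CS1 = "extension/internal", CS2 = "flagged/direct_no_edge",
                 CS3 = "extension/internal")
    ),
    # indirect claim matched only by a reversed two-edge path
    list(
      baseline = h_tbl(h_row("IL6", "IL6R"), h_row("IL6R", "STAT3")),
      new = h_tbl(h_row("STAT3", "IL6", "positive", "indirect"),
                  role = "new_list"),
      expect = c(CS1 = "flagged/path_mismatch", CS2 = "contradiction/path",
                 CS3 = "flagged/path_mismatch")
    )
  )
}
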