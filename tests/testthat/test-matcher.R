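el <- function(id, type = "protein") list(identifier = id, type = type)

test_that("element match requires identifier and type to agree", {
  expect_true(element_match(el("AMPK"), el(" ampk ")))
  expect_false(element_match(el("AMPK", "protein"), el("AMPK", "gene")))
  expect_false(element_match(el("AMPK"), el("LKB1")))
})

test_that("element match is an equivalence relation on normalized elements", {
  set.seed(4)
  ids <- c("a", "A ", "b", "q15831", "Q15831")
  types <- c("protein", "gene")
  pool <- expand.grid(id = ids, type = types, stringsAsFactors = FALSE)
  n <- nrow(pool)
  for (k in 1:200) {
    i <- sample(n, 1); j <- sample(n, 1); l <- sample(n, 1)
    a <- el(pool$id[i], pool$type[i])
    b <- el(pool$id[j], pool$type[j])
    c <- el(pool$id[l], pool$type[l])
    expect_true(element_match(a, a))                       # reflexive
    expect_equal(element_match(a, b), element_match(b, a)) # symmetric
    if (element_match(a, b) && element_match(b, c)) {      # transitive
      expect_true(element_match(a, c))
    }
    # agrees with direct string/type comparison
    expect_equal(element_match(a, b),
                 normalize_identity(a$identifier) == normalize_identity(b$identifier) &&
                   a$type == b$type)
  }
})

test_that("attribute strategies are nested and reject provenance fields", {
  sets <- lapply(c("CA0", "CA1", "CA2", "CA3", "CA4"), function(nm) {
    attribute_strategy(nm)$included
  })
  expect_equal(sets[[1]], character())
  expect_equal(sets[[2]], "compartment")
  expect_equal(sets[[3]], c("compartment", "mechanism"))
  expect_equal(sets[[4]], c("compartment", "mechanism", "cell_line"))
  for (i in 1:4) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  expect_error(attribute_strategy("custom", c("compartment", "paper_ids")),
               class = "netreconcile_config_error")
  expect_error(attribute_strategy("custom", "score"),
               class = "netreconcile_config_error")
  expect_equal(attribute_strategy("custom", c("mechanism", "tissue"))$included,
               c("mechanism", "tissue"))
})

test_that("identical interactions have an empty mismatch set under CA4", {
  x <- h_tbl(h_row("A", "B", src_comp = "cytoplasm", mechanism = "binding",
                   cell_line = "hela", tissue = "lung", organism = "human",
                   context = "stimulus:egf"))
  m <- attribute_mismatches(x[1, ], x[1, ], attribute_strategy("CA4"))
  expect_false(m$sign)
  expect_false(m$connection)
  expect_equal(m$attrs, character())
})

test_that("an empty attribute side never produces a mismatch", {
  new <- h_tbl(h_row("A", "B", cell_line = "hela"))
  base <- h_tbl(h_row("A", "B", cell_line = ""))
  m <- attribute_mismatches(new[1, ], base[1, ], attribute_strategy("CA3"))
  expect_equal(m$attrs, character())
  # and with both sides filled and different, the mismatch appears
  base2 <- h_tbl(h_row("A", "B", cell_line = "mcf7"))
  m2 <- attribute_mismatches(new[1, ], base2[1, ], attribute_strategy("CA3"))
  expect_equal(m2$attrs, "cell_line")
})

test_that("compartments are compared per endpoint, crosswise for reversed edges", {
  new <- h_tbl(h_row("A", "B", src_comp = "nucleus", tgt_comp = "cytoplasm"))
  base_fwd <- h_tbl(h_row("A", "B", src_comp = "cytoplasm",
                          tgt_comp = "cytoplasm"))
  m <- attribute_mismatches(new[1, ], base_fwd[1, ], attribute_strategy("CA1"))
  expect_equal(m$attrs, "compartment")

  # reversed baseline B->A: new source pairs with baseline target
  base_rev <- h_tbl(h_row("B", "A", src_comp = "cytoplasm",
                          tgt_comp = "nucleus"))
  m_rev <- attribute_mismatches(new[1, ], base_rev[1, ],
                                attribute_strategy("CA1"), reversed = TRUE)
  expect_equal(m_rev$attrs, character()) # crosswise values agree
})

test_that("context maps compare key-by-key with one-sided keys ignored", {
  new <- h_tbl(h_row("A", "B", context = "stimulus:egf;timepoint:24h"))
  same <- h_tbl(h_row("A", "B", context = "stimulus:egf"))
  diff <- h_tbl(h_row("A", "B", context = "stimulus:tnf;dose:10"))
  s4 <- attribute_strategy("CA4")
  expect_equal(attribute_mismatches(new[1, ], same[1, ], s4)$attrs, character())
  expect_equal(attribute_mismatches(new[1, ], diff[1, ], s4)$attrs,
               "context_other")
})

test_that("random attribute tables agree with a field-by-field oracle", {
  set.seed(77)
  vocab <- list(comp = c("cytoplasm", "nucleus", ""),
                mech = c("binding", "phosphorylation", ""),
                cl = c("hela", "mcf7", ""), ct = c("epithelial", ""),
                ti = c("lung", ""), org = c("human", "mouse", ""))
  draw <- function() {
    h_tbl(h_row("A", "B", sample(c("positive", "negative"), 1),
                sample(c("direct", "indirect"), 1),
                src_comp = sample(vocab$comp, 1),
                tgt_comp = sample(vocab$comp, 1),
                mechanism = sample(vocab$mech, 1),
                cell_line = sample(vocab$cl, 1),
                cell_type = sample(vocab$ct, 1),
                tissue = sample(vocab$ti, 1),
                organism = sample(vocab$org, 1)))
  }
  strategies <- lapply(c("CA0", "CA1", "CA2", "CA3", "CA4"),
                       attribute_strategy)
  conflict <- function(a, b) a != "" && b != "" && a != b
  for (k in 1:60) {
    new <- draw()[1, ]
    base <- draw()[1, ]
    want_all <- c(
      compartment = conflict(new$src_compartment, base$src_compartment) ||
        conflict(new$tgt_compartment, base$tgt_compartment),
      mechanism = conflict(new$mechanism, base$mechanism),
      cell_line = conflict(new$cell_line, base$cell_line),
      cell_type = conflict(new$cell_type, base$cell_type),
      tissue = conflict(new$tissue, base$tissue),
      organism = conflict(new$organism, base$organism),
      context_other = FALSE
    )
    prev <- character()
    for (s in strategies) {
      m <- attribute_mismatches(new, base, s)
      expect_equal(sort(m$attrs),
                   sort(names(which(want_all[s$included]))))
      expect_equal(m$sign, new$sign != base$sign)
      expect_equal(m$connection, new$connection != base$connection)
      # monotonicity across the nesting
      expect_true(all(prev %in% m$attrs))
      prev <- m$attrs
    }
  }
})

test_that("provenance never influences the mismatch set", {
  set.seed(5)
  base <- h_tbl(h_row("A", "B", src_comp = "cytoplasm", mechanism = "binding"))
  for (k in 1:25) {
    raw <- h_row("A", "B", src_comp = "cytoplasm", mechanism = "binding",
                 paper = paste0("pmid:", sample(1e6, 1)),
                 score = as.character(runif(1)))
    raw$Evidence <- paste(sample(letters, 12, replace = TRUE), collapse = "")
    new <- build_interaction_tbl(raw)
    m <- attribute_mismatches(new[1, ], base[1, ], attribute_strategy("CA4"))
    expect_false(m$sign)
    expect_equal(m$attrs, character())
  }
})

test_that("path matching aggregates sign, direction and edge attributes", {
  base <- h_tbl(h_row("A", "B", "positive"), h_row("B", "C", "positive"))
  g <- build_graph(base)
  p <- baseline_paths(g, element_key("A", "protein"),
                      element_key("C", "protein"))[[1]]
  new <- h_tbl(h_row("A", "C", "positive", "indirect"), role = "new_list")

  m0 <- match_against_path(new[1, ], p, g, attribute_strategy("CA0"))
  expect_false(m0$sign)
  expect_false(m0$direction)
  expect_equal(m0$attrs, character())

  # net-sign parity vs strict mode on a double-negative path
  base2 <- h_tbl(h_row("A", "B", "negative"), h_row("B", "C", "negative"))
  g2 <- build_graph(base2)
  p2 <- baseline_paths(g2, element_key("A", "protein"),
                       element_key("C", "protein"))[[1]]
  expect_equal(p2$net_sign, "positive")
  expect_false(match_against_path(new[1, ], p2, g2, attribute_strategy("CA0"),
                                  sign_mode = "parity")$sign)
  expect_true(match_against_path(new[1, ], p2, g2, attribute_strategy("CA0"),
                                 sign_mode = "strict")$sign)

  # reversed path sets the direction component
  m_rev <- match_against_path(new[1, ], p, g, attribute_strategy("CA0"),
                              reversed = TRUE)
  expect_true(m_rev$direction)
})

test_that("path attribute union agrees with edge-wise brute force", {
  set.seed(12)
  comp <- c("cytoplasm", "nucleus", "")
  mech <- c("binding", "phosphorylation", "")
  for (k in 1:25) {
    n_edge <- sample(2:5, 1)
    nodes <- sprintf("p%d", 0:n_edge)
    rows <- lapply(seq_len(n_edge), function(i) {
      h_row(nodes[i], nodes[i + 1], sample(c("positive", "negative"), 1),
            src_comp = sample(comp, 1), tgt_comp = sample(comp, 1),
            mechanism = sample(mech, 1))
    })
    base <- do.call(h_tbl, rows)
    g <- build_graph(base)
    p <- baseline_paths(g, element_key(nodes[1], "protein"),
                        element_key(nodes[n_edge + 1], "protein"),
                        max_len = 6)[[1]]
    new <- h_tbl(h_row(nodes[1], nodes[n_edge + 1], "positive", "indirect",
                       src_comp = sample(comp, 1), tgt_comp = sample(comp, 1),
                       mechanism = sample(mech, 1)), role = "new_list")[1, ]
    m <- match_against_path(new, p, g, attribute_strategy("CA2"))
    conflict <- function(a, b) a != "" && b != "" && a != b
    want <- character()
    if (any(vapply(seq_len(n_edge), function(i) {
      conflict(new$mechanism, base$mechanism[i])
    }, logical(1)))) want <- c(want, "mechanism")
    if (conflict(new$src_compartment, base$src_compartment[1]) ||
        conflict(new$tgt_compartment, base$tgt_compartment[n_edge])) {
      want <- c(want, "compartment")
    }
    expect_equal(sort(m$attrs), sort(want))
    expect_equal(m$sign,
                 (sum(base$sign == "negative") %% 2 == 0) !=
                   (new$sign == "positive"))
  }
})
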