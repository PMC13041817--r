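test_that("exact duplicates of baseline edges are strong corroborations everywhere", {
  base <- h_tbl(h_row("LKB1", "AMPK", "positive", "direct",
                      src_comp = "cytoplasm", tgt_comp = "cytoplasm",
                      mechanism = "phosphorylation", cell_line = "hela",
                      cell_type = "epithelial", tissue = "lung",
                      organism = "human", context = "stimulus:egf"))
  g <- build_graph(base)
  new <- h_tbl(h_row("LKB1", "AMPK", "positive", "direct",
                     src_comp = "cytoplasm", tgt_comp = "cytoplasm",
                     mechanism = "phosphorylation", cell_line = "hela",
                     cell_type = "epithelial", tissue = "lung",
                     organism = "human", context = "stimulus:egf"),
               role = "new_list")
  for (scheme in c("CS1", "CS2", "CS3")) {
    for (ca in c("CA0", "CA1", "CA2", "CA3", "CA4")) {
      expect_equal(h_classify1(new, g, scheme, attribute_strategy(ca)),
                   "corroboration/strong")
    }
  }
})

test_that("forward-edge decisions follow sign > attribute > connection > fill order", {
  base <- h_tbl(h_row("A", "B", "positive", "direct", src_comp = "cytoplasm",
                      mechanism = "binding"))
  g <- build_graph(base)
  ca2 <- attribute_strategy("CA2")

  # sign conflict dominates even with attribute conflicts present
  sign_new <- h_tbl(h_row("A", "B", "negative", "direct",
                          src_comp = "nucleus", mechanism = "transcription"),
                    role = "new_list")
  expect_equal(h_classify1(sign_new, g, "CS1", ca2), "contradiction/sign")

  # attribute conflict without sign conflict
  attr_new <- h_tbl(h_row("A", "B", "positive", "direct",
                          src_comp = "nucleus", mechanism = "binding"),
                    role = "new_list")
  expect_equal(h_classify1(attr_new, g, "CS1", ca2),
               "contradiction/attribute")

  # connection difference alone -> indirect corroboration
  conn_new <- h_tbl(h_row("A", "B", "positive", "indirect",
                          src_comp = "cytoplasm", mechanism = "binding"),
                    role = "new_list")
  expect_equal(h_classify1(conn_new, g, "CS1", ca2), "corroboration/indirect")

  # new fills attributes the baseline leaves empty -> specification
  spec_new <- h_tbl(h_row("A", "B", "positive", "direct",
                          src_comp = "cytoplasm", tgt_comp = "nucleus",
                          mechanism = "binding"),
                    role = "new_list")
  expect_equal(h_classify1(spec_new, g, "CS1", ca2),
               "corroboration/specification")

  # baseline-only values fall to weak_missing
  weak_new <- h_tbl(h_row("A", "B", "positive", "direct"), role = "new_list")
  expect_equal(h_classify1(weak_new, g, "CS1", ca2),
               "corroboration/weak_missing")
})

test_that("the best parallel edge wins: a sign-consistent edge avoids contradiction", {
  base <- h_tbl(h_row("A", "B", "negative", "direct"),
                h_row("A", "B", "positive", "direct"))
  g <- build_graph(base)
  new <- h_tbl(h_row("A", "B", "positive", "direct"), role = "new_list")
  cl <- classify_interactions(new, g, reconciler_config("CS1"))
  expect_equal(cl$category, "corroboration")
  expect_equal(cl$matched_edge_ids[[1]], 2L)
})

test_that("membership decides full and hanging extensions before anything else", {
  g <- build_graph(h_tbl(h_row("A", "B")))
  both_out <- h_tbl(h_row("X", "Y"), role = "new_list")
  one_out <- h_tbl(h_row("A", "Y"), role = "new_list")
  for (scheme in c("CS1", "CS2", "CS3")) {
    expect_equal(h_classify1(both_out, g, scheme), "extension/full")
    expect_equal(h_classify1(one_out, g, scheme), "extension/hanging")
  }
})

test_that("self-loops use edge logic only and never path searches", {
  g <- build_graph(h_tbl(h_row("A", "A", "positive"), h_row("A", "B"),
                         h_row("B", "A")))
  loop_match <- h_tbl(h_row("A", "A", "positive"), role = "new_list")
  expect_equal(h_classify1(loop_match, g, "CS1"), "corroboration/weak_missing")
  loop_flip <- h_tbl(h_row("A", "A", "negative"), role = "new_list")
  expect_equal(h_classify1(loop_flip, g, "CS1"), "contradiction/sign")
  # node B has no self-edge; A->B->A would be a cycle, not consulted
  loop_none <- h_tbl(h_row("B", "B", "positive"), role = "new_list")
  expect_equal(h_classify1(loop_none, g, "CS1"), "extension/internal")
})

test_that("CS2's direct flagging honours the strict path-only variant", {
  g <- build_graph(h_tbl(h_row("M", "P"), h_row("Q", "T")))
  new <- h_tbl(h_row("M", "T", "positive", "direct"), role = "new_list")
  expect_equal(h_classify1(new, g, "CS2"), "flagged/direct_no_edge")
  expect_equal(h_classify1(new, g, "CS2", direct_flag_mode = "path_only"),
               "extension/internal")
  # with a connecting path both variants flag under CS2
  g2 <- build_graph(h_tbl(h_row("M", "P"), h_row("P", "T")))
  expect_equal(h_classify1(new, g2, "CS2"), "flagged/direct_no_edge")
  expect_equal(h_classify1(new, g2, "CS2", direct_flag_mode = "path_only"),
               "flagged/direct_no_edge")
})

test_that("classification is total, order-preserving and permutation-equivariant", {
  fx <- generate_fixture(fixture_spec(seed = 21, duplicate_rate = 0.3))
  g <- build_graph(fx$baseline)
  cfg <- reconciler_config("CS1")
  cl <- classify_interactions(fx$new, g, cfg)
  expect_equal(nrow(cl), nrow(fx$new))
  expect_true(all(cl$category %in% c("corroboration", "contradiction",
                                     "flagged", "extension")))
  expect_false(any(is.na(cl$subcategory)))
  expect_equal(sum(table(cl$category)), nrow(fx$new))

  # empty list -> empty output
  expect_equal(nrow(classify_interactions(fx$new[0, ], g, cfg)), 0L)

  # permuted input -> permuted output (no cross-row state)
  set.seed(1)
  perm <- sample(nrow(fx$new))
  cl_perm <- classify_interactions(fx$new[perm, ], g, cfg)
  expect_equal(cl_perm$category, cl$category[perm])
  expect_equal(cl_perm$subcategory, cl$subcategory[perm])

  # n copies of one interaction -> n identical rows
  reps <- dplyr::bind_rows(rep(list(fx$new[1, ]), 5))
  cl_rep <- classify_interactions(reps, g, cfg)
  expect_equal(unique(cl_rep$category), cl$category[1])
})

test_that("schemes differ exactly on the reversed-edge and path/direct leaves", {
  fx <- generate_fixture(fixture_spec(seed = 33, default_count = 3))
  g <- build_graph(fx$baseline)
  cls <- lapply(c("CS1", "CS2", "CS3"), function(s) {
    classify_interactions(fx$new, g, reconciler_config(s))
  })
  leaves <- fx$truth$leaf
  diff12 <- which(cls[[1]]$category != cls[[2]]$category |
                    cls[[1]]$subcategory != cls[[2]]$subcategory)
  diff13 <- which(cls[[1]]$category != cls[[3]]$category |
                    cls[[1]]$subcategory != cls[[3]]$subcategory)
  expect_true(all(leaves[diff12] %in%
                    c("path_mismatch", "direct_path", "internal_direct")))
  expect_true(all(leaves[diff13] %in% c("direction", "direction_attr")))
  # and each scheme-sensitive leaf does differ where planted
  expect_true(all(c("path_mismatch", "direct_path", "internal_direct") %in%
                    leaves[diff12]))
  expect_true(all(c("direction", "direction_attr") %in% leaves[diff13]))
})

test_that("full and hanging extensions are invariant across attribute strategies", {
  fx <- generate_fixture(fixture_spec(seed = 8))
  g <- build_graph(fx$baseline)
  ref <- classify_interactions(fx$new, g, reconciler_config("CS1"))
  ext <- ref$subcategory %in% c("full", "hanging")
  for (ca in c("CA0", "CA2", "CA3", "CA4")) {
    cl <- classify_interactions(fx$new, g,
                                reconciler_config("CS1", attribute_strategy(ca)))
    expect_equal(cl$subcategory[ext], ref$subcategory[ext])
    expect_equal(cl$category[ext], ref$category[ext])
  }
})

test_that("corroborations shrink monotonically as strategies widen", {
  for (seed in c(3, 14, 25)) {
    case <- random_reconciliation_case(seed, n_nodes = 10, n_base = 20,
                                      n_new = 40, attribute_fill = 0.7)
    g <- build_graph(case$baseline)
    counts <- vapply(c("CA0", "CA1", "CA2", "CA3", "CA4"), function(ca) {
      cl <- classify_interactions(case$new, g,
                                  reconciler_config("CS1",
                                                    attribute_strategy(ca)))
      sum(cl$category == "corroboration")
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("classifier agrees with the brute-force oracle on random small instances", {
  for (s in c("CS1", "CS2", "CS3")) {
    for (i in 1:15) {
      case <- random_reconciliation_case(i + 500 * match(s, c("CS1", "CS2", "CS3")))
      cfg <- reconciler_config(s, strategy = attribute_strategy(
        c("CA0", "CA1", "CA2", "CA3", "CA4")[(i %% 5) + 1]))
      g <- build_graph(case$baseline)
      a <- classify_interactions(case$new, g, cfg)
      b <- brute_force_classify(case$new, case$baseline, cfg)
      expect_equal(a$category, b$category)
      expect_equal(a$subcategory, b$subcategory)
    }
  }
})

test_that("the oracle refuses large baselines and handles the empty graph", {
  case <- random_reconciliation_case(1, n_nodes = 30, n_base = 60)
  expect_error(brute_force_classify(case$new, case$baseline,
                                    reconciler_config()),
               class = "netreconcile_contract_error")
  empty <- h_tbl(h_row("A", "B"))[0, ]
  out <- brute_force_classify(h_tbl(h_row("X", "Y"), role = "new_list"),
                              empty, reconciler_config())
  expect_equal(out$category, "extension")
  expect_equal(out$subcategory, "full")
})
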