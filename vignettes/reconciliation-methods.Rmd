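---
title: "Reconciling extracted interactions with a curated baseline graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling extracted interactions with a curated baseline graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netreconcile)
```

## The reconciliation problem

Curated mechanistic models of cell signalling are directed, signed,
attributed graphs: nodes are biological elements (proteins, genes, RNAs,
chemicals, processes), edges state that a source element increases
(positive) or decreases (negative) a target, either as a single
mechanistic step (*direct*) or through unstated intermediates
(*indirect*), possibly qualified by compartment, mechanism and cellular
context. Machine readers and LLM extraction pipelines now emit candidate
interactions far faster than curators can vet them. `netreconcile` treats
the integration step as a formal graph-comparison problem: every row of a
new interaction list is classified relative to the baseline graph as a
corroboration, contradiction, flagged case, or extension, with a
subcategory, a pointer to the matched baseline edge or path, and the
mismatch set that drove the decision.

## Match conditions

Element identity is the pair (normalized identifier, element type).
Identifiers are lower-cased and whitespace-collapsed before comparison; no
synonym or ontology resolution is attempted, because grounding is the
extraction pipeline's responsibility and errors there surface, visibly, as
spurious extensions. When several identity columns are populated the
reader prefers database ID over symbol over name and records which was
used.

Two interactions satisfy the *necessary interaction match condition* when
both endpoint pairs element-match and the signs agree. Non-essential
attributes enter only through the configured attribute-inclusion strategy,
and a pair with at least one empty side never mismatches — absence of
annotation is not evidence of disagreement. Free-form context is compared
key-by-key, ignoring keys present on only one side, which is the same
empty-exclusion rule generalized to map entries. Provenance (paper IDs,
evidence statements, reader scores) is carried through to the output but
never inspected by any comparison; the test suite fuzzes provenance fields
to pin that down. Compartments are compared per matched endpoint
(source-vs-source and target-vs-target, or crosswise when a reversed edge
is the match), since the two endpoints of one interaction legitimately
live in different compartments.

## The decision tree

Classification proceeds most-specific-match-first, a precedence the data
formats leave open and which we fix as: forward edge over reversed edge,
edges over paths, forward paths over reversed paths.

1. **Membership.** If neither endpoint is a baseline node the row is a
   `full` extension; if exactly one is, `hanging`. These two leaves depend
   only on node identity, which is why they are provably invariant under
   every attribute strategy.
2. **Forward edge.** Among parallel edges the best match is the one with
   the smallest mismatch burden (sign counted heaviest, then the number of
   attribute mismatches; ties broken by baseline input order). This
   prevents a sign-consistent parallel edge from being shadowed by a
   contradicting one. A sign mismatch gives `contradiction/sign`
   regardless of anything else; otherwise an attribute mismatch gives
   `contradiction/attribute`; otherwise a direct/indirect disagreement
   gives `corroboration/indirect`; otherwise the corroboration subtype is
   decided by the fill pattern of the compared attributes — all filled on
   both sides: `strong`; the new row fills attributes the baseline leaves
   empty (and never the reverse): `specification`; anything else:
   `weak_missing`. Under `CA0` nothing is compared, so a sign- and
   connection-consistent edge match is vacuously `strong`.
3. **Reversed edge.** The mismatch set necessarily contains *direction*;
   compartments pair crosswise. Under CS1/CS2 a direction-only mismatch is
   `flagged/direction` and anything further makes it
   `contradiction/direction`; CS3 inverts this, on the reasoning that a
   bare reversal is a hard structural conflict while extra attribute
   disagreement hints at a different context in which the reversed claim
   might hold.
4. **Path.** Shortest paths by hop count (length ≥ 2, since a direct edge
   is not a path), forward first, reversed only if no forward path exists.
   An indirect new interaction with at least one fully consistent forward
   path is `corroboration/path`; with only mismatching paths (sign,
   attribute, or reversed direction) it is `flagged/path_mismatch` under
   CS1/CS3 and `contradiction/path` under CS2, and the path with the
   fewest mismatches is reported. A *direct* new interaction aligning only
   with a path is an `extension/internal` under CS1/CS3 but
   `flagged/direct_no_edge` under CS2, which treats a direct claim between
   path-connected nodes as a likely reader error.
5. **No connection.** Both endpoints known, no edge or path either way:
   `extension/internal`, except that CS2 flags *direct* rows as
   `direct_no_edge`. The published scheme description mentions only the
   path-aligned case, but its worked examples flag a direct claim with
   neither an edge nor a path; we therefore apply CS2's flagging whenever
   both endpoints are baseline nodes without a direct edge, and expose a
   `direct_flag_mode = "path_only"` switch for the narrower reading.

Self-loop interactions use edge logic only: reversed-edge and path queries
are meaningless for a single node, so a self-loop whose node exists but
has no self-edge falls through to `extension/internal`.

## Path conventions and numerical choices

*Net sign.* The sign of a path is the parity of its negative edges
(positive iff their number is even), the standard composition rule for
signed networks. Because the composition rule is a genuine modelling
choice, `sign_mode = "strict"` instead requires every path edge to carry
the new interaction's sign.

*Parallel edges on paths.* A path is a node-key sequence; the
representative edge of each hop is the first baseline row (input order)
among its parallel edges. Both the main classifier and the independent
brute-force reference implement this convention separately, so their
agreement is a check of the rule's implementation, not of a shared
shortcut.

*Determinism.* Equal-length paths are ordered lexicographically by their
node-key sequences before the `max_paths` cut; parallel-edge ties break by
input order; classification is row-independent, so permuting the input
permutes the output. Identical inputs and configuration give byte-identical
output files.

*Search limits.* `max_path_len = 6` hops and `max_paths = 10` by default.
Path search dominates the cost of classification, and unbounded
enumeration is pathological on dense graphs; six hops comfortably exceeds
the indirect-regulation depths that curated signalling models encode,
while keeping worst-case queries cheap. Both limits are configurable.

*Degenerate inputs.* An empty interaction list yields an empty (valid)
graph or an empty classified table; rows missing source or target identity
are rejected with a row-indexed report rather than dropped silently;
unknown sign vocabulary is an error listing the offending values, never a
guess; a missing connection column defaults to *indirect*, which is the
conservative choice because it avoids CS2's direct-specific flagging on
unannotated rows.

## Attribute strategies

`CA0` ⊂ `CA1` (compartment) ⊂ `CA2` (+mechanism) ⊂ `CA3` (+cell line) ⊂
`CA4` (+cell type, tissue, organism, free-form context). The exact roster
of "remaining context" attributes in the widest tier is not standardized
across extraction pipelines, so `CA4`'s tail is our enumeration and
`attribute_strategy("custom", ...)` accepts any subset. Nesting yields a
testable monotonicity: widening the strategy can only create mismatches,
so total corroborations are non-increasing from `CA0` to `CA4`
(specifications survive because one-sided-empty values are excluded).

## The fixture generator and what passing tests mean

`generate_fixture()` plants each decision-tree leaf as a dedicated motif —
exact copy, attribute fill/blank edits, sign flip, endpoint swap (with and
without a crosswise compartment edit), two-hop shortcuts over consistent,
sign-broken and reversed chains, disconnected node pairs — on top of a
disjoint random background component (directed random graph, 80% positive
edges, echoing activation-heavy curated networks; attribute fill rate
0.6). Motif nodes are unique per plant, so plants cannot interact; truth
labels come from a hand-coded per-leaf lookup conditional on scheme and on
whether the planted attribute is compared, not from the classifier.
Default problem sizes: two plants per leaf (30 new interactions) over a
baseline of roughly 70 rows; the property suites use up to 240 random
instances of ≤ 12 nodes for oracle comparison and lists of 10², 10³ and
10⁴ rows for the runtime-scaling fit.

The generator emulates the *structural* circumstances of each decision
leaf, with clean grounding and a controlled attribute vocabulary. It does
not emulate what makes real extractor output hard: inconsistent entity
grounding (the dominant source of spurious extensions in practice),
synonym and subtype variation, skewed category proportions (real lists are
overwhelmingly extensions), or free-text attribute noise. Passing the
closure and oracle suites therefore demonstrates that the decision logic
is implemented exactly as specified — it does not certify end-to-end
accuracy on any particular reader's output.

## Known limitations

- Reconciliation quality is bounded by upstream grounding; no attempt is
  made to resolve identifier variants across databases.
- Confidence scores from extraction systems are carried but not used;
  classification is purely structural.
- "Specification" covers attribute refinement only; element-level subtype
  specialisation (e.g. a family member refining a family node) is not
  detected, since element identity is atomic here.
- Coverage attribution for path corroborations marks every edge on the
  matched path (`coverage_mode = "edge_only"` disables this); which
  convention a given published coverage figure uses should be checked
  before comparing numbers.
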