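# Baseline graph store: a directed multigraph keyed by element identity,
# with edge lookup and hop-count shortest-path queries.
#
# Edge storage and all reconciliation logic are local; igraph stands behind
# the shortest-path search only (unit edge weights, i.e. search by hop
# count). Parallel edges with different sign/attributes are all retained in
# the edge table; for path queries the graph is simplified to unique node
# pairs, and the representative edge of a hop is the first baseline row (in
# input order) among its parallel edges.

#' Build a baseline graph from an interaction table
#'
#' Nodes are the union of all interaction endpoints, keyed by element
#' identity (normalized identifier + element type). Every input row becomes
#' exactly one directed edge; duplicated endpoint pairs yield parallel
#' edges.
#'
#' @param tbl Canonical interaction tibble (see [read_interactions()]).
#' @return A `baseline_graph` object: list with `nodes` (tibble: `key`,
#'   `identifier`, `type`, `name`), `edges` (the input tibble plus
#'   `edge_id`), and internal lookup structures.
#' @export
#' @examples
#' base <- build_interaction_tbl(data.frame(
#'   `Regulator Name` = "LKB1", `Regulated Name` = "AMPK",
#'   Sign = "positive", check.names = FALSE), role = "baseline")
#' g <- build_graph(base)
#' g
build_graph <- function(tbl) {
  edges <- tbl
  edges$edge_id <- seq_len(nrow(edges))

  node_tbl <- dplyr::bind_rows(
    tibble(key = edges$src_key, identifier = edges$src_identifier,
           type = edges$src_type, name = edges$src_name),
    tibble(key = edges$tgt_key, identifier = edges$tgt_identifier,
           type = edges$tgt_type, name = edges$tgt_name)
  )
  nodes <- dplyr::distinct(node_tbl, .data$key, .keep_all = TRUE)

  # pair index: "src_key=>tgt_key" -> integer edge ids (input order)
  pair_env <- new.env(parent = emptyenv(), size = max(16L, nrow(edges) * 2L))
  pair_keys <- paste0(edges$src_key, "=>", edges$tgt_key)
  for (i in seq_len(nrow(edges))) {
    k <- pair_keys[i]
    pair_env[[k]] <- c(pair_env[[k]], i)
  }

  node_env <- new.env(parent = emptyenv(), size = max(16L, nrow(nodes) * 2L))
  for (k in nodes$key) node_env[[k]] <- TRUE

  ig <- igraph::make_empty_graph(directed = TRUE)
  ig <- igraph::add_vertices(ig, nrow(nodes), name = nodes$key)
  if (nrow(edges) > 0) {
    uniq <- !duplicated(pair_keys)
    ig <- igraph::add_edges(
      ig, rbind(edges$src_key[uniq], edges$tgt_key[uniq]),
      attr = list(rep_edge = edges$edge_id[uniq])
    )
  }

  structure(
    list(nodes = nodes, edges = edges, pair_index = pair_env,
         node_index = node_env, igraph = ig,
         n_nodes = nrow(nodes), n_edges = nrow(edges)),
    class = "baseline_graph"
  )
}

#' @export
print.baseline_graph <- function(x, ...) {
  io <- io_node_counts(x)
  cat("<baseline_graph> ", x$n_nodes, " nodes, ", x$n_edges,
      " directed edges (", io[["inputs"]], " input, ", io[["outputs"]],
      " output nodes)\n", sep = "")
  invisible(x)
}

#' Graph-level summary of a baseline graph
#'
#' @param x A `baseline_graph`.
#' @param ... Unused.
#' @return One-row tibble: node, edge, input-node and output-node counts.
#' @export
glance.baseline_graph <- function(x, ...) {
  io <- io_node_counts(x)
  tibble(n_nodes = x$n_nodes, n_edges = x$n_edges,
         n_input_nodes = io[["inputs"]], n_output_nodes = io[["outputs"]])
}

#' Does the baseline graph contain a node with this identity key?
#'
#' @param g A `baseline_graph`.
#' @param key Element identity key (see [element_key()]).
#' @return Logical vector.
#' @export
has_node <- function(g, key) {
  vapply(key, function(k) !is.null(g$node_index[[k]]), logical(1),
         USE.NAMES = FALSE)
}

#' Input/output node counts
#'
#' Input nodes have no regulators (in-degree 0); output nodes have no
#' downstream targets (out-degree 0).
#'
#' @param g A `baseline_graph`.
#' @return Named integer vector `c(inputs = , outputs = )`.
#' @export
io_node_counts <- function(g) {
  if (g$n_nodes == 0) {
    return(c(inputs = 0L, outputs = 0L))
  }
  indeg <- igraph::degree(g$igraph, mode = "in")
  outdeg <- igraph::degree(g$igraph, mode = "out")
  c(inputs = sum(indeg == 0L), outputs = sum(outdeg == 0L))
}

#' Look up baseline edges between two elements
#'
#' Returns every parallel edge whose endpoints element-match the query, in
#' baseline input order; an empty edge tibble when either node is absent.
#' The query is directed: `find_edges(g, s, t)` and `find_edges(g, t, s)`
#' are independent.
#'
#' @param g A `baseline_graph`.
#' @param source,target Element identity keys (see [element_key()]).
#' @return Tibble of baseline edge rows (possibly empty).
#' @export
find_edges <- function(g, source, target) {
  ids <- g$pair_index[[paste0(source, "=>", target)]]
  g$edges[ids %||% integer(0), , drop = FALSE]
}

# Internal: shortest paths by hop count between two node keys, as lists of
# edge-id sequences. Assumes both endpoints exist. Paths of length 1 are
# excluded by deleting direct source->target edges before the search (a
# direct edge cannot occur inside a longer simple source->target path, so
# this leaves exactly the minimum-length paths of >= 2 hops).
shortest_key_paths <- function(g, source, target, max_len = 6L,
                               max_paths = 10L) {
  if (source == target) {
    return(list())
  }
  ig <- g$igraph
  eid <- suppressWarnings(
    igraph::get_edge_ids(ig, c(source, target), error = FALSE)
  )
  if (length(eid) > 0 && eid[1] > 0) {
    ig <- igraph::delete_edges(ig, eid[1])
  }
  res <- suppressWarnings(
    igraph::all_shortest_paths(ig, from = source, to = target, mode = "out")
  )
  vpaths <- res$vpaths %||% res$res
  if (length(vpaths) == 0) {
    return(list())
  }
  key_seqs <- lapply(vpaths, function(p) igraph::V(ig)$name[as.integer(p)])
  key_seqs <- key_seqs[lengths(key_seqs) - 1L >= 2L &
                         lengths(key_seqs) - 1L <= max_len]
  if (length(key_seqs) == 0) {
    return(list())
  }
  ord <- order(vapply(key_seqs, paste, character(1), collapse = " -> "))
  key_seqs <- key_seqs[ord]
  head(key_seqs, max_paths)
}

#' Enumerate shortest baseline paths between two elements
#'
#' Finds all minimum-hop-count directed paths of length >= 2 edges from
#' `source` to `target` (a direct edge is not a path), up to `max_paths`
#' paths of at most `max_len` hops, in deterministic lexicographic order of
#' the node-key sequence. Each hop is represented by the first baseline edge
#' (input order) among parallel edges, and the path's net sign is the
#' parity of negative edges along it: positive iff the number of
#' negative-sign edges is even.
#'
#' @param g A `baseline_graph`.
#' @param source,target Element identity keys; both must be present in `g`
#'   (check with [has_node()]) and distinct.
#' @param max_len Maximum path length in edges (default 6).
#' @param max_paths Maximum number of paths returned (default 10).
#' @return List of `baseline_path` objects: `keys` (node-key sequence),
#'   `edge_ids` (baseline edge ids), `length` (edge count), `net_sign`,
#'   `signs` (per-edge signs).
#' @export
baseline_paths <- function(g, source, target, max_len = 6L, max_paths = 10L) {
  if (!has_node(g, source) || !has_node(g, target)) {
    abort("both path endpoints must be baseline nodes; check has_node() first",
          class = "netreconcile_contract_error")
  }
  if (identical(source, target)) {
    abort("path query requires distinct endpoints",
          class = "netreconcile_contract_error")
  }
  key_seqs <- shortest_key_paths(g, source, target, max_len, max_paths)
  lapply(key_seqs, function(keys) path_from_keys(g, keys))
}

path_from_keys <- function(g, keys) {
  nhop <- length(keys) - 1L
  edge_ids <- integer(nhop)
  for (i in seq_len(nhop)) {
    ids <- g$pair_index[[paste0(keys[i], "=>", keys[i + 1L])]]
    edge_ids[i] <- ids[1L]
  }
  signs <- g$edges$sign[edge_ids]
  structure(
    list(keys = keys, edge_ids = edge_ids, length = nhop,
         net_sign = if (sum(signs == "negative") %% 2L == 0L) "positive" else "negative",
         signs = signs),
    class = "baseline_path"
  )
}

#' @export
print.baseline_path <- function(x, ...) {
  cat("<baseline_path> ", paste(sub("\\|\\|.*$", "", x$keys), collapse = " -> "),
      " (", x$length, " edges, net ", x$net_sign, ")\n", sep = "")
  invisible(x)
}
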