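# Shared fixtures and independent oracles for the test suite.

# tiny named undirected graph from "a-b" edge strings
mk_graph <- function(edges, isolated = character(0)) {
  pairs <- do.call(rbind, strsplit(edges, "-", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    as.data.frame(pairs, stringsAsFactors = FALSE), directed = FALSE,
    vertices = data.frame(
      name = unique(c(as.vector(t(pairs)), isolated)),
      stringsAsFactors = FALSE))
  igraph::simplify(g)
}

# random connected graph on n named nodes: spanning tree + extra edges
rand_connected_graph <- function(n, p_extra = 0.3) {
  ids <- sprintf("n%02d", seq_len(n))
  edges <- if (n > 1)
    cbind(ids[vapply(2:n, function(i) sample.int(i - 1, 1), 0L)], ids[2:n])
  else matrix(character(0), ncol = 2)
  if (n > 2) {
    all_pairs <- t(utils::combn(ids, 2))
    extra <- all_pairs[stats::runif(nrow(all_pairs)) < p_extra, , drop = FALSE]
    edges <- rbind(edges, extra)
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE), directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  igraph::simplify(g)
}

# random indicator matrix over the graph's genes
rand_matrix <- function(g, n_cases = sample(1:4, 1)) {
  genes <- igraph::V(g)$name
  indicator_matrix(matrix(
    stats::rbinom(length(genes) * n_cases, 1, 0.5),
    nrow = length(genes),
    dimnames = list(genes, paste0("c", seq_len(n_cases)))))
}

# --- independent naive oracle: maximum feasible connected subset -----------
# Enumerates every node subset with bitmask arithmetic; entirely separate
# from the package's grow-from-root enumeration.
oracle_best <- function(g, activity, strategy, budget) {
  nodes <- sort(igraph::V(g)$name)
  n <- length(nodes)
  el <- igraph::as_edgelist(g)
  adj_mask <- integer(n)
  for (i in seq_len(nrow(el))) {
    a <- match(el[i, 1], nodes); b <- match(el[i, 2], nodes)
    adj_mask[a] <- bitwOr(adj_mask[a], bitwShiftL(1L, b - 1L))
    adj_mask[b] <- bitwOr(adj_mask[b], bitwShiftL(1L, a - 1L))
  }
  exc <- stats::setNames(activity$exception_count, activity$gene)[nodes]
  active <- stats::setNames(activity$is_active, activity$gene)[nodes]
  cost <- if (strategy == "INES") as.integer(!active) else as.integer(exc)
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  best <- 0L
  for (s in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(s, bit) != 0L)
    if (length(idx) <= best) next
    if (sum(cost[idx]) > budget) next
    reach <- bit[idx[1]]
    repeat {
      nxt <- reach
      for (i in idx)
        if (bitwAnd(reach, bit[i]) != 0L)
          nxt <- bitwOr(nxt, bitwAnd(adj_mask[i], s))
      if (nxt == reach) break
      reach <- nxt
    }
    if (reach == s) best <- length(idx)
  }
  best
}

# --- brute-force check that no border-exception condition remains ----------
# For every retained exception node v: every component of G' - v must
# contain a non-exception node, and the number of such components must not
# be exactly 1 (otherwise v itself would still be a border exception node).
ben_condition_clear <- function(p) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(p$edges, stringsAsFactors = FALSE), directed = FALSE,
    vertices = data.frame(name = p$nodes, stringsAsFactors = FALSE))
  for (v in p$exception_nodes) {
    sub <- igraph::delete_vertices(g, v)
    if (igraph::vcount(sub) == 0) next
    comp <- igraph::components(sub)
    with_nonexc <- 0L
    for (ci in seq_len(comp$no)) {
      members <- names(comp$membership)[comp$membership == ci]
      if (all(members %in% p$exception_nodes)) return(FALSE)
      with_nonexc <- with_nonexc + 1L
    }
    if (with_nonexc == 1L) return(FALSE)
  }
  TRUE
}

# pathway constructed directly from graph + exception labels (bypasses the
# extractors, for BEN unit tests)
mk_pathway <- function(g, exceptions, n_cases = 4L) {
  nodes <- sort(igraph::V(g)$name)
  exc_count <- stats::setNames(ifelse(nodes %in% exceptions, n_cases, 0L),
                               nodes)
  structure(list(
    nodes = nodes,
    edges = igraph::as_edgelist(igraph::induced_subgraph(g, nodes)),
    exception_nodes = sort(intersect(nodes, exceptions)),
    node_exceptions = as.integer(exc_count) |> stats::setNames(nodes),
    total_case_exceptions = sum(exc_count),
    strategy = "INES", size = length(nodes)), class = "pathway")
}

# all 0/1 labelings of the graph's nodes as exception sets
all_exception_labelings <- function(g) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  lapply(seq_len(2^n) - 1L, function(mask)
    nodes[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L])
}
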