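#' Remove border exception nodes from a pathway
#'
#' Exception nodes sitting at the periphery of a solution ("border
#' exception nodes", BENs) inflate its size without bridging active
#' regions.  This filter repeatedly pops a random node `v` from the
#' remaining exception set; connected components of the pathway minus `v`
#' that consist solely of exception nodes are marked for removal, and if
#' exactly one component contains a non-exception node, `v` itself is a
#' BEN and is marked too.  Marked nodes and their incident edges are
#' removed and the loop continues until the exception set is exhausted.
#' Worst-case running time is O((|V| + |E|) * K).
#'
#' All non-exception nodes are always retained and the output is connected
#' whenever the input is.  The retained exception nodes may depend on the
#' pop order, hence the exposed seed.
#'
#' @param p a pathway object (its `exception_nodes` define the exception
#'   set; `edges` its induced subgraph).
#' @param rng_seed integer seed controlling the random pop order.
#' @return a pathway with the same `strategy` and no remaining BENs;
#'   `total_case_exceptions` is recomputed over the retained nodes.
#' @export
remove_border_exception_nodes <- function(p, rng_seed = 1L) {
  stopifnot(inherits(p, "pathway"))
  withr::with_seed(as.integer(rng_seed), {
    nodes <- p$nodes
    edges <- p$edges
    v_e <- p$exception_nodes
    adj <- edge_adj(nodes, edges)

    while (length(v_e) > 0) {
      v <- if (length(v_e) == 1) v_e else sample(v_e, 1)
      v_e <- setdiff(v_e, v)
      v_ben <- character(0)
      comps <- components_of(adj, setdiff(nodes, v))
      s <- 0L
      for (comp in comps) {
        if (all(comp %in% v_e)) {
          v_ben <- c(v_ben, comp)
        } else {
          s <- s + 1L
        }
      }
      if (s == 1L) v_ben <- c(v_ben, v)
      v_e <- setdiff(v_e, v_ben)
      if (length(v_ben)) {
        nodes <- setdiff(nodes, v_ben)
        keep <- !(edges[, 1] %in% v_ben | edges[, 2] %in% v_ben)
        edges <- edges[keep, , drop = FALSE]
        adj <- edge_adj(nodes, edges)
      }
    }
    nodes <- sort(nodes)
    total <- if (!is.null(p$node_exceptions))
      sum(p$node_exceptions[nodes]) else p$total_case_exceptions
    structure(list(nodes = nodes, edges = edges,
                   exception_nodes = sort(intersect(p$exception_nodes, nodes)),
                   node_exceptions = p$node_exceptions[nodes],
                   total_case_exceptions = total,
                   strategy = p$strategy, size = length(nodes)),
              class = "pathway")
  })
}

# adjacency list restricted to a node/edge set
edge_adj <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nm in nodes) adj[[nm]] <- character(0)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# connected components of the subgraph induced on `nodes`
components_of <- function(adj, nodes) {
  comps <- list()
  remaining <- nodes
  while (length(remaining)) {
    queue <- remaining[1]
    comp <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(intersect(adj[[v]], nodes), comp))
    }
    comps[[length(comps) + 1]] <- comp
    remaining <- setdiff(remaining, comp)
  }
  comps
}
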