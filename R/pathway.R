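#' Extraction configuration
#'
#' @param strategy `"INES"` (per-node L plus a budget of `k` inactive
#'   exception nodes per solution) or `"GLONE"` (a single global budget L
#'   on the total case exceptions summed over all solution genes; `k` is
#'   ignored).
#' @param algorithm `"greedy"` or `"exact"` (small-instance enumeration).
#' @param k exception-node budget for INES (integer >= 0).
#' @param l an [l_spec()] (or `"20%"` / numeric shorthand).
#' @param ben_filter logical; apply the border-exception-node filter
#'   ([remove_border_exception_nodes()]) to INES solutions.
#' @param max_solutions maximum number of ranked solutions returned.
#' @param seed integer seed (used by the BEN filter's random pop order).
#' @return an `extraction_config` object.
#' @export
extraction_config <- function(strategy = c("INES", "GLONE"),
                              algorithm = c("greedy", "exact"),
                              k = 0L, l = 0L, ben_filter = FALSE,
                              max_solutions = 20L, seed = 1L) {
  strategy <- match.arg(strategy)
  algorithm <- match.arg(algorithm)
  stopifnot(k >= 0, max_solutions >= 1)
  structure(list(strategy = strategy, algorithm = algorithm,
                 k = as.integer(k), l = l_spec(l),
                 ben_filter = isTRUE(ben_filter),
                 max_solutions = as.integer(max_solutions),
                 seed = as.integer(seed)),
            class = "extraction_config")
}

# Construct a pathway (extracted solution) from a node set.
# `graph_adj` is the named adjacency list of the host network.
new_pathway <- function(nodes, graph_adj, act, strategy) {
  nodes <- sort(unique(as.character(nodes)))
  edges <- induced_edges(graph_adj, nodes)
  exception_nodes <- nodes[!act$active[nodes]]
  node_exceptions <- stats::setNames(as.integer(act$exc[nodes]), nodes)
  structure(list(nodes = nodes, edges = edges,
                 exception_nodes = exception_nodes,
                 node_exceptions = node_exceptions,
                 total_case_exceptions = sum(node_exceptions),
                 strategy = strategy, size = length(nodes)),
            class = "pathway")
}

empty_pathway <- function(strategy = "INES") {
  structure(list(nodes = character(0),
                 edges = matrix(character(0), ncol = 2),
                 exception_nodes = character(0),
                 node_exceptions = stats::setNames(integer(0), character(0)),
                 total_case_exceptions = 0L,
                 strategy = strategy, size = 0L),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("<pathway: %d node(s), %d exception node(s), %d total case exception(s)>\n",
              x$size, length(x$exception_nodes), x$total_case_exceptions))
  if (x$size) cat(" ", paste(x$nodes, collapse = " "), "\n")
  invisible(x)
}

# named adjacency list (character neighbours) from an igraph network
adjacency_list <- function(network) {
  nm <- igraph::V(network)$name
  adj <- igraph::as_adj_list(network, mode = "all")
  out <- lapply(adj, function(v) nm[as.integer(v)])
  names(out) <- nm
  out
}

induced_edges <- function(adj, nodes) {
  keep <- nodes
  rows <- list()
  for (v in keep) {
    nb <- intersect(adj[[v]], keep)
    nb <- nb[nb > v]
    if (length(nb)) rows[[v]] <- cbind(v, nb)
  }
  if (length(rows) == 0) return(matrix(character(0), ncol = 2))
  m <- do.call(rbind, rows)
  dimnames(m) <- NULL
  m
}

# connectivity of a node subset under an adjacency list
subset_connected <- function(adj, nodes) {
  n <- length(nodes)
  if (n <= 1) return(TRUE)
  seen <- stats::setNames(logical(n), nodes)
  queue <- nodes[1]
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- intersect(adj[[v]], nodes)
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Test whether a node set is a feasible solution
#'
#' A pathway is valid when its induced subgraph is connected and its
#' exception usage is within budget: at most `k` inactive nodes under
#' INES, or total case exceptions at most the resolved L under GLONE.
#'
#' @param p a pathway object or character vector of node ids.
#' @param network the host igraph network.
#' @param activity an `activity_profile` (see [compute_activity()]).
#' @param config an [extraction_config()].
#' @return logical.
#' @export
is_valid_solution <- function(p, network, activity, config) {
  nodes <- if (inherits(p, "pathway")) p$nodes else as.character(p)
  if (length(nodes) == 0) return(FALSE)
  adj <- adjacency_list(network)
  act <- activity_lookup(activity)
  if (!all(nodes %in% names(adj))) return(FALSE)
  if (!subset_connected(adj, nodes)) return(FALSE)
  if (config$strategy == "INES") {
    sum(!act$active[nodes]) <= config$k
  } else {
    sum(act$exc[nodes]) <= glone_budget(config$l, attr(activity, "n_cases"))
  }
}

# internal feasibility check against precomputed lookups
feasible_set <- function(nodes, adj, act, strategy, k, l_total) {
  if (!subset_connected(adj, nodes)) return(FALSE)
  if (strategy == "INES") sum(!act$active[nodes]) <= k
  else sum(act$exc[nodes]) <= l_total
}

# rank a list of node-set character vectors: size desc, then
# lexicographically smallest sorted tuple; dedupe; cap at max_solutions
rank_solutions <- function(node_sets, graph_adj, act, strategy, max_solutions) {
  if (length(node_sets) == 0) return(list())
  node_sets <- lapply(node_sets, function(x) sort(unique(x)))
  keys <- vapply(node_sets, paste, "", collapse = "\t")
  node_sets <- node_sets[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  sizes <- lengths(node_sets)
  ord <- order(-sizes, keys, method = "radix")
  node_sets <- node_sets[ord][seq_len(min(length(node_sets), max_solutions))]
  lapply(node_sets, new_pathway, graph_adj = graph_adj, act = act,
         strategy = strategy)
}
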