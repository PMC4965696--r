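#' Greedy module-cover extraction
#'
#' Grows one candidate solution from every feasible seed node: at each step
#' the feasible neighbouring node is added that (1) is active, then (2)
#' brings the most new active neighbours, then (3) has the smallest id;
#' growth stops when no feasible neighbour remains.  Candidates are
#' deduplicated and ranked by size (descending), ties broken by the
#' lexicographically smallest sorted node-id tuple.  The procedure is fully
#' deterministic.
#'
#' @param network host igraph network.
#' @param activity an `activity_profile` covering the network's genes.
#' @param config an [extraction_config()] with `algorithm = "greedy"`.
#' @return a ranked list of pathway objects (possibly empty), at most
#'   `config$max_solutions` long.
#' @export
greedy_extract <- function(network, activity, config) {
  nodes <- igraph::V(network)$name
  if (length(nodes) == 0) return(list())
  adj <- adjacency_list(network)
  act <- activity_lookup(activity)
  ines <- config$strategy == "INES"
  l_total <- if (ines) NA_integer_
             else glone_budget(config$l, attr(activity, "n_cases"))

  seeds <- if (ines) {
    if (config$k >= 1) nodes else nodes[act$active[nodes]]
  } else {
    nodes[act$exc[nodes] <= l_total]
  }
  if (length(seeds) == 0) return(list())

  grow <- function(seed) {
    sub <- seed
    in_sub <- stats::setNames(logical(length(nodes)), nodes)
    in_sub[seed] <- TRUE
    used <- if (ines) as.integer(!act$active[seed]) else act$exc[seed]
    repeat {
      frontier <- unique(unlist(adj[sub], use.names = FALSE))
      frontier <- frontier[!in_sub[frontier]]
      if (ines) {
        feas <- act$active[frontier] | used < config$k
      } else {
        feas <- used + act$exc[frontier] <= l_total
      }
      frontier <- frontier[feas]
      if (length(frontier) == 0) break
      gain <- vapply(frontier, function(v) {
        nb <- adj[[v]]
        sum(act$active[nb] & !in_sub[nb])
      }, 0L)
      ord <- order(!act$active[frontier], -gain, frontier, method = "radix")
      best <- frontier[ord[1]]
      sub <- c(sub, best)
      in_sub[best] <- TRUE
      used <- used + if (ines) as.integer(!act$active[best]) else act$exc[best]
    }
    sub
  }

  sols <- lapply(seeds, grow)
  rank_solutions(sols, adj, act, config$strategy, config$max_solutions)
}

#' Exact small-instance extraction by connected-subgraph enumeration
#'
#' Enumerates every connected induced subgraph once (grow-from-each-root
#' enumeration with an exclusion set, pruning branches whose exception
#' usage already exceeds the budget — usage is monotone under growth) and
#' returns a maximum-cardinality feasible pathway, ties broken by the
#' lexicographically smallest sorted node-id tuple.  Intended as a
#' small-instance optimum oracle; use [greedy_extract()] beyond
#' `node_limit` nodes.
#'
#' @param network host igraph network (at most `node_limit` nodes).
#' @param activity an `activity_profile`.
#' @param config an [extraction_config()] with `algorithm = "exact"`.
#' @param node_limit refuse instances larger than this (default 15).
#' @return a single pathway (empty pathway if no feasible solution exists).
#' @export
exact_extract <- function(network, activity, config, node_limit = 15L) {
  nodes <- sort(igraph::V(network)$name)
  if (length(nodes) > node_limit)
    stop(sprintf("exact extraction limited to %d nodes (got %d); use the greedy algorithm",
                 node_limit, length(nodes)), call. = FALSE)
  if (length(nodes) == 0) return(empty_pathway(config$strategy))
  adj <- adjacency_list(network)
  act <- activity_lookup(activity)
  ines <- config$strategy == "INES"
  l_total <- if (ines) NA_integer_
             else glone_budget(config$l, attr(activity, "n_cases"))
  budget <- if (ines) config$k else l_total
  cost <- function(v) if (ines) as.integer(!act$active[[v]]) else act$exc[[v]]

  best_nodes <- character(0)
  best_key <- ""
  consider <- function(sub) {
    if (length(sub) < length(best_nodes)) return(invisible())
    key <- paste(sort(sub), collapse = "\t")
    if (length(sub) > length(best_nodes) ||
        (length(sub) == length(best_nodes) && key < best_key)) {
      best_nodes <<- sub
      best_key <<- key
    }
    invisible()
  }

  recurse <- function(sub, used, ext, forb) {
    consider(sub)
    while (length(ext)) {
      v <- ext[1]
      ext <- ext[-1]
      c_v <- cost(v)
      if (used + c_v <= budget) {
        new_ext <- unique(c(ext, setdiff(adj[[v]], c(sub, forb, ext, v))))
        recurse(c(sub, v), used + c_v, new_ext, forb)
      }
      forb <- c(forb, v)
    }
  }

  forb_global <- character(0)
  for (root in nodes) {
    c_r <- cost(root)
    if (c_r <= budget) {
      recurse(root, c_r, setdiff(adj[[root]], c(forb_global, root)),
              forb_global)
    }
    forb_global <- c(forb_global, root)
  }
  if (length(best_nodes) == 0) return(empty_pathway(config$strategy))
  new_pathway(best_nodes, adj, act, config$strategy)
}

#' Run a full module-cover extraction
#'
#' High-level wrapper: combines datasets, resolves L against the case
#' count, computes activity over the network's genes (honouring a positive
#' list attached by [apply_node_lists()]), dispatches to the configured
#' extractor and optionally applies the border-exception-node filter.
#'
#' @param network host igraph network (optionally annotated by
#'   [apply_node_lists()]).
#' @param datasets an [indicator_matrix()] or [dataset_collection()].
#' @param config an [extraction_config()].
#' @return a ranked list of pathway objects.
#' @export
extract_pathways <- function(network, datasets, config) {
  matrix <- if (inherits(datasets, "dataset_collection"))
    combine_datasets(datasets) else datasets
  stopifnot(inherits(matrix, "indicator_matrix"))
  positive <- igraph::graph_attr(network, "positive") %||% character(0)
  # for GLONE the per-node activity flag only steers greedy preferences and
  # exception-node labelling; the budget itself is global and uncapped
  l <- if (config$strategy == "INES") resolve_l(config$l, ncol(matrix))
       else min(glone_budget(config$l, ncol(matrix)), ncol(matrix))
  activity <- compute_activity(matrix, l, positive = positive,
                               genes = igraph::V(network)$name)
  sols <- if (config$algorithm == "greedy") {
    greedy_extract(network, activity, config)
  } else {
    p <- exact_extract(network, activity, config)
    if (p$size == 0) list() else list(p)
  }
  if (config$ben_filter && config$strategy == "INES" && length(sols)) {
    adj <- adjacency_list(network)
    act <- activity_lookup(activity)
    sols <- lapply(seq_along(sols), function(i)
      remove_border_exception_nodes(sols[[i]],
                                    rng_seed = config$seed + i - 1L))
    sols <- rank_solutions(lapply(sols, `[[`, "nodes"), adj, act,
                           config$strategy, config$max_solutions)
  }
  sols
}
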