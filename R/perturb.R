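#' Network perturbation strategies
#'
#' Four common strategies for introducing controlled noise into an
#' interaction network, used to probe how stable extracted pathways are
#' when the network changes:
#'
#' * **label_permutation** — pairs of nodes swap identities: the edge
#'   structure is preserved exactly, but the local density of active genes
#'   changes because a gene's activity follows its label while its
#'   topological position does not.
#' * **rewire** — Maslov–Sneppen degree-preserving rewiring: two edges
#'   `(a,b)` and `(c,d)` are replaced by `(a,d)` and `(c,b)`, rejecting
#'   swaps that would create self-loops or duplicate edges, so every
#'   node's degree is preserved exactly.
#' * **node_removal** — a fraction of nodes is deleted with incident
#'   edges, emulating a less complete network.
#' * **edge_removal** — a fraction of edges is deleted, reducing density
#'   while keeping the node set.
#'
#' The perturbation level is a percentage in `[0, 100]`: the fraction of
#' nodes relabelled/removed or of edges rewired/removed (round-half-up
#' counts).  Level 0 is the identity for every strategy, and a fixed seed
#' yields a bit-identical result.
#'
#' @param net igraph network.
#' @param level percentage in `[0, 100]`.
#' @param rng_seed integer seed.
#' @return a `perturbed_network`: list with elements `network` (igraph),
#'   `strategy`, `level`, `seed`.
#' @name perturbation
NULL

new_perturbed <- function(network, strategy, level, seed) {
  structure(list(network = network, strategy = strategy,
                 level = level, seed = as.integer(seed)),
            class = "perturbed_network")
}

#' @export
print.perturbed_network <- function(x, ...) {
  cat(sprintf("<perturbed_network: %s at %g%% (seed %d): %d nodes, %d edges>\n",
              x$strategy, x$level, x$seed,
              igraph::vcount(x$network), igraph::ecount(x$network)))
  invisible(x)
}

check_level <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1, level >= 0, level <= 100)
}

#' @rdname perturbation
#' @export
permute_node_labels <- function(net, level, rng_seed = 1L) {
  check_level(level)
  m <- round_half_up(level / 100 * igraph::vcount(net))
  if (level == 0 || m < 2)
    return(new_perturbed(net, "label_permutation", level, rng_seed))
  withr::with_seed(as.integer(rng_seed), {
    labels <- igraph::V(net)$name
    chosen <- sample(seq_along(labels), m)
    repeat {
      perm <- sample(m)
      if (!all(perm == seq_len(m))) break
    }
    labels[chosen] <- labels[chosen][perm]
    out <- net
    igraph::V(out)$name <- labels
    new_perturbed(out, "label_permutation", level, rng_seed)
  })
}

#' @rdname perturbation
#' @export
rewire_degree_preserving <- function(net, level, rng_seed = 1L) {
  check_level(level)
  target <- round_half_up(level / 100 * igraph::ecount(net))
  if (level == 0 || target == 0)
    return(new_perturbed(net, "rewire", level, rng_seed))
  withr::with_seed(as.integer(rng_seed), {
    el <- igraph::as_edgelist(net)
    n_edges <- nrow(el)
    if (n_edges < 2) return(new_perturbed(net, "rewire", level, rng_seed))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\t")
    present <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(n_edges)) assign(key(el[i, 1], el[i, 2]), TRUE, present)
    rewired <- logical(n_edges)
    done <- 0L
    attempts <- 0L
    cap <- 100L * target
    while (done < target && attempts < cap) {
      attempts <- attempts + 1L
      cand <- which(!rewired)
      if (length(cand) < 2) break
      ij <- sample(cand, 2)
      a <- el[ij[1], 1]; b <- el[ij[1], 2]
      c <- el[ij[2], 1]; d <- el[ij[2], 2]
      # randomize orientation of the second edge
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # proposed replacement: (a,d) and (c,b)
      if (a == d || c == b) next
      k1 <- key(a, d); k2 <- key(c, b)
      if (k1 == k2 || exists(k1, present) || exists(k2, present)) next
      rm(list = c(key(a, b), key(c, d)), envir = present)
      assign(k1, TRUE, present)
      assign(k2, TRUE, present)
      el[ij[1], ] <- c(a, d)
      el[ij[2], ] <- c(c, b)
      rewired[ij] <- TRUE
      done <- done + 2L
    }
    if (done < target)
      warning(sprintf(
        "rewiring stopped after %d attempts with %d of %d edges rewired",
        attempts, done, target), call. = FALSE)
    out <- as_network(el, igraph::V(net)$name)
    new_perturbed(out, "rewire", level, rng_seed)
  })
}

#' @rdname perturbation
#' @export
remove_nodes <- function(net, level, rng_seed = 1L) {
  check_level(level)
  m <- round_half_up(level / 100 * igraph::vcount(net))
  if (m == 0) return(new_perturbed(net, "node_removal", level, rng_seed))
  withr::with_seed(as.integer(rng_seed), {
    drop <- sample(igraph::V(net)$name, m)
    new_perturbed(igraph::delete_vertices(net, drop),
                  "node_removal", level, rng_seed)
  })
}

#' @rdname perturbation
#' @export
remove_edges <- function(net, level, rng_seed = 1L) {
  check_level(level)
  m <- round_half_up(level / 100 * igraph::ecount(net))
  if (m == 0) return(new_perturbed(net, "edge_removal", level, rng_seed))
  withr::with_seed(as.integer(rng_seed), {
    drop <- sample(seq_len(igraph::ecount(net)), m)
    new_perturbed(igraph::delete_edges(net, drop),
                  "edge_removal", level, rng_seed)
  })
}

#' Dispatch a perturbation strategy by name
#'
#' @param strategy one of `"label_permutation"`, `"rewire"`,
#'   `"node_removal"`, `"edge_removal"` (CLI aliases `labelswap`,
#'   `noderemove`, `edgeremove` accepted).
#' @inheritParams perturbation
#' @return a `perturbed_network`.
#' @export
perturb_network <- function(net, strategy, level, rng_seed = 1L) {
  strategy <- switch(strategy,
    labelswap = "label_permutation",
    noderemove = "node_removal",
    edgeremove = "edge_removal",
    strategy)
  fn <- switch(strategy,
    label_permutation = permute_node_labels,
    rewire = rewire_degree_preserving,
    node_removal = remove_nodes,
    edge_removal = remove_edges,
    stop("unknown perturbation strategy: ", strategy, call. = FALSE))
  fn(net, level, rng_seed)
}
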