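#' Synthetic planted-module instance specification
#'
#' Defaults describe the benchmark condition used throughout the test
#' suite: a 100-node scale-free background network (preferential
#' attachment, 2 edges per new node, mirroring the topology of biological
#' interaction networks), a planted connected module of 10 genes, and a
#' 40-case indicator matrix in which module genes are active in 95% of
#' cases and background genes in 5%.
#'
#' @param n_nodes nodes in the background network.
#' @param attachment edges added per node during preferential attachment.
#' @param module_size size of the planted connected module.
#' @param n_cases number of cases (matrix columns).
#' @param p_active_in_module per-case activity probability for module genes.
#' @param p_active_background per-case activity probability elsewhere.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_nodes = 100L, attachment = 2L,
                           module_size = 10L, n_cases = 40L,
                           p_active_in_module = 0.95,
                           p_active_background = 0.05, seed = 1L) {
  stopifnot(module_size <= n_nodes, n_nodes >= 2, attachment >= 1,
            n_cases >= 1,
            p_active_in_module >= 0, p_active_in_module <= 1,
            p_active_background >= 0, p_active_background <= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 attachment = as.integer(attachment),
                 module_size = as.integer(module_size),
                 n_cases = as.integer(n_cases),
                 p_active_in_module = p_active_in_module,
                 p_active_background = p_active_background,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a planted-module synthetic instance
#'
#' Builds a scale-free background network by preferential attachment,
#' plants a random connected module (breadth-first growth from a random
#' root with shuffled neighbour order), and draws a binary indicator
#' matrix whose module rows are dense in 1s and background rows sparse.
#' The planted module is returned as the gold-standard set.  Fully
#' deterministic for a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `network` (igraph), `matrix`
#'   ([indicator_matrix()]), `gold` (character vector of module gene ids)
#'   and `spec`.
#' @export
generate_synthetic_instance <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    g <- igraph::sample_pa(spec$n_nodes, m = spec$attachment,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("g%0*d", nchar(spec$n_nodes),
                                 seq_len(spec$n_nodes))
    adj <- adjacency_list(g)

    # random connected module: BFS from a random root, shuffled frontier
    root <- sample(igraph::V(g)$name, 1)
    module <- character(0)
    frontier <- root
    while (length(module) < spec$module_size) {
      if (length(frontier) == 0)
        stop("background network too fragmented to plant the module",
             call. = FALSE)
      v <- frontier[1]
      frontier <- frontier[-1]
      if (v %in% module) next
      module <- c(module, v)
      nb <- setdiff(adj[[v]], c(module, frontier))
      if (length(nb) > 1) nb <- sample(nb)
      frontier <- c(frontier, nb)
    }

    genes <- igraph::V(g)$name
    p <- ifelse(genes %in% module, spec$p_active_in_module,
                spec$p_active_background)
    vals <- matrix(stats::rbinom(length(genes) * spec$n_cases, 1,
                                 rep(p, times = spec$n_cases)),
                   nrow = length(genes), ncol = spec$n_cases,
                   dimnames = list(genes, paste0("c", seq_len(spec$n_cases))))
    list(network = g, matrix = indicator_matrix(vals, "synthetic"),
         gold = sort(module), spec = spec)
  })
}
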