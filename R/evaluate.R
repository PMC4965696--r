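#' Jaccard similarity between two gene sets
#'
#' `|a ∩ b| / |a ∪ b|`.  Two empty sets are equal and score 1 (a warning
#' notes the degenerate comparison); an empty set against a non-empty set
#' scores 0.
#'
#' @param a,b character vectors of gene identifiers (duplicates ignored).
#' @return a number in `[0, 1]`.
#' @examples
#' jaccard(c("x", "y"), c("y", "z")) # 1/3
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0 && length(b) == 0) {
    warning("Jaccard of two empty sets defined as 1", call. = FALSE)
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Pick the largest solution from a ranked list
#'
#' Largest = most nodes; ties broken by the lexicographically smallest
#' sorted node-id tuple.  An empty list yields an empty pathway (whose
#' Jaccard against any non-empty baseline is 0).
#'
#' @param solutions list of pathway objects.
#' @return a single pathway.
#' @export
largest_solution <- function(solutions) {
  if (length(solutions) == 0) return(empty_pathway())
  best <- solutions[[1]]
  for (p in solutions[-1]) {
    if (p$size > best$size ||
        (p$size == best$size && tuple_less(p$nodes, best$nodes)))
      best <- p
  }
  best
}

run_batch <- function(network, datasets, config, strategy, levels,
                      n_per_level, master_seed, score_fn) {
  stopifnot(length(levels) >= 1, all(levels >= 0 & levels <= 100),
            n_per_level >= 1)
  baseline <- largest_solution(extract_pathways(network, datasets, config))
  rows <- vector("list", length(levels) * n_per_level)
  idx <- 1L
  for (lev in levels) {
    for (rep in seq_len(n_per_level)) {
      seed <- derive_seed(master_seed, strategy, lev, rep)
      pert <- perturb_network(network, strategy, lev, seed)
      sol <- tryCatch(
        largest_solution(extract_pathways(pert$network, datasets, config)),
        error = function(e) empty_pathway(config$strategy))
      rows[[idx]] <- data.frame(level = lev, replicate = rep, seed = seed,
                                jaccard = score_fn(sol, baseline),
                                stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  list(baseline = baseline, table = do.call(rbind, rows))
}

#' Robustness analysis over perturbation levels
#'
#' Extracts pathways once from the unperturbed network, then for each
#' perturbation level generates `n_per_level` perturbed replicates
#' (replicate seeds derived deterministically from `master_seed`, the
#' strategy, the level and the replicate index), re-runs the identical
#' extraction, and records the Jaccard overlap between the largest
#' perturbed and largest unperturbed solutions.
#'
#' @param network host igraph network.
#' @param datasets an [indicator_matrix()] or [dataset_collection()].
#' @param config an [extraction_config()].
#' @param strategy perturbation strategy (see [perturb_network()]).
#' @param levels perturbation percentages, e.g. `seq(10, 50, 10)`.
#' @param n_per_level replicate networks per level (default 10).
#' @param master_seed integer master seed.
#' @return a `robustness_result`: data frame with columns `level`,
#'   `replicate`, `seed`, `jaccard` and attributes `baseline` (pathway),
#'   `strategy`, `master_seed`.
#' @export
robustness_analysis <- function(network, datasets, config, strategy,
                                levels = seq(10, 50, 10), n_per_level = 10,
                                master_seed = 1L) {
  out <- run_batch(network, datasets, config, strategy, levels, n_per_level,
                   master_seed,
                   score_fn = function(sol, baseline)
                     suppressWarnings(jaccard(sol$nodes, baseline$nodes)))
  structure(out$table, baseline = out$baseline, strategy = strategy,
            master_seed = master_seed,
            class = c("robustness_result", "data.frame"))
}

#' Validation analysis against a gold-standard gene set
#'
#' Like [robustness_analysis()], but each replicate's largest solution is
#' compared against a curated gold-standard set, and the baseline overlap
#' `J(S_unperturbed, S_gold)` is recorded.  All solution genes count,
#' including exception nodes (a disease gene may well enter a solution as
#' an exception node).
#'
#' @inheritParams robustness_analysis
#' @param gold non-empty character vector of gold-standard gene ids.
#' @return a `validation_result` data frame (columns as in
#'   [robustness_analysis()]) with attributes `baseline`, `gold`,
#'   `baseline_jaccard`, `strategy`, `master_seed`.
#' @export
validation_analysis <- function(network, datasets, config, strategy,
                                levels = seq(10, 50, 10), n_per_level = 10,
                                gold, master_seed = 1L) {
  gold <- unique(as.character(gold))
  stopifnot(length(gold) >= 1)
  out <- run_batch(network, datasets, config, strategy, levels, n_per_level,
                   master_seed,
                   score_fn = function(sol, baseline)
                     suppressWarnings(jaccard(sol$nodes, gold)))
  structure(out$table, baseline = out$baseline, gold = gold,
            baseline_jaccard = suppressWarnings(jaccard(out$baseline$nodes, gold)),
            strategy = strategy, master_seed = master_seed,
            class = c("validation_result", "data.frame"))
}

#' Summarize Jaccard values per perturbation level
#'
#' @param result a `robustness_result` or `validation_result`.
#' @return data frame with one row per level: `level`, `n`, `mean`, `sd`,
#'   `median`, `min`, `max` (sd of a single value is 0).
#' @export
summarize_levels <- function(result) {
  stopifnot(is.data.frame(result), all(c("level", "jaccard") %in% names(result)))
  levels <- sort(unique(result$level))
  rows <- lapply(levels, function(lev) {
    x <- result$jaccard[result$level == lev]
    data.frame(level = lev, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               median = stats::median(x), min = min(x), max = max(x))
  })
  do.call(rbind, rows)
}
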