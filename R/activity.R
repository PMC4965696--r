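#' Compute per-gene case-exception counts and activity flags
#'
#' A gene's exception count is the number of cases in which its indicator
#' entry is 0; the gene is active when that count does not exceed the
#' resolved case-exception parameter L.  Genes present in the network but
#' absent from the matrix are maximally inactive (exception count =
#' number of cases).  Positive-list genes are forced to zero exceptions
#' and are therefore active for any L.
#'
#' @param matrix an [indicator_matrix()].
#' @param l resolved L as an integer case count (see [resolve_l()]).
#' @param positive character vector of always-active gene ids.
#' @param genes the gene universe to profile; defaults to the matrix's
#'   genes.  Pass the network's vertex names to cover unmeasured genes.
#' @return an `activity_profile`: data frame with columns `gene`,
#'   `exception_count`, `is_active`, plus attributes `n_cases` and `l`.
#' @export
compute_activity <- function(matrix, l, positive = character(0), genes = NULL) {
  n_cases <- ncol(matrix)
  l <- as.integer(l)
  stopifnot(l >= 0, l <= n_cases)
  if (is.null(genes)) genes <- rownames(matrix)
  genes <- unique(as.character(genes))
  exc <- rep.int(n_cases, length(genes))
  names(exc) <- genes
  measured <- intersect(genes, rownames(matrix))
  exc[measured] <- n_cases - rowSums(matrix[measured, , drop = FALSE])
  exc[intersect(genes, positive)] <- 0L
  out <- data.frame(gene = genes, exception_count = as.integer(exc),
                    is_active = exc <= l, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, n_cases = n_cases, l = l,
            class = c("activity_profile", "data.frame"))
}

# fast lookup helpers used by the extractors
activity_lookup <- function(activity) {
  list(exc = stats::setNames(activity$exception_count, activity$gene),
       active = stats::setNames(activity$is_active, activity$gene))
}
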