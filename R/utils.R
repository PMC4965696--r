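#' Round half away from zero
#'
#' Perturbation counts use conventional round-half-up rather than the IEEE
#' round-half-to-even of [base::round()], so that e.g. 25% of 10 items is 3.
#'
#' @param x numeric vector, assumed non-negative.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Stable FNV-1a-style string hash folded into the positive 31-bit integer
#' range, so that replicate streams do not shift when levels or strategies
#' are added to an analysis.
#'
#' @param master_seed integer master seed.
#' @param ... label components (strategy, level, replicate index, ...).
#' @return a single integer in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(master_seed, ..., sep = "\x1f")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 16777619 multiplication done in double precision, folded mod 2^31 - 1
    h <- (h * 16777619) %% (2^31 - 1)
  }
  as.integer(h %% (2^31 - 1)) + 1L
}

# Compare two sorted character tuples lexicographically; returns TRUE when
# `a` precedes `b`. Equal-length tuples only (callers compare equal sizes).
tuple_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# Canonical single-string key for a node set (tab never occurs in gene ids
# read by our parsers, so this preserves tuple order for sorting).
node_key <- function(nodes) paste(sort(nodes), collapse = "\t")

`%||%` <- function(x, y) if (is.null(x)) y else x
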