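#' Parse a dataset-combination logic formula
#'
#' Grammar: `id | expr AND expr | expr OR expr | (expr)`, where `AND` binds
#' tighter than `OR` and ids are dataset labels.  Negation is not part of
#' the model.  A single id is a valid formula.
#'
#' @param text the formula string, e.g. `"(D1 AND D2) OR D3"`.
#' @return a `logic_formula` expression tree: leaves are
#'   `list(op = "id", id = <label>)`, internal nodes
#'   `list(op = "AND"|"OR", args = list(...))`.
#' @examples
#' f <- parse_formula("D1 OR D2")
#' @export
parse_formula <- function(text) {
  tokens <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  if (length(tokens) == 0) stop("empty formula", call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L; tokens[pos - 1L] }

  parse_atom <- function() {
    tok <- peek()
    if (is.na(tok)) stop("unexpected end of formula", call. = FALSE)
    if (tok == "(") {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")"))
        stop("unbalanced parentheses in formula", call. = FALSE)
      advance()
      return(e)
    }
    if (tok %in% c(")", "AND", "OR"))
      stop("unexpected token '", tok, "' in formula", call. = FALSE)
    advance()
    list(op = "id", id = tok)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (identical(peek(), "AND")) { advance(); args <- c(args, list(parse_atom())) }
    if (length(args) == 1) args[[1]] else list(op = "AND", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "OR")) { advance(); args <- c(args, list(parse_and())) }
    if (length(args) == 1) args[[1]] else list(op = "OR", args = args)
  }

  tree <- parse_or()
  if (!is.na(peek()))
    stop("trailing token '", peek(), "' in formula", call. = FALSE)
  structure(tree, class = "logic_formula")
}

formula_leaves <- function(node) {
  if (node$op == "id") return(node$id)
  unique(unlist(lapply(node$args, formula_leaves)))
}

#' @export
print.logic_formula <- function(x, ...) {
  cat("<logic_formula>", deparse_formula(x), "\n")
  invisible(x)
}

deparse_formula <- function(node) {
  if (node$op == "id") return(node$id)
  parts <- vapply(node$args, deparse_formula, "")
  paste0("(", paste(parts, collapse = paste0(" ", node$op, " ")), ")")
}

#' Bundle indicator matrices with a combination formula
#'
#' @param matrices a list of [indicator_matrix()] objects with distinct
#'   dataset ids.
#' @param formula a [parse_formula()] result or formula string; defaults to
#'   the OR of all datasets.
#' @return a `dataset_collection` object.
#' @export
dataset_collection <- function(matrices, formula = NULL) {
  if (inherits(matrices, "indicator_matrix")) matrices <- list(matrices)
  ids <- vapply(matrices, attr, "", "dataset_id")
  if (anyDuplicated(ids))
    stop("duplicate dataset id(s): ", paste(unique(ids[duplicated(ids)]),
                                            collapse = ", "), call. = FALSE)
  if (is.null(formula)) formula <- paste(ids, collapse = " OR ")
  if (is.character(formula)) formula <- parse_formula(formula)
  unknown <- setdiff(formula_leaves(formula), ids)
  if (length(unknown))
    stop("formula references unknown dataset id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  names(matrices) <- ids
  structure(list(matrices = matrices, formula = formula),
            class = "dataset_collection")
}

#' Combine datasets into a single indicator matrix
#'
#' Case-aligned mode: all matrices must have the same number of cases and
#' are combined column-by-column (AND = conjunction, OR = disjunction).
#' The gene universe is the union of all gene ids; a gene missing from a
#' dataset contributes an all-zero row there, so AND is conservative.
#'
#' @param collection a [dataset_collection()].
#' @return an [indicator_matrix()] with dataset id `"combined"` (or the
#'   original id for a single dataset).
#' @export
combine_datasets <- function(collection) {
  stopifnot(inherits(collection, "dataset_collection"))
  mats <- collection$matrices
  ncases <- vapply(mats, ncol, 0L)
  if (length(unique(ncases)) > 1)
    stop("datasets have unequal case counts (", paste(ncases, collapse = ", "),
         "); only case-aligned combination is supported", call. = FALSE)
  genes <- unique(unlist(lapply(mats, rownames)))
  case_ids <- colnames(mats[[1]])
  padded <- lapply(mats, function(m) {
    out <- matrix(0L, length(genes), ncases[1], dimnames = list(genes, case_ids))
    out[rownames(m), ] <- m
    out
  })
  eval_node <- function(node) {
    if (node$op == "id") return(padded[[node$id]])
    vals <- lapply(node$args, eval_node)
    acc <- vals[[1]]
    for (v in vals[-1])
      acc <- if (node$op == "AND") acc * v else pmax(acc, v)
    acc
  }
  out_id <- if (length(mats) == 1) attr(mats[[1]], "dataset_id") else "combined"
  indicator_matrix(eval_node(collection$formula), out_id)
}

#' Specify the case-exception parameter L
#'
#' L bounds how many cases a gene may be inactive in and still count as
#' active (INES), or the total case-exception budget of a solution (GLONE).
#' It is given either as an absolute case count or as a percentage of the
#' number of cases, which is convenient when datasets differ in case count.
#'
#' @param value non-negative number: a case count, or a percentage in
#'   `[0, 100]` when `kind = "percent"`.  The string forms `"8"` and
#'   `"20%"` are also accepted (the `%` suffix selects percent).
#' @param kind `"absolute"` or `"percent"`.
#' @return an `l_spec` object.
#' @examples
#' l_spec("20%")
#' l_spec(8)
#' @export
l_spec <- function(value, kind = c("absolute", "percent")) {
  if (inherits(value, "l_spec")) return(value)
  if (is.character(value)) {
    value <- trimws(value)
    if (grepl("%$", value)) {
      kind <- "percent"
      value <- as.numeric(sub("%$", "", value))
    } else {
      kind <- if (identical(kind, c("absolute", "percent"))) "absolute"
              else match.arg(kind)
      value <- as.numeric(value)
    }
  } else kind <- match.arg(kind)
  if (is.na(value) || value < 0) stop("L must be non-negative", call. = FALSE)
  if (kind == "percent" && value > 100)
    stop("percentage L must not exceed 100", call. = FALSE)
  if (kind == "absolute" && value != floor(value))
    stop("absolute L must be an integer", call. = FALSE)
  structure(list(kind = kind, value = value), class = "l_spec")
}

#' @export
print.l_spec <- function(x, ...) {
  cat("<l_spec>", if (x$kind == "percent") paste0(x$value, "%")
      else paste(x$value, "cases"), "\n")
  invisible(x)
}

#' Resolve an L specification to a case count
#'
#' Percentages are resolved as `ceiling(p/100 * n_cases)`; absolute values
#' exceeding the case count are capped with a warning.
#'
#' @param spec an [l_spec()] (or value coercible by `l_spec()`).
#' @param n_cases number of cases (>= 1).
#' @return an integer case count in `[0, n_cases]`.
#' @examples
#' resolve_l(l_spec("25%"), 32) # 8
#' resolve_l(l_spec("20%"), 38) # ceiling(7.6) = 8
#' @export
resolve_l <- function(spec, n_cases) {
  spec <- l_spec(spec)
  stopifnot(n_cases >= 1)
  if (spec$kind == "percent") {
    as.integer(ceiling(spec$value / 100 * n_cases))
  } else {
    if (spec$value > n_cases) {
      warning(sprintf("L = %d exceeds the %d available cases; capped",
                      as.integer(spec$value), as.integer(n_cases)),
              call. = FALSE)
      as.integer(n_cases)
    } else as.integer(spec$value)
  }
}

# GLONE's global case-exception budget: percentages resolve against the
# case count as in resolve_l, but an absolute budget is a total over all
# solution genes and may legitimately exceed the case count, so it is not
# capped.
glone_budget <- function(spec, n_cases) {
  spec <- l_spec(spec)
  if (spec$kind == "percent") resolve_l(spec, n_cases)
  else as.integer(spec$value)
}
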