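#' Construct an indicator matrix
#'
#' A genes-by-cases binary table; entry 1 marks a case in which the gene is
#' "active" (e.g. differentially expressed), 0 otherwise.
#'
#' @param values numeric/integer matrix of 0/1 entries with row names
#'   (gene ids); column names (case ids) generated as `c1..cn` when absent.
#' @param dataset_id a short label identifying the dataset.
#' @return an object of class `indicator_matrix` (a 0/1 integer matrix with
#'   a `dataset_id` attribute).
#' @export
indicator_matrix <- function(values, dataset_id = "D1") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("indicator matrix requires gene ids as row names", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  storage.mode(values) <- "integer"
  bad <- which(!(values %in% c(0L, 1L)) | is.na(values))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf("non-binary entry at gene '%s', case '%s'",
                 rownames(values)[i], colnames(values)[j]), call. = FALSE)
  }
  structure(values, dataset_id = as.character(dataset_id),
            class = c("indicator_matrix", class(values)))
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("<indicator_matrix '%s': %d genes x %d cases, %d active entries>\n",
              attr(x, "dataset_id"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Read an indicator matrix from TSV
#'
#' Expected layout: first column gene id, remaining columns 0/1 entries.
#' A header row is auto-detected: the first row is treated as a header iff
#' any of its non-first fields is not `"0"`/`"1"`; otherwise case ids are
#' generated as `c1..cn`.
#'
#' @param source file path or character vector of lines.
#' @param dataset_id label for the dataset (defaults to the file base name).
#' @return an [indicator_matrix()].
#' @export
read_indicator_matrix <- function(source, dataset_id = NULL) {
  from_file <- length(source) == 1 && file.exists(source)
  if (is.null(dataset_id))
    dataset_id <- if (from_file) sub("\\.[^.]*$", "", basename(source)) else "D1"
  lines <- if (from_file) readLines(source) else source
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty indicator matrix", call. = FALSE)
  rows <- strsplit(lines, "\t", fixed = TRUE)

  first <- rows[[1]]
  # a header needs at least one data row below it; a lone non-binary row is
  # a data error, not a header
  has_header <- length(rows) > 1 && length(first) > 1 &&
    !all(first[-1] %in% c("0", "1"))
  case_ids <- NULL
  if (has_header) {
    case_ids <- first[-1]
    rows <- rows[-1]
    if (length(rows) == 0) stop("indicator matrix has a header but no rows",
                                call. = FALSE)
  }
  ncase <- length(rows[[1]]) - 1
  if (ncase < 1) stop("indicator matrix rows need at least one case column",
                      call. = FALSE)
  if (is.null(case_ids)) case_ids <- paste0("c", seq_len(ncase))
  genes <- vapply(rows, `[`, "", 1)
  vals <- matrix(0L, nrow = length(rows), ncol = ncase,
                 dimnames = list(genes, case_ids))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) - 1 != ncase)
      stop(sprintf("ragged row for gene '%s': expected %d case entries, got %d",
                   r[1], ncase, length(r) - 1), call. = FALSE)
    ent <- r[-1]
    bad <- which(!ent %in% c("0", "1"))
    if (length(bad))
      stop(sprintf("non-binary entry '%s' at gene '%s', case '%s'",
                   ent[bad[1]], r[1], case_ids[bad[1]]), call. = FALSE)
    vals[i, ] <- as.integer(ent)
  }
  indicator_matrix(vals, dataset_id)
}

#' Write an indicator matrix as TSV (with header row)
#' @param x an [indicator_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_indicator_matrix <- function(x, path) {
  lines <- c(paste(c("id", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)),
                    function(i) paste(c(rownames(x)[i], x[i, ]), collapse = "\t"),
                    ""))
  writeLines(lines, path)
  invisible(path)
}

#' Threshold a p-value matrix into an indicator matrix
#'
#' An entry becomes 1 iff its p-value is strictly below the cutoff
#' (`p < cutoff`; a p-value exactly at the cutoff is not significant).
#'
#' @param pmatrix numeric genes-by-cases matrix of p-values in `[0, 1]`,
#'   with gene ids as row names.
#' @param cutoff significance cutoff in `(0, 1)`; default 0.05.
#' @param dataset_id label for the resulting dataset.
#' @return an [indicator_matrix()].
#' @export
pvalues_to_indicator <- function(pmatrix, cutoff = 0.05, dataset_id = "D1") {
  pmatrix <- as.matrix(pmatrix)
  if (any(is.na(pmatrix)) || any(pmatrix < 0) || any(pmatrix > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (!(cutoff > 0 && cutoff < 1))
    stop("cutoff must lie in (0, 1)", call. = FALSE)
  indicator_matrix(ifelse(pmatrix < cutoff, 1L, 0L), dataset_id)
}
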