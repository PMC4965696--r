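#' Read an undirected interaction network
#'
#' Networks are modelled as simple undirected [igraph] graphs with unique
#' character vertex names (gene identifiers).  Self-loops are dropped with a
#' warning and duplicate edges (as unordered pairs) are collapsed, since the
#' module-cover model is blind to direction and multiplicity.
#'
#' @param source a file path, or a character vector of lines (for `"sif"`
#'   and `"tsv"`; `"graphml"` requires a path).
#' @param dialect one of `"tsv"` (two tab-separated identifier columns),
#'   `"sif"` (three whitespace-separated columns, the middle interaction
#'   type is ignored), or `"graphml"` (Cytoscape interop, via igraph).
#' @return an undirected simple igraph object with vertex names.
#' @examples
#' g <- read_network(c("A\tB", "B\tC"), dialect = "tsv")
#' igraph::vcount(g) # 3
#' @export
read_network <- function(source, dialect = c("tsv", "sif", "graphml")) {
  dialect <- match.arg(dialect)
  if (dialect == "graphml") {
    if (!(is.character(source) && length(source) == 1 && file.exists(source)))
      stop("graphml networks must be read from a file path", call. = FALSE)
    g <- igraph::read_graph(source, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    if (is.null(igraph::V(g)$name))
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    return(as_network(igraph::as_edgelist(g), igraph::V(g)$name))
  }
  lines <- if (length(source) == 1 && file.exists(source)) readLines(source) else source
  lines_raw <- lines
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("empty network file", call. = FALSE)

  edges <- matrix(character(0), ncol = 2)
  singletons <- character(0)
  for (i in seq_along(lines)) {
    fields <- if (dialect == "tsv") strsplit(lines[i], "\t", fixed = TRUE)[[1]]
              else strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    fields <- fields[nzchar(fields)]
    if (dialect == "tsv") {
      if (length(fields) != 2)
        stop(sprintf("malformed TSV edge at line %d: expected 2 fields, got %d",
                     lineno[i], length(fields)), call. = FALSE)
      edges <- rbind(edges, fields)
    } else {
      # SIF permits "A" alone (isolated node) or "A type B [C ...]"
      if (length(fields) == 1) {
        singletons <- c(singletons, fields)
      } else if (length(fields) >= 3) {
        for (tgt in fields[3:length(fields)]) edges <- rbind(edges, c(fields[1], tgt))
      } else {
        stop(sprintf("malformed SIF line %d: expected 1 or >=3 fields, got 2",
                     lineno[i]), call. = FALSE)
      }
    }
  }
  as_network(edges, unique(c(as.vector(t(edges)), singletons)))
}

# Build the canonical simple undirected graph from an edge matrix and the
# full node set (which may include isolated nodes).
as_network <- function(edges, nodes) {
  nodes <- unique(as.character(nodes))
  edges <- matrix(as.character(edges), ncol = 2)
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s): %s", sum(loops),
                    paste(unique(edges[loops, 1]), collapse = ", ")),
            call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network in a supported dialect
#'
#' @param network an igraph object with vertex names.
#' @param path output file path.
#' @param dialect `"tsv"`, `"sif"`, or `"graphml"`.
#' @param sif_type interaction type written in the middle SIF column.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, dialect = c("tsv", "sif", "graphml"),
                          sif_type = "pp") {
  dialect <- match.arg(dialect)
  if (dialect == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(network)
  iso <- setdiff(igraph::V(network)$name, as.vector(el))
  if (dialect == "tsv") {
    # the 2-column dialect cannot declare isolated nodes
    if (length(iso))
      warning(sprintf("%d isolated node(s) not representable in TSV dialect",
                      length(iso)), call. = FALSE)
    lines <- paste(el[, 1], el[, 2], sep = "\t")
  } else {
    lines <- c(paste(el[, 1], sif_type, el[, 2]), iso)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene list (one identifier per line, '#' comments allowed)
#'
#' @param source file path or character vector of lines.
#' @return character vector of identifiers.
#' @export
read_gene_list <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source)) readLines(source) else source
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

#' Apply positive and negative gene lists to a network
#'
#' Negative-list genes are excluded from the analysis: they and their
#' incident edges are removed from the network.  Positive-list genes are
#' always considered active regardless of the indicator matrix; they are
#' recorded in the graph attribute `positive` consumed by
#' [compute_activity()].
#'
#' @param network igraph network.
#' @param positive,negative character vectors of gene identifiers; ids not
#'   present in the network are ignored with a warning.
#' @return the filtered igraph network, with graph attribute `positive`.
#' @export
apply_node_lists <- function(network, positive = character(0),
                             negative = character(0)) {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  both <- intersect(positive, negative)
  if (length(both))
    stop("gene(s) in both the positive and negative list: ",
         paste(both, collapse = ", "), call. = FALSE)
  known <- igraph::V(network)$name
  missing <- setdiff(c(positive, negative), known)
  if (length(missing))
    warning("list gene(s) absent from the network ignored: ",
            paste(missing, collapse = ", "), call. = FALSE)
  out <- igraph::delete_vertices(network, intersect(negative, known))
  igraph::graph_attr(out, "positive") <- intersect(positive, known)
  out
}
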