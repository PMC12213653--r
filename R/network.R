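#' Read a protein-protein interaction network from text
#'
#' Accepts a plain two-column edge list (optionally with extra columns,
#' which are ignored) or Cytoscape SIF, where each line
#' `source <type> target1 [target2 ...]` fans out to one edge per target.
#' The result is a simple undirected graph: self-loops are dropped and
#' duplicate edges (in either orientation) collapsed; the number of
#' records removed is stored in the graph attributes `dropped_self_loops`
#' and `dropped_duplicates`.
#'
#' @param path Path to the network file.
#' @param dialect `"edge_list"` (default) or `"sif"`.
#' @return An undirected simple [igraph::graph] over gene identifiers.
#' @export
read_network <- function(path, dialect = c("edge_list", "sif")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    stop("network file is empty: ", path)
  from <- character(0); to <- character(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (dialect == "edge_list") {
      if (length(tok) < 2)
        stop("line ", i, ": expected two columns, got ", length(tok))
      from <- c(from, tok[1]); to <- c(to, tok[2])
    } else {
      if (length(tok) == 1)
        stop("line ", i, ": SIF line with a bare node and no interaction")
      if (length(tok) < 3)
        stop("line ", i, ": SIF line needs source, type, target")
      from <- c(from, rep(tok[1], length(tok) - 2L))
      to <- c(to, tok[-(1:2)])
    }
  }
  n_records <- length(from)
  self <- from == to
  n_self <- sum(self)
  from <- from[!self]; to <- to[!self]
  # canonical orientation so a-b and b-a collapse
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dupd <- duplicated(key)
  n_dup <- sum(dupd)
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[!dupd], to = b[!dupd], stringsAsFactors = FALSE),
    directed = FALSE
  )
  g <- igraph::set_graph_attr(g, "dropped_self_loops", n_self)
  g <- igraph::set_graph_attr(g, "dropped_duplicates", n_dup)
  g <- igraph::set_graph_attr(g, "n_records", n_records)
  g
}

#' Write an edge list to TSV
#' @param network An undirected igraph.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
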