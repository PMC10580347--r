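#' Build an interaction network from an edge table
#'
#' Constructs an undirected, unweighted gene-gene interaction network from a
#' two-column edge table. Self-loops and duplicate edges (in either
#' orientation) are dropped; gene symbols are case-sensitive strings matched
#' exactly.
#'
#' @param edges A data frame whose first two columns are gene symbols, one
#'   interaction per row. Extra columns are ignored.
#' @param quiet Suppress the message reporting node/edge totals and dropped
#'   rows.
#'
#' @return An `interaction_network` object wrapping an [igraph] graph, with
#'   attributes recording how many self-loops and duplicate edges were
#'   removed.
#' @examples
#' net <- interaction_network(data.frame(a = c("A", "B", "B"),
#'                                       b = c("B", "C", "C")))
#' network_degree(net, "B")
#' @export
interaction_network <- function(edges, quiet = FALSE) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) {
    stop("`edges` must have at least two columns (gene_a, gene_b)",
         call. = FALSE)
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  keep <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0L) stop("no valid edges in input", call. = FALSE)

  self <- a == b
  n_self <- sum(self)
  loop_nodes <- unique(a[self])  # a self-loop still registers its node
  a2 <- a[!self]
  b2 <- b[!self]

  # canonical unordered orientation so (x,y) and (y,x) collapse together
  lo <- pmin(a2, b2)
  hi <- pmax(a2, b2)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)

  nodes <- unique(c(lo, hi, loop_nodes))
  if (length(nodes) == 0L) stop("no valid edges in input", call. = FALSE)

  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[!dup], to = hi[!dup], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )

  if (!quiet) {
    message(sprintf(
      "interaction_network: %d nodes, %d edges (%d self-loop(s), %d duplicate edge(s) dropped)",
      igraph::vcount(g), igraph::ecount(g), n_self, n_dup
    ))
  }
  structure(
    list(graph = g, n_self_loops_dropped = n_self,
         n_duplicates_dropped = n_dup),
    class = "interaction_network"
  )
}

#' Read an interaction network from a TSV edge list
#'
#' Reads a tab/whitespace-separated two-column edge list. A header row is
#' auto-detected: when both fields of the first row match `header_names`
#' (case-insensitively) the row is skipped.
#'
#' @param path Path to the edge-list file.
#' @param header_names Field names that identify a header row.
#' @inheritParams interaction_network
#' @return An `interaction_network`.
#' @export
read_network_tsv <- function(path,
                             header_names = c("gene_a", "gene_b", "from", "to",
                                              "source", "target", "gene1", "gene2"),
                             quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty edge-list file: ", path, call. = FALSE)
  fields <- strsplit(lines, "[\t ]+")
  bad <- vapply(fields, length, 1L) < 2L
  if (all(bad)) stop("no rows with two fields in ", path, call. = FALSE)
  fields <- fields[!bad]
  first <- tolower(fields[[1]][1:2])
  if (all(first %in% tolower(header_names))) fields <- fields[-1]
  if (length(fields) == 0L) stop("no data rows in ", path, call. = FALSE)
  edges <- data.frame(
    gene_a = vapply(fields, `[[`, "", 1L),
    gene_b = vapply(fields, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
  interaction_network(edges, quiet = quiet)
}

#' Read a gene set (one symbol per line, `#` comments allowed)
#'
#' @param path Path to the gene-list file.
#' @return A character vector of unique gene symbols.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Network accessors
#'
#' `network_nodes()` returns all gene symbols; `network_degree()` the number
#' of distinct neighbours of each queried node; `network_distance()` the
#' unweighted shortest-path length between node sets. Unreachable pairs are
#' reported as `NA` (a sentinel, never a large finite stand-in), so callers
#' must handle disconnection explicitly.
#'
#' @param net An `interaction_network`.
#' @param nodes,from,to Character vectors of gene symbols; querying a symbol
#'   absent from the network is an error naming it.
#' @return `network_nodes()`: character vector. `network_degree()`: named
#'   integer vector. `network_distance()`: numeric matrix of
#'   `length(from) x length(to)` hop counts with `NA` for disconnected pairs;
#'   a single scalar when both `from` and `to` have length one.
#' @examples
#' net <- interaction_network(data.frame(a = c("A", "B"), b = c("B", "C")),
#'                            quiet = TRUE)
#' network_distance(net, "A", "C")  # 2
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  igraph::V(net$graph)$name
}

.check_nodes <- function(net, nodes, arg = "nodes") {
  missing <- setdiff(nodes, network_nodes(net))
  if (length(missing) > 0L) {
    stop(sprintf("unknown node(s) in `%s`: %s", arg,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' @rdname network_nodes
#' @export
network_degree <- function(net, nodes = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  if (is.null(nodes)) nodes <- network_nodes(net)
  .check_nodes(net, nodes)
  deg <- igraph::degree(net$graph, v = nodes, loops = FALSE)
  storage.mode(deg) <- "integer"
  deg
}

#' @rdname network_nodes
#' @export
network_distance <- function(net, from, to) {
  stopifnot(inherits(net, "interaction_network"))
  .check_nodes(net, from, "from")
  .check_nodes(net, to, "to")
  d <- igraph::distances(net$graph, v = from, to = to)
  d[is.infinite(d)] <- NA_real_
  if (length(from) == 1L && length(to) == 1L) unname(d[1, 1]) else d
}
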