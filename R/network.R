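#' Construct a PPI network from an edge table
#'
#' A `ppi_network` is a labeled, simple, undirected graph: an ordered vector
#' of unique node labels plus a deduplicated set of unordered edges.
#' Self-loops are dropped (with a warning), reciprocal duplicates are stored
#' once, and node order is first-appearance order in the input (so the same
#' file always yields the same matrix layout downstream).
#'
#' @param edges A data frame whose first two columns are the interacting
#'   protein labels (character). Extra columns are ignored.
#' @param nodes Optional character vector of node labels. Labels seen in
#'   `edges` but absent here are appended in first-appearance order; use this
#'   to keep isolated proteins in the network.
#' @return An object of class `ppi_network` with elements `nodes` (character)
#'   and `edges` (a tibble with columns `from`, `to`, canonically ordered).
#' @examples
#' ppi_network(data.frame(a = c("u1", "u2"), b = c("u2", "u3")))
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) {
    abort("`edges` must have at least two columns (interacting labels).")
  }
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  if (anyNA(from) || anyNA(to)) abort("edge labels must not be NA")

  loops <- from == to
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop(s)", sum(loops)))
    from <- from[!loops]
    to <- to[!loops]
  }
  # canonical unordered storage: lexicographically smaller label first
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[keep]
  hi <- hi[keep]

  seen <- unique(c(nodes, as.vector(rbind(from, to))))
  new_ppi_network(seen, tibble(from = lo, to = hi))
}

new_ppi_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' Coerce to a `ppi_network`
#'
#' @param x A `ppi_network`, or a data frame of edges (first two columns are
#'   the endpoint labels).
#' @param ... Passed on to [ppi_network()].
#' @return A `ppi_network`.
#' @export
as_ppi_network <- function(x, ...) UseMethod("as_ppi_network")

#' @export
as_ppi_network.ppi_network <- function(x, ...) x

#' @export
as_ppi_network.data.frame <- function(x, ...) ppi_network(x, ...)

#' @export
as_ppi_network.default <- function(x, ...) {
  abort("cannot coerce this object to a ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<ppi_network> %d nodes, %d edges (%d connected component%s)\n",
    length(x$nodes), nrow(x$edges), n_components(x),
    if (n_components(x) == 1L) "" else "s"
  ))
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

# 0/1 symmetric sparse adjacency in the network's node order
adjacency_matrix <- function(net) {
  n <- n_nodes(net)
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  sparseMatrix(
    i = c(i, j), j = c(j, i), x = 1,
    dims = c(n, n), dimnames = list(net$nodes, net$nodes)
  )
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
}

n_components <- function(net) {
  if (n_nodes(net) == 0L) return(0L)
  igraph::count_components(as_igraph(net))
}
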