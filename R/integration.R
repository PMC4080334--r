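#' Normalize raw BLAST bit scores to \[0, 1\]
#'
#' Cross-network similarity uses the geometric-mean normalization
#' `cross / sqrt(self_u * self_v)`, where `self_u = BLAST(u, u)` and
#' `self_v = BLAST(v, v)` are the self-alignment bit scores. This is the
#' standard convention that keeps scores in \[0, 1\] and makes a protein's
#' similarity to itself exactly 1. Values that land numerically above 1 are
#' clamped with a warning.
#'
#' @param cross Raw bit score(s) for the cross pair(s), `>= 0`.
#' @param self_u,self_v Self-alignment bit scores, `> 0`. Recycled.
#' @return Numeric vector of scores in \[0, 1\].
#' @examples
#' normalize_bit_scores(100, 100, 400) # 0.5
#' @export
normalize_bit_scores <- function(cross, self_u, self_v) {
  if (any(self_u <= 0) || any(self_v <= 0)) {
    abort("self bit scores must be positive")
  }
  if (any(cross < 0)) abort("cross bit scores must be nonnegative")
  s <- as.numeric(cross / sqrt(self_u * self_v))
  if (any(s > 1)) {
    warn(sprintf("%d normalized score(s) above 1 clamped to 1", sum(s > 1)))
    s[s > 1] <- 1
  }
  s
}

#' Build the integrated two-network graph
#'
#' The integrated network places the first network's proteins at indices
#' `1..N1` and the second network's at `N1+1..N` (`N = N1 + N2`). Its
#' topology matrix `A` is the block diagonal of the two adjacency matrices
#' (no cross-network topological edges), and its homology matrix `S` holds
#' the similarity scores symmetrically in the two off-diagonal blocks.
#' Identical labels may occur in both networks (same-species joint
#' clustering); nodes are namespaced internally as `"1:label"` / `"2:label"`
#' and output writers report the original labels.
#'
#' @param net1,net2 The two networks ([ppi_network()] or edge data frames).
#' @param sim Cross-network similarity: a data frame with columns
#'   `node1` (in `net1`), `node2` (in `net2`), `score` in \[0, 1\], e.g. from
#'   [read_similarity()]. `NULL` means no homology information.
#' @return An object of class `integrated_network`: `node_order` (namespaced
#'   ids), `labels` (original), `network` (1/2 per node), `n1`, `n2`,
#'   `A` and `S` (sparse N x N matrices).
#' @export
build_integrated <- function(net1, net2, sim = NULL) {
  net1 <- as_ppi_network(net1)
  net2 <- as_ppi_network(net2)
  if (n_nodes(net1) == 0L || n_nodes(net2) == 0L) {
    abort("both networks must be non-empty")
  }
  n1 <- n_nodes(net1)
  n2 <- n_nodes(net2)
  n <- n1 + n2

  A <- bdiag(adjacency_matrix(net1), adjacency_matrix(net2))
  A <- methods::as(A, "CsparseMatrix")

  if (is.null(sim) || nrow(as.data.frame(sim)) == 0L) {
    S <- sparseMatrix(i = integer(), j = integer(), x = numeric(), dims = c(n, n))
  } else {
    sim <- as.data.frame(sim)
    if (ncol(sim) < 3) abort("`sim` needs columns node1, node2, score")
    u <- as.character(sim[[1]])
    v <- as.character(sim[[2]])
    s <- as.numeric(sim[[3]])
    i <- match(u, net1$nodes)
    j <- match(v, net2$nodes)
    if (anyNA(i)) {
      abort(sprintf("similarity label '%s' not in network 1", u[which(is.na(i))[1]]))
    }
    if (anyNA(j)) {
      abort(sprintf("similarity label '%s' not in network 2", v[which(is.na(j))[1]]))
    }
    if (any(s < 0 | s > 1)) abort("similarity scores must lie in [0, 1]")
    key <- paste(i, j)
    if (anyDuplicated(key)) {
      warn("duplicate similarity pairs: keeping the maximum score")
      s <- as.numeric(tapply(s, key, max)[unique(key)])
      first <- !duplicated(key)
      i <- i[first]
      j <- j[first]
    }
    keep <- s > 0
    i <- i[keep]
    j <- j[keep]
    s <- s[keep]
    S <- sparseMatrix(
      i = c(i, n1 + j), j = c(n1 + j, i), x = c(s, s), dims = c(n, n)
    )
  }

  structure(
    list(
      node_order = c(paste0("1:", net1$nodes), paste0("2:", net2$nodes)),
      labels = c(net1$nodes, net2$nodes),
      network = rep(1:2, c(n1, n2)),
      n1 = n1, n2 = n2,
      A = A, S = methods::as(S, "CsparseMatrix")
    ),
    class = "integrated_network"
  )
}

#' @export
print.integrated_network <- function(x, ...) {
  cat(sprintf(
    "<integrated_network> N = %d (%d + %d), %d topological edges, %d homological links\n",
    x$n1 + x$n2, x$n1, x$n2, sum(x$A) / 2, Matrix::nnzero(x$S) / 2
  ))
  invisible(x)
}
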