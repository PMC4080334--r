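#' Joint clustering of two PPI networks (ASModel)
#'
#' End-to-end pipeline: build the integrated network
#' ([build_integrated()]), derive the alternating-random-walk transition
#' matrix ([build_transition()]), compute its stationary distribution,
#' symmetrize into the equivalent undirected weight matrix, and find k
#' low-conductance sets spectrally ([spectral_partition()]). Every protein
#' of both networks receives exactly one cluster label, so clusters may mix
#' proteins from both networks — that is the point: homologous regions of
#' the two networks are pulled into common clusters.
#'
#' @param net1,net2 The two networks ([ppi_network()] or edge data frames).
#' @param sim Cross-network similarity table (`node1`, `node2`, `score` in
#'   \[0, 1\]), e.g. from [read_similarity()]; `NULL` for no homology, in
#'   which case the walker can never cross networks and clusters stay
#'   within one network.
#' @param k Number of clusters.
#' @param seed Integer seed (k-means restarts).
#' @param keep_model Keep the integrated network and transition model on the
#'   returned object (for inspection; costs memory).
#' @return An object of class `asmodel_fit` with elements `assignment`
#'   (tibble: `node`, `network`, `cluster`), `k`, `seed`, `pi`,
#'   `objective` (total conductance of the partition), `method`, and
#'   cluster-level `summary`. Use [tidy()] / [glance()] to extract tidy
#'   tables and [write_clusters()] to export.
#' @examples
#' pair <- generate_pair(synthetic_pair_config(
#'   modules1 = c(6, 6), modules2 = c(8, 8),
#'   edge_density = 0.9, sim_density = 0.4
#' ), seed = 1)
#' fit <- suppressWarnings(asmodel(pair$net1, pair$net2, pair$sim, k = 2))
#' glance(fit)
#' @export
asmodel <- function(net1, net2, sim = NULL, k, seed = 1L, keep_model = FALSE) {
  M <- build_integrated(net1, net2, sim)
  tm <- build_transition(M, keep_intermediates = keep_model)
  part <- partition_chain(tm$P, k = k, seed = seed)
  assignment <- tibble(
    node = M$labels,
    network = M$network,
    cluster = part$labels
  )
  structure(
    list(
      assignment = assignment,
      k = as.integer(k),
      seed = as.integer(seed),
      pi = part$pi,
      objective = part$objective,
      method = "asmodel",
      n1 = M$n1, n2 = M$n2,
      model = if (keep_model) list(integrated = M, transition = tm, sym = part$sym)
    ),
    class = "asmodel_fit"
  )
}

#' Single-network normalized-cut baseline
#'
#' The same low-conductance machinery applied to one network alone: the
#' chain is the simple random walk `P = D^{-1} A` on the network's own
#' adjacency matrix, and the identical stationary/symmetrize/spectral
#' pipeline finds k low-conductance sets. This is the NCut baseline the
#' joint model is compared against.
#'
#' @param net A [ppi_network()] or edge data frame.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return An `asmodel_fit` with `method = "ncut"` (the `network` column is
#'   all 1).
#' @export
ncut_single <- function(net, k, seed = 1L) {
  net <- as_ppi_network(net)
  if (n_nodes(net) == 0L) abort("network must be non-empty")
  P <- row_stochastic(adjacency_matrix(net), "self_loop")
  if (length(attr(P, "fallback_rows")) > 0) {
    warn(sprintf(
      "%d isolated node(s): self-loop fallback applied",
      length(attr(P, "fallback_rows"))
    ))
  }
  part <- partition_chain(P, k = k, seed = seed)
  structure(
    list(
      assignment = tibble(
        node = net$nodes,
        network = rep(1L, n_nodes(net)),
        cluster = part$labels
      ),
      k = as.integer(k),
      seed = as.integer(seed),
      pi = part$pi,
      objective = part$objective,
      method = "ncut",
      n1 = n_nodes(net), n2 = 0L,
      model = NULL
    ),
    class = "asmodel_fit"
  )
}

#' Project joint clusters onto one constituent network
#'
#' Restricts every cluster to the chosen network's proteins and drops the
#' restrictions smaller than `min_size` (cluster size >= 2 by default, the
#' convention under which cluster counts and coverage are reported). The
#' coverage is the number of that network's proteins contained in the
#' retained clusters.
#'
#' @param fit An `asmodel_fit` (or a data frame with `node`, `network`,
#'   `cluster` columns).
#' @param which Which network to project onto, `1` or `2`.
#' @param min_size Minimum retained cluster size.
#' @return List with `clusters` (named list of label vectors, names are
#'   cluster ids) and `coverage` (integer).
#' @export
project_clusters <- function(fit, which = 1, min_size = 2L) {
  assignment <- if (inherits(fit, "asmodel_fit")) fit$assignment else as_tibble(fit)
  if (!which %in% assignment$network) {
    return(list(clusters = list(), coverage = 0L))
  }
  sub <- assignment[assignment$network == which, ]
  clusters <- split(sub$node, sub$cluster)
  clusters <- clusters[lengths(clusters) >= min_size]
  list(clusters = clusters, coverage = sum(lengths(clusters)))
}

#' @export
print.asmodel_fit <- function(x, ...) {
  nc <- length(unique(x$assignment$cluster))
  cat(sprintf(
    "<asmodel_fit> method = %s, %d nodes, k = %d (%d non-empty clusters)\n",
    x$method, nrow(x$assignment), x$k, nc
  ))
  cat(sprintf("  total conductance: %.4f\n", x$objective))
  invisible(x)
}

#' @describeIn asmodel Per-node tidy table: one row per protein with its
#'   network of origin and cluster label.
#' @param x An `asmodel_fit`.
#' @param ... Unused.
#' @export
tidy.asmodel_fit <- function(x, ...) {
  x$assignment
}

#' @describeIn asmodel One-row model summary: node counts, requested and
#'   realized cluster counts, total conductance.
#' @export
glance.asmodel_fit <- function(x, ...) {
  tibble(
    method = x$method,
    n_nodes = nrow(x$assignment),
    n1 = x$n1,
    n2 = x$n2,
    k = x$k,
    n_clusters = length(unique(x$assignment$cluster)),
    objective = x$objective
  )
}

#' @describeIn asmodel Stacked bar chart of cluster sizes, colored by the
#'   network of origin of the member proteins.
#' @param object An `asmodel_fit`.
#' @export
autoplot.asmodel_fit <- function(object, ...) {
  dat <- dplyr::count(object$assignment, .data$cluster, .data$network)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$cluster), y = .data$n, fill = factor(.data$network)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "cluster", y = "proteins", fill = "network",
      title = sprintf("Cluster composition (%s)", object$method)
    )
}
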