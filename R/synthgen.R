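#' Configuration for a planted-module synthetic network pair
#'
#' The defaults are the benchmark's study conditions: network 1 has 4
#' modules of 24 nodes, network 2 has 4 modules of 36 nodes, within-module
#' edge density 0.5, and cross-network similarity density 0.2 between
#' corresponding ("orthologous") module pairs. No between-module edges
#' exist before rewiring; noise is injected by Maslov–Sneppen
#' degree-preserving rewiring of a given fraction of both the interaction
#' edges (per network) and the similarity pairs.
#'
#' @param modules1,modules2 Integer vectors of module sizes (equal length;
#'   position pairs are orthologous).
#' @param edge_density Within-module edge probability in \[0, 1\].
#' @param sim_density Fraction of node pairs within each orthologous module
#'   pair that receive a similarity link (exact count, sampled without
#'   replacement).
#' @param noise Fraction of edges rewired, in \[0, 1\].
#' @return A `synthetic_pair_config`.
#' @export
synthetic_pair_config <- function(modules1 = rep(24L, 4),
                                  modules2 = rep(36L, 4),
                                  edge_density = 0.5,
                                  sim_density = 0.2,
                                  noise = 0) {
  modules1 <- as.integer(modules1)
  modules2 <- as.integer(modules2)
  if (length(modules1) != length(modules2)) {
    abort("`modules1` and `modules2` must have the same number of modules")
  }
  if (any(modules1 < 2L) || any(modules2 < 2L)) {
    abort("every module must have at least 2 nodes")
  }
  if (edge_density < 0 || edge_density > 1) abort("`edge_density` must be in [0, 1]")
  if (sim_density < 0 || sim_density > 1) abort("`sim_density` must be in [0, 1]")
  if (noise < 0 || noise > 1) abort("`noise` must be in [0, 1]")
  structure(
    list(
      modules1 = modules1, modules2 = modules2,
      edge_density = edge_density, sim_density = sim_density, noise = noise
    ),
    class = "synthetic_pair_config"
  )
}

#' @export
print.synthetic_pair_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_pair_config> modules %s / %s, edge density %g, similarity density %g, noise %g\n",
    paste(x$modules1, collapse = "+"), paste(x$modules2, collapse = "+"),
    x$edge_density, x$sim_density, x$noise
  ))
  invisible(x)
}

module_labels <- function(sizes, prefix) {
  sprintf("%s%03d", prefix, seq_len(sum(sizes)))
}

# independent Bernoulli(density) edges within each module; no edges between
sample_module_edges <- function(sizes, labels, density) {
  offsets <- cumsum(c(0L, sizes))
  from <- character(0)
  to <- character(0)
  for (p in seq_along(sizes)) {
    idx <- offsets[p] + seq_len(sizes[p])
    pairs <- utils::combn(labels[idx], 2)
    keep <- rbinom(ncol(pairs), 1L, density) == 1L
    from <- c(from, pairs[1, keep])
    to <- c(to, pairs[2, keep])
  }
  tibble(from = from, to = to)
}

#' Generate a synthetic network pair with planted modules
#'
#' Within each module, each node pair becomes an edge independently with
#' probability `edge_density`. Between corresponding modules across the two
#' networks, exactly `round(sim_density * size1 * size2)` node pairs are
#' sampled without replacement and given similarity score 1. Finally,
#' [rewire()] permutes `noise` of each network's interaction edges and,
#' independently, `noise` of the similarity pairs (side-preserving
#' bipartite swaps). The same config and seed always reproduce the same
#' pair.
#'
#' @param config A [synthetic_pair_config()].
#' @param seed Integer seed.
#' @return A `synthetic_pair`: `net1`, `net2` ([ppi_network()], isolated
#'   nodes retained), `sim` (tibble `node1`, `node2`, `score`),
#'   `truth1`, `truth2` (tibbles `node`, `module`), and `config`.
#' @export
generate_pair <- function(config, seed = 1L) {
  if (!inherits(config, "synthetic_pair_config")) {
    abort("`config` must be a synthetic_pair_config")
  }
  withr::with_seed(as.integer(seed), {
    labels1 <- module_labels(config$modules1, "u")
    labels2 <- module_labels(config$modules2, "v")
    truth1 <- tibble(node = labels1, module = rep(seq_along(config$modules1), config$modules1))
    truth2 <- tibble(node = labels2, module = rep(seq_along(config$modules2), config$modules2))

    edges1 <- sample_module_edges(config$modules1, labels1, config$edge_density)
    edges2 <- sample_module_edges(config$modules2, labels2, config$edge_density)

    off1 <- cumsum(c(0L, config$modules1))
    off2 <- cumsum(c(0L, config$modules2))
    sim_from <- character(0)
    sim_to <- character(0)
    for (p in seq_along(config$modules1)) {
      u <- labels1[off1[p] + seq_len(config$modules1[p])]
      v <- labels2[off2[p] + seq_len(config$modules2[p])]
      all_pairs <- expand.grid(u = u, v = v, stringsAsFactors = FALSE)
      m <- round(config$sim_density * nrow(all_pairs))
      take <- sample.int(nrow(all_pairs), m)
      sim_from <- c(sim_from, all_pairs$u[take])
      sim_to <- c(sim_to, all_pairs$v[take])
    }
    sim <- tibble(node1 = sim_from, node2 = sim_to, score = 1)

    if (config$noise > 0) {
      edges1 <- rewire(edges1, config$noise)
      edges2 <- rewire(edges2, config$noise)
      sim_rw <- rewire(sim[, c("node1", "node2")], config$noise, bipartite = TRUE)
      sim <- tibble(node1 = sim_rw[[1]], node2 = sim_rw[[2]], score = 1)
    }

    structure(
      list(
        net1 = ppi_network(edges1, nodes = labels1),
        net2 = ppi_network(edges2, nodes = labels2),
        sim = sim,
        truth1 = truth1, truth2 = truth2,
        config = config
      ),
      class = "synthetic_pair"
    )
  })
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf(
    "<synthetic_pair> net1: %d nodes/%d edges, net2: %d nodes/%d edges, %d similarity links, noise %g\n",
    n_nodes(x$net1), n_edges(x$net1), n_nodes(x$net2), n_edges(x$net2),
    nrow(x$sim), x$config$noise
  ))
  invisible(x)
}

#' Maslov–Sneppen degree-preserving rewiring
#'
#' Randomly permutes a fraction of an edge set by double-edge swaps that
#' preserve every node's degree and never introduce self-loops or duplicate
#' edges. Swapping continues until the number of edges differing from the
#' input (symmetric-difference criterion) reaches
#' `ceiling(fraction * nrow(edges))`, or an attempt cap of
#' `100 * nrow(edges)` is hit, in which case the achieved fraction is
#' reported in a warning and the best effort returned.
#'
#' For `bipartite = TRUE` (similarity links) an edge's two endpoints live on
#' different sides; swaps exchange right endpoints only, preserving each
#' side's degrees and never creating within-side edges.
#'
#' @param edges Data frame whose first two columns are the edge endpoints.
#' @param fraction Fraction of edges to displace, in \[0, 1\].
#' @param bipartite Are the edges bipartite (column 1 side vs column 2
#'   side)?
#' @param seed Optional integer seed; `NULL` uses the current RNG state (as
#'   when called from [generate_pair()]).
#' @return A tibble of rewired edges with the same columns and degree
#'   sequence(s) as the input.
#' @export
rewire <- function(edges, fraction, bipartite = FALSE, seed = NULL) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1]")
  edges <- as.data.frame(edges)
  m <- nrow(edges)
  run <- function() rewire_impl(edges, fraction, bipartite)
  if (m < 2L || fraction == 0) {
    return(tibble(from = as.character(edges[[1]]), to = as.character(edges[[2]])))
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

edge_key <- function(a, b, bipartite) {
  if (bipartite) paste(a, b, sep = "\r") else paste(pmin(a, b), pmax(a, b), sep = "\r")
}

rewire_impl <- function(edges, fraction, bipartite) {
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  m <- length(from)
  target <- ceiling(fraction * m)

  keys <- edge_key(from, to, bipartite)
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (k in keys) assign(k, TRUE, envir = present)
  orig <- new.env(hash = TRUE, parent = emptyenv())
  for (k in keys) assign(k, TRUE, envir = orig)

  n_diff <- 0L
  attempts <- 0L
  cap <- 100L * m
  while (n_diff < target && attempts < cap) {
    attempts <- attempts + 1L
    ij <- sample.int(m, 2L)
    a <- from[ij[1]]; b <- to[ij[1]]
    c_ <- from[ij[2]]; d <- to[ij[2]]
    if (!bipartite && runif(1) < 0.5) {
      tmp <- c_; c_ <- d; d <- tmp # random orientation of the second edge
    }
    # proposed swap: (a,b),(c,d) -> (a,d),(c,b)
    if (a == d || c_ == b) next
    k_new1 <- edge_key(a, d, bipartite)
    k_new2 <- edge_key(c_, b, bipartite)
    if (k_new1 == k_new2) next
    if (exists(k_new1, envir = present, inherits = FALSE)) next
    if (exists(k_new2, envir = present, inherits = FALSE)) next

    k_old1 <- edge_key(a, b, bipartite)
    k_old2 <- edge_key(c_, d, bipartite)
    rm(list = c(k_old1, k_old2), envir = present)
    assign(k_new1, TRUE, envir = present)
    assign(k_new2, TRUE, envir = present)
    # diff count = |current \ original|
    in_orig <- function(k) exists(k, envir = orig, inherits = FALSE)
    n_diff <- n_diff -
      (1L - in_orig(k_old1)) - (1L - in_orig(k_old2)) +
      (1L - in_orig(k_new1)) + (1L - in_orig(k_new2))
    from[ij[1]] <- a; to[ij[1]] <- d
    from[ij[2]] <- c_; to[ij[2]] <- b
  }
  if (n_diff < target) {
    warn(sprintf(
      "rewiring attempt cap reached: displaced %d of the targeted %d edges (achieved fraction %.3f)",
      n_diff, target, n_diff / m
    ))
  }
  tibble(from = from, to = to)
}

#' Write a synthetic pair to a directory of plain-text files
#'
#' Writes `net1.tsv`, `net2.tsv` (edge lists), `sim.tsv` (similarity), and
#' `truth1.tsv`, `truth2.tsv` (node, module id).
#'
#' @param pair A `synthetic_pair`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pair <- function(pair, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wtsv <- function(df, file) {
    utils::write.table(df, file.path(dir, file),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  wtsv(pair$net1$edges, "net1.tsv")
  wtsv(pair$net2$edges, "net2.tsv")
  wtsv(pair$sim, "sim.tsv")
  wtsv(pair$truth1, "truth1.tsv")
  wtsv(pair$truth2, "truth2.tsv")
  invisible(dir)
}
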