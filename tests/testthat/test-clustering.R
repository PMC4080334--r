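test_that("stationary distributions satisfy known closed forms", {
  # period-2 chain: the damped iteration still finds the uniform fixed point
  P <- rbind(c(0, 1), c(1, 0))
  expect_equal(stationary_distribution(P), c(0.5, 0.5), tolerance = 1e-10)

  # reversible chain: pi proportional to the row sums of the weight matrix
  withr::with_seed(5, {
    W <- matrix(stats::runif(36), 6, 6)
    W <- W + t(W)
    P <- as.matrix(row_stochastic(W))
    expect_equal(
      stationary_distribution(P),
      rowSums(W) / sum(W),
      tolerance = 1e-8
    )
  })

  # identity chain: reducible, uniform start selects the uniform distribution
  expect_warning(pi <- stationary_distribution(diag(4)), "reducible")
  expect_equal(pi, rep(0.25, 4))

  expect_error(stationary_distribution(rbind(c(1, 1), c(0, 1))), "row-stochastic")
})

test_that("symmetrization yields the equivalent undirected weight matrix", {
  P <- rbind(c(0, 1), c(1, 0))
  sy <- symmetrize(P, c(0.5, 0.5))
  expect_equal(as.matrix(sy$Pbar), rbind(c(0, 0.5), c(0.5, 0)))
  expect_equal(sy$Dbar, c(0.5, 0.5))

  # reversible chain: Pbar equals diag(pi) %*% P exactly (detailed balance)
  withr::with_seed(11, {
    W <- matrix(stats::runif(25), 5, 5)
    W <- W + t(W)
    P <- as.matrix(row_stochastic(W))
    pi <- rowSums(W) / sum(W)
    sy <- symmetrize(P, pi)
    expect_equal(as.matrix(sy$Pbar), diag(pi) %*% P, tolerance = 1e-12)
    expect_equal(sy$Dbar, pi, tolerance = 1e-8)
    expect_true(Matrix::isSymmetric(sy$Pbar))
  })
})

test_that("conductance matches Eq-level closed forms and the brute-force oracle", {
  withr::with_seed(2, {
    W <- matrix(stats::runif(16, 0.1, 1), 4, 4)
    W <- W + t(W)
    P <- as.matrix(row_stochastic(W))
    pi <- stationary_distribution(P)
    # singleton: 1 - P(i, i)
    for (i in 1:4) expect_equal(conductance(P, pi, i), 1 - P[i, i], tolerance = 1e-10)
  })

  # one block of a block-diagonal chain leaks nothing
  Pb <- as.matrix(Matrix::bdiag(
    row_stochastic(matrix(1, 3, 3)), row_stochastic(matrix(1, 2, 2))
  ))
  pi_b <- suppressWarnings(stationary_distribution(Pb))
  expect_equal(conductance(Pb, pi_b, 1:3), 0)

  # 4-node path, simple walk: pi proportional to degree; direct Eq-9 oracle
  A <- matrix(0, 4, 4)
  A[cbind(1:3, 2:4)] <- 1
  A <- A + t(A)
  P <- as.matrix(row_stochastic(A))
  pi <- rowSums(A) / sum(A) # c(1,2,2,1)/6
  expect_equal(
    conductance(P, pi, 1:2),
    conductance_oracle(P, pi, 1:2),
    tolerance = 1e-12
  )
  expect_equal(conductance_oracle(P, pi, 1:2), (2 / 6) * (1 / 2) / (3 / 6))

  expect_error(conductance(P, pi, integer(0)), "proper subset")
  expect_error(conductance(P, pi, 1:4), "proper subset")
})

test_that("the partition objective equals the cut ratio on the symmetrized graph", {
  withr::with_seed(31, {
    for (M in tiny_fixture_suite()) {
      ch <- chain_for(M)
      n <- nrow(ch$P)
      for (rep in 1:10) {
        size <- sample(n - 1, 1)
        subset <- sample(n, size)
        expect_equal(
          conductance(ch$P, ch$pi, subset),
          cut_ratio_oracle(ch$Pbar, ch$pi, subset),
          tolerance = 1e-10
        )
      }
      # two-cluster objective via the definition
      labels <- rep(1L, n)
      labels[sample(n, floor(n / 2))] <- 2L
      expect_equal(
        objective(ch$P, ch$pi, labels),
        conductance(ch$P, ch$pi, which(labels == 1)) +
          conductance(ch$P, ch$pi, which(labels == 2))
      )
    }
  })
  P <- rbind(c(0, 1), c(1, 0))
  expect_error(objective(P, c(.5, .5), c(1L, 1L)), "at least 2")
})

test_that("spectral partitioning separates ideal structure exactly", {
  clique_edges <- function(labels) {
    pairs <- utils::combn(labels, 2)
    data.frame(from = pairs[1, ], to = pairs[2, ])
  }
  net <- ppi_network(rbind(clique_edges(sprintf("a%d", 1:5)), clique_edges(sprintf("b%d", 1:5))))
  fit <- suppressWarnings(ncut_single(net, k = 2, seed = 1))
  truth <- rep(1:2, each = 5)
  expect_equal(nmi(truth, fit$assignment$cluster), 1)
  expect_equal(fit$objective, 0)

  # two disconnected cliques joined as separate networks, no similarity:
  # each network is its own cluster
  net1 <- ppi_network(clique_edges(sprintf("u%d", 1:4)))
  net2 <- ppi_network(clique_edges(sprintf("v%d", 1:4)))
  jfit <- suppressWarnings(asmodel(net1, net2, NULL, k = 2, seed = 1))
  expect_equal(nmi(jfit$assignment$network, jfit$assignment$cluster), 1)
})

test_that("identical networks with identity similarity pair up mirror nodes", {
  edges <- data.frame(
    from = c("p1", "p2", "p3", "p4", "p4", "p5"),
    to = c("p2", "p3", "p1", "p5", "p6", "p6")
  )
  net <- ppi_network(rbind(edges, data.frame(from = "p1", to = "p4")))
  sim <- data.frame(node1 = net$nodes, node2 = net$nodes, score = 1)
  fit <- suppressWarnings(asmodel(net, net, sim, k = 2, seed = 1))
  a <- fit$assignment
  # each cluster draws equally from both copies
  comp <- table(a$cluster, a$network)
  expect_equal(unname(comp[, 1]), unname(comp[, 2]))
  # mirror nodes share a cluster
  for (p in net$nodes) {
    expect_equal(
      a$cluster[a$node == p & a$network == 1],
      a$cluster[a$node == p & a$network == 2]
    )
  }
})

test_that("clustering is deterministic under a fixed seed and order-invariant", {
  cfg <- synthetic_pair_config(modules1 = c(8, 8), modules2 = c(6, 6), noise = 0.2)
  pair <- generate_pair(cfg, seed = 9)
  f1 <- suppressWarnings(asmodel(pair$net1, pair$net2, pair$sim, k = 2, seed = 4))
  f2 <- suppressWarnings(asmodel(pair$net1, pair$net2, pair$sim, k = 2, seed = 4))
  expect_identical(f1$assignment, f2$assignment)

  # permuting the edge input order leaves the partition unchanged
  edges_perm <- pair$net1$edges[sample(nrow(pair$net1$edges)), ]
  net1p <- ppi_network(edges_perm, nodes = pair$net1$nodes)
  f3 <- suppressWarnings(asmodel(net1p, pair$net2, pair$sim, k = 2, seed = 4))
  expect_identical(f1$assignment, f3$assignment)
})

test_that("ncut on one network matches the collapsed no-similarity joint model", {
  cfg <- synthetic_pair_config(modules1 = c(6, 6), modules2 = c(5, 5), edge_density = 0.8)
  pair <- generate_pair(cfg, seed = 21)
  single <- suppressWarnings(ncut_single(pair$net1, k = 2, seed = 3))
  # with S = 0 the chain never crosses networks; clusters restricted to
  # network 1 must induce the same partition the baseline finds
  joint <- suppressWarnings(asmodel(pair$net1, pair$net2, NULL, k = 4, seed = 3))
  sub <- joint$assignment[joint$assignment$network == 1, ]
  expect_equal(nmi(single$assignment$cluster, sub$cluster), 1, tolerance = 1e-8)
})

test_that("cluster projection drops small restrictions and counts coverage", {
  assignment <- tibble::tibble(
    node = c("u1", "u2", "v1", "u3", "v2", "v3"),
    network = c(1L, 1L, 2L, 1L, 2L, 2L),
    cluster = c(1L, 1L, 1L, 2L, 2L, 2L)
  )
  p1 <- project_clusters(assignment, which = 1)
  expect_equal(p1$clusters, list(`1` = c("u1", "u2")))
  expect_equal(p1$coverage, 2L)
  p2 <- project_clusters(assignment, which = 2)
  expect_equal(p2$clusters, list(`2` = c("v2", "v3")))
  # all-singleton projection: nothing retained
  p3 <- project_clusters(assignment, which = 2, min_size = 3)
  expect_equal(length(p3$clusters), 0L)
  expect_equal(p3$coverage, 0L)
})

test_that("tidy, glance and autoplot expose the fit", {
  pair <- generate_pair(synthetic_pair_config(modules1 = c(5, 5), modules2 = c(4, 4)), seed = 2)
  fit <- suppressWarnings(asmodel(pair$net1, pair$net2, pair$sim, k = 2, seed = 1))
  td <- tidy(fit)
  expect_named(td, c("node", "network", "cluster"))
  expect_equal(nrow(td), 18)
  gl <- glance(fit)
  expect_equal(gl$n_nodes, 18)
  expect_equal(gl$k, 2L)
  expect_s3_class(autoplot(fit), "ggplot")
})
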