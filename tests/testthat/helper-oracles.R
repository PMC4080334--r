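# Independent oracles (dense base-R arithmetic, exhaustive enumeration)
# used to cross-check the sparse implementation. Deliberately written
# without calling the package's own code paths.

# build a ppi_network from "a b" edge strings
net_from_strings <- function(...) {
  parts <- strsplit(c(...), " ")
  ppi_network(data.frame(
    from = vapply(parts, `[[`, "", 1),
    to = vapply(parts, `[[`, "", 2)
  ))
}

# dense row normalization with identity-row fallback
dense_rownorm <- function(W) {
  W <- as.matrix(W)
  rs <- rowSums(W)
  for (i in seq_len(nrow(W))) {
    if (rs[i] == 0) {
      W[i, ] <- 0
      W[i, i] <- 1
      rs[i] <- 1
    }
  }
  W / rs
}

# all six walk matrices by direct dense matrix products
dense_transition_oracle <- function(A, S) {
  A <- as.matrix(A)
  S <- as.matrix(S)
  n <- nrow(A)
  I <- diag(n)
  P_A <- dense_rownorm(A)
  P_Sbar <- dense_rownorm(S + I)
  P_S <- dense_rownorm(S)
  P_Abar <- dense_rownorm(A + I)
  P_ASbar <- P_A %*% P_Sbar
  P_SAbar <- P_S %*% P_Abar
  list(
    P_A = P_A, P_Sbar = P_Sbar, P_S = P_S, P_Abar = P_Abar,
    P_ASbar = P_ASbar, P_SAbar = P_SAbar,
    P = 0.5 * P_ASbar + 0.5 * P_SAbar
  )
}

# Eq-9 conductance by direct double summation over node pairs
conductance_oracle <- function(P, pi, subset) {
  P <- as.matrix(P)
  n <- nrow(P)
  comp <- setdiff(seq_len(n), subset)
  num <- 0
  for (i in subset) for (j in comp) num <- num + pi[i] * P[i, j]
  num / sum(pi[subset])
}

# cut/volume on the symmetrized undirected weight matrix
cut_ratio_oracle <- function(Pbar, pi, subset) {
  Pbar <- as.matrix(Pbar)
  comp <- setdiff(seq_len(nrow(Pbar)), subset)
  sum(Pbar[subset, comp, drop = FALSE]) / sum(pi[subset])
}

# exhaustive minimum of the 2-way total-conductance objective
brute_force_best_2partition <- function(P, pi) {
  P <- as.matrix(P)
  n <- nrow(P)
  best <- Inf
  best_labels <- NULL
  for (code in 0:(2^(n - 1) - 2)) { # node 1 always in cluster 1; full set excluded
    inC <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2)))))
    subset <- which(inC)
    obj <- conductance_oracle(P, pi, subset) +
      conductance_oracle(P, pi, setdiff(seq_len(n), subset))
    if (obj < best) {
      best <- obj
      best_labels <- ifelse(inC, 1L, 2L)
    }
  }
  list(objective = best, labels = best_labels)
}

# loop-based contingency-table NMI (natural log, arithmetic-mean norm)
nmi_oracle <- function(truth, pred) {
  n <- length(truth)
  tl <- unique(truth)
  pl <- unique(pred)
  mi <- 0
  for (a in tl) {
    for (b in pl) {
      nij <- sum(truth == a & pred == b)
      if (nij > 0) {
        mi <- mi + (nij / n) * log((nij / n) / ((sum(truth == a) / n) * (sum(pred == b) / n)))
      }
    }
  }
  ht <- 0
  for (a in tl) ht <- ht - (sum(truth == a) / n) * log(sum(truth == a) / n)
  hp <- 0
  for (b in pl) hp <- hp - (sum(pred == b) / n) * log(sum(pred == b) / n)
  if ((ht + hp) == 0) return(1)
  mi / ((ht + hp) / 2)
}

# upper-tail hypergeometric by explicit binomial sums
hyper_oracle <- function(N, M, n, m) {
  hi <- min(M, n)
  if (m > hi) return(0)
  total <- 0
  for (i in m:hi) total <- total + choose(M, i) * choose(N - M, n - i)
  total / choose(N, n)
}

# a small random integrated network (dense enough to be interesting)
random_integrated <- function(n1, n2, p_edge = 0.4, p_sim = 0.3) {
  e1 <- t(utils::combn(n1, 2))
  e1 <- e1[stats::runif(nrow(e1)) < p_edge, , drop = FALSE]
  e2 <- t(utils::combn(n2, 2))
  e2 <- e2[stats::runif(nrow(e2)) < p_edge, , drop = FALSE]
  labs1 <- sprintf("u%d", seq_len(n1))
  labs2 <- sprintf("v%d", seq_len(n2))
  net1 <- ppi_network(
    data.frame(from = labs1[e1[, 1]], to = labs1[e1[, 2]]),
    nodes = labs1
  )
  net2 <- ppi_network(
    data.frame(from = labs2[e2[, 1]], to = labs2[e2[, 2]]),
    nodes = labs2
  )
  pairs <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  pairs <- pairs[stats::runif(nrow(pairs)) < p_sim, , drop = FALSE]
  sim <- if (nrow(pairs) > 0) {
    data.frame(
      node1 = labs1[pairs$i], node2 = labs2[pairs$j],
      score = round(stats::runif(nrow(pairs), 0.1, 1), 3)
    )
  } else {
    NULL
  }
  build_integrated(net1, net2, sim)
}

# fixture suite of small integrated networks (N <= 10 nodes total)
tiny_fixture_suite <- function() {
  list(
    # two paths, one cross link
    build_integrated(
      net_from_strings("a b", "b c"),
      net_from_strings("x y", "y z"),
      data.frame(node1 = "b", node2 = "y", score = 0.8)
    ),
    # triangle + square, two cross links
    build_integrated(
      net_from_strings("a b", "b c", "a c"),
      net_from_strings("w x", "x y", "y z", "w z"),
      data.frame(node1 = c("a", "c"), node2 = c("w", "y"), score = c(1, 0.5))
    ),
    # star + path, full bipartite similarity
    build_integrated(
      net_from_strings("h a", "h b", "h c"),
      net_from_strings("p q", "q r"),
      expand.grid(
        node1 = c("h", "a", "b", "c"), node2 = c("p", "q", "r"),
        stringsAsFactors = FALSE
      ) |> transform(score = 0.6)
    ),
    # two cliques, no similarity
    build_integrated(
      net_from_strings("a b", "b c", "a c"),
      net_from_strings("x y", "y z", "x z"),
      NULL
    )
  )
}

# fitted chain for a fixture: P, pi, Pbar, Dbar (warnings silenced: many
# fixtures are deliberately reducible)
chain_for <- function(M) {
  tm <- suppressWarnings(build_transition(M))
  pi <- suppressWarnings(stationary_distribution(tm$P))
  sy <- symmetrize(tm$P, pi)
  list(P = tm$P, pi = pi, Pbar = sy$Pbar, Dbar = sy$Dbar, tm = tm)
}
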