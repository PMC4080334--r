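# Low-conductance-set machinery: stationary distribution, conductance,
# symmetrized equivalent graph, and the spectral k-way partitioner.

check_row_stochastic <- function(P, tol = 1e-8) {
  if (nrow(P) != ncol(P)) abort("`P` must be square")
  if (max(abs(rowSums(P) - 1)) > tol) {
    abort("`P` is not row-stochastic (row sums differ from 1)")
  }
}

#' Stationary distribution of a finite Markov chain
#'
#' Solves `pi' P = pi'` by damped power iteration from the uniform start:
#' each step replaces the iterate by the average of itself and its image,
#' `x <- (x + x P) / 2`. This running-average smoothing has the same fixed
#' points as plain power iteration but converges geometrically even on
#' periodic chains (the alternating walk can be 2-periodic). On a reducible
#' chain the stationary distribution is not unique; the one selected by the
#' uniform start is returned with a warning.
#'
#' @param P Row-stochastic matrix.
#' @param tol Convergence tolerance on the 1-norm residual `||x P - x||_1`.
#' @param max_iter Iteration cap.
#' @param check_reducible Warn when the chain's transition graph is not
#'   strongly connected (one strong-components pass; skip in hot loops).
#' @return Probability vector `pi` with `sum(pi) == 1` and
#'   `pi' P = pi'` within `tol`.
#' @export
stationary_distribution <- function(P, tol = 1e-12, max_iter = 1e5,
                                    check_reducible = TRUE) {
  P <- methods::as(methods::as(P, "dMatrix"), "CsparseMatrix")
  check_row_stochastic(P)
  n <- nrow(P)
  if (check_reducible) {
    # force general storage: symmetric sparse classes would expose only one
    # triangle to the directed-graph constructor
    g <- igraph::graph_from_adjacency_matrix(
      methods::as(P, "generalMatrix"),
      mode = "directed", weighted = TRUE
    )
    ncomp <- igraph::count_components(g, mode = "strong")
    if (ncomp > 1L) {
      warn(sprintf(
        "chain is reducible (%d strongly connected components); returning the stationary distribution selected by the uniform start",
        ncomp
      ))
    }
  }
  x <- rep(1 / n, n)
  res <- Inf
  for (it in seq_len(max_iter)) {
    xP <- as.numeric(crossprod(P, x))
    res <- sum(abs(xP - x))
    if (res < tol) break
    x <- 0.5 * (x + xP)
    x <- x / sum(x)
  }
  if (res >= tol) {
    abort(sprintf(
      "stationary distribution did not converge in %d iterations (residual %.3e)",
      as.integer(max_iter), res
    ))
  }
  x
}

#' Symmetrize a chain into its equivalent undirected weight matrix
#'
#' With `Pi = diag(pi)`, the matrix `Pbar = (Pi P + P' Pi) / 2` is symmetric
#' and carries the same cut structure as the directed chain: for any node
#' set, the `Pbar`-weighted cut over the set's stationary mass equals the
#' chain's conductance of the set. At stationarity its row sums recover
#' `pi`, so the diagonal degree matrix of `Pbar` is `diag(pi)`.
#'
#' @param P Row-stochastic matrix.
#' @param pi Its stationary distribution.
#' @return List with `Pbar` (sparse symmetric matrix) and `Dbar` (numeric
#'   vector of its row sums).
#' @export
symmetrize <- function(P, pi) {
  P <- methods::as(methods::as(P, "dMatrix"), "CsparseMatrix")
  U <- Diagonal(x = pi) %*% P
  Pbar <- methods::as((U + t(U)) / 2, "CsparseMatrix")
  list(Pbar = Pbar, Dbar = rowSums(Pbar))
}

#' Conductance of a node subset
#'
#' The stationary probability flow leaving the set divided by the set's
#' stationary mass:
#' `sum_{i in C, j notin C} pi_i P(i, j) / sum_{i in C} pi_i`.
#' A set with zero stationary mass contributes no flow and its conductance
#' is reported as 0.
#'
#' @param P Row-stochastic matrix.
#' @param pi Stationary distribution of `P`.
#' @param subset Integer (or logical) node indices; must be a nonempty
#'   proper subset.
#' @return Conductance in \[0, 1\].
#' @export
conductance <- function(P, pi, subset) {
  n <- nrow(P)
  if (is.logical(subset)) subset <- which(subset)
  subset <- as.integer(subset)
  if (length(subset) == 0L || length(subset) >= n) {
    abort("`subset` must be a nonempty proper subset of the nodes")
  }
  comp <- setdiff(seq_len(n), subset)
  mass <- sum(pi[subset])
  if (mass == 0) return(0)
  outflow <- sum(pi[subset] * rowSums(P[subset, comp, drop = FALSE]))
  outflow / mass
}

#' Total conductance of a partition
#'
#' The k-way clustering objective: the sum of [conductance()] over the
#' nonempty clusters of a hard partition.
#'
#' @param P Row-stochastic matrix.
#' @param pi Stationary distribution of `P`.
#' @param assignment Integer cluster label per node (or a `cluster` column
#'   in a data frame).
#' @return Nonnegative total conductance.
#' @export
objective <- function(P, pi, assignment) {
  if (is.data.frame(assignment)) assignment <- assignment$cluster
  if (length(assignment) != nrow(P)) abort("assignment length must match `P`")
  ids <- unique(assignment)
  if (length(ids) < 2L) {
    abort("the objective needs at least 2 nonempty clusters")
  }
  sum(vapply(ids, function(h) conductance(P, pi, assignment == h), 0))
}

# -- spectral solver ----------------------------------------------------------

# k-means++ seeding: d^2-weighted center sampling
kmeanspp_centers <- function(E, k) {
  n <- nrow(E)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums((E - matrix(E[idx[1], ], n, ncol(E), byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    tot <- sum(d2)
    idx[j] <- if (tot > 0) sample.int(n, 1L, prob = d2 / tot) else sample.int(n, 1L)
    dj <- rowSums((E - matrix(E[idx[j], ], n, ncol(E), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  E[idx, , drop = FALSE]
}

# Lloyd iterations tolerant of duplicate centers and empty clusters;
# distance ties go to the lowest cluster index.
lloyd_kmeans <- function(E, centers, iter_max = 100L) {
  n <- nrow(E)
  k <- nrow(centers)
  labels <- integer(n)
  for (it in seq_len(iter_max)) {
    d <- vapply(
      seq_len(k),
      function(j) rowSums((E - matrix(centers[j, ], n, ncol(E), byrow = TRUE))^2),
      numeric(n)
    )
    d <- matrix(d, nrow = n)
    new_labels <- max.col(-d, ties.method = "first")
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      members <- labels == j
      if (any(members)) centers[j, ] <- colMeans(E[members, , drop = FALSE])
    }
  }
  d_final <- vapply(
    seq_len(k),
    function(j) rowSums((E - matrix(centers[j, ], n, ncol(E), byrow = TRUE))^2),
    numeric(n)
  )
  d_final <- matrix(d_final, nrow = n)
  list(labels = labels, tot_withinss = sum(d_final[cbind(seq_len(n), labels)]))
}

top_k_eigenvectors <- function(L, k, dense_limit = 3000L) {
  n <- nrow(L)
  if (n <= dense_limit) {
    Ld <- as.matrix(L)
    Ld <- (Ld + base::t(Ld)) / 2
    ev <- eigen(Ld, symmetric = TRUE)
    ev$vectors[, seq_len(k), drop = FALSE]
  } else {
    res <- igraph::arpack(
      function(x, extra) as.numeric(L %*% x),
      sym = TRUE,
      options = list(
        n = n, nev = k, ncv = min(n, max(2L * k + 1L, 20L)),
        which = "LA", maxiter = 5000
      )
    )
    matrix(res$vectors, nrow = n)[, seq_len(k), drop = FALSE]
  }
}

#' Spectral k-way low-conductance partitioning
#'
#' Ng–Jordan–Weiss-style solver for the trace-maximization relaxation of
#' the k-way minimum-conductance problem: take the top-k eigenvectors of the
#' symmetrically normalized matrix `D^{-1/2} Pbar D^{-1/2}`, normalize the
#' embedding rows to unit length (zero rows — nodes with no stationary mass
#' — are left at zero with a warning), and round to a hard partition with
#' k-means (k-means++ seeding, 10 restarts, Lloyd updates, distance ties to
#' the lowest cluster index). Deterministic for a fixed seed. Some of the k
#' clusters may come out empty; the number of distinct labels can be < k.
#'
#' @param Pbar Symmetric nonnegative matrix from [symmetrize()].
#' @param Dbar Its row sums (numeric vector).
#' @param k Number of clusters, `2 <= k <= N`.
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return Integer vector of cluster labels in `1..k`, with `k` attached as
#'   attribute `"k"`.
#' @export
spectral_partition <- function(Pbar, Dbar, k, seed = 1L, nstart = 10L) {
  n <- nrow(Pbar)
  if (k < 2L) abort("`k` must be at least 2")
  if (k > n) abort("`k` must not exceed the number of nodes")
  d_inv_sqrt <- ifelse(Dbar > 0, 1 / sqrt(Dbar), 0)
  L <- Diagonal(x = d_inv_sqrt) %*% Pbar %*% Diagonal(x = d_inv_sqrt)
  V <- top_k_eigenvectors(methods::as(L, "CsparseMatrix"), k)
  rn <- sqrt(rowSums(V^2))
  zero <- rn < .Machine$double.eps
  if (any(zero)) {
    warn(sprintf(
      "%d embedding row(s) are zero (no stationary mass); left at the origin",
      sum(zero)
    ))
    rn[zero] <- 1
  }
  E <- V / rn

  labels <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      fit <- lloyd_kmeans(E, kmeanspp_centers(E, k))
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
    best$labels
  })
  attr(labels, "k") <- as.integer(k)
  labels
}

# stationary -> symmetrize -> spectral, shared by asmodel() and ncut_single()
partition_chain <- function(P, k, seed) {
  pi <- stationary_distribution(P)
  sy <- symmetrize(P, pi)
  labels <- spectral_partition(sy$Pbar, sy$Dbar, k = k, seed = seed)
  obj <- tryCatch(
    objective(P, pi, as.integer(labels)),
    error = function(e) NA_real_
  )
  list(pi = pi, labels = as.integer(labels), objective = obj, sym = sy)
}
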