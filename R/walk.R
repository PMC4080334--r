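#' Row-normalize a nonnegative matrix to a stochastic matrix
#'
#' Divides each row by its sum. A row of zeros has no outgoing probability;
#' under `zero_row_policy = "self_loop"` (the default everywhere in the
#' pipeline) such a row becomes the identity row — the walker stays put —
#' which keeps the matrix stochastic and reduces gracefully to
#' single-network behavior for proteins with no homology partner.
#'
#' @param W Nonnegative square matrix (base or `Matrix` sparse).
#' @param zero_row_policy `"self_loop"` or `"error"`.
#' @return A sparse row-stochastic matrix; the indices of rows where the
#'   fallback fired are attached as attribute `"fallback_rows"`.
#' @export
row_stochastic <- function(W, zero_row_policy = c("self_loop", "error")) {
  zero_row_policy <- match.arg(zero_row_policy)
  W <- methods::as(methods::as(W, "dMatrix"), "CsparseMatrix")
  if (nrow(W) != ncol(W)) abort("`W` must be square")
  if (any(W@x < 0)) abort("`W` must be nonnegative")
  rs <- rowSums(W)
  zero <- rs == 0
  if (any(zero)) {
    if (zero_row_policy == "error") {
      abort(sprintf(
        "zero row(s) at node index %s: no outgoing transition",
        paste(head(which(zero), 5), collapse = ", ")
      ))
    }
    W <- W + Diagonal(nrow(W), x = as.numeric(zero))
    rs[zero] <- 1
  }
  P <- Diagonal(x = 1 / rs) %*% W
  P <- methods::as(P, "CsparseMatrix")
  attr(P, "fallback_rows") <- which(zero)
  P
}

#' Build the alternating-random-walk transition model
#'
#' The walker on the integrated network must alternate between a topological
#' step (within-network interactions, matrix `A`) and a homological step
#' (cross-network similarity, matrix `S`). Writing `Abar = A + I` and
#' `Sbar = S + I` for the self-loop-augmented variants, the two step orders
#' give two-step transition matrices
#' `P_ASbar = P_A %*% P_Sbar` (topology first, then homology-or-stay) and
#' `P_SAbar = P_S %*% P_Abar` (homology first, then topology-or-stay),
#' where each factor is the row normalization of the corresponding matrix.
#' Both orders are assumed equally likely, so the final chain is
#' `P = (P_ASbar + P_SAbar) / 2`.
#'
#' Proteins with no homology partner have an empty `S` row; their `P_S` row
#' falls back to a self-loop (see [row_stochastic()]), so for them the
#' homology-first walk reduces to the lazy topological walk. Rows of `A`
#' with no interactions trigger the same fallback, with a warning.
#'
#' @param M An `integrated_network` from [build_integrated()].
#' @param keep_intermediates Keep all six factor/product matrices (needed by
#'   the equation-level tests); `FALSE` stores only `P`, for a memory-lean
#'   run on large networks.
#' @return An object of class `transition_model` with elements `P` and
#'   (optionally) `P_A`, `P_Sbar`, `P_S`, `P_Abar`, `P_ASbar`, `P_SAbar`,
#'   plus `fallback` listing the rows where each self-loop fallback fired.
#' @export
build_transition <- function(M, keep_intermediates = TRUE) {
  if (!inherits(M, "integrated_network")) {
    abort("`M` must be an integrated_network")
  }
  n <- M$n1 + M$n2
  I_n <- Diagonal(n)

  P_A <- row_stochastic(M$A, "self_loop")
  if (length(attr(P_A, "fallback_rows")) > 0) {
    warn(sprintf(
      "%d isolated node(s) in the topology matrix: self-loop fallback applied",
      length(attr(P_A, "fallback_rows"))
    ))
  }
  P_Sbar <- row_stochastic(M$S + I_n, "self_loop") # rows never empty
  P_S <- row_stochastic(M$S, "self_loop")
  P_Abar <- row_stochastic(M$A + I_n, "self_loop") # rows never empty

  P_ASbar <- methods::as(P_A %*% P_Sbar, "CsparseMatrix")
  P_SAbar <- methods::as(P_S %*% P_Abar, "CsparseMatrix")
  P <- methods::as(0.5 * P_ASbar + 0.5 * P_SAbar, "CsparseMatrix")

  out <- list(
    P = P,
    fallback = list(
      topology = attr(P_A, "fallback_rows"),
      homology = attr(P_S, "fallback_rows")
    )
  )
  if (keep_intermediates) {
    out <- c(out, list(
      P_A = P_A, P_Sbar = P_Sbar, P_S = P_S, P_Abar = P_Abar,
      P_ASbar = P_ASbar, P_SAbar = P_SAbar
    ))
  }
  structure(out, class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf(
    "<transition_model> %d states, %d nonzero transitions; %d homology self-loop fallback(s)\n",
    nrow(x$P), Matrix::nnzero(x$P), length(x$fallback$homology)
  ))
  invisible(x)
}

#' Dump a transition matrix in MatrixMarket format
#'
#' @param tm A `transition_model` (or any matrix).
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_transition_mtx <- function(tm, path) {
  P <- if (inherits(tm, "transition_model")) tm$P else tm
  Matrix::writeMM(methods::as(P, "CsparseMatrix"), path)
  invisible(path)
}
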