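# Evaluation metrics: NMI, neighbor affinity, complex prediction,
# information content, hypergeometric enrichment.

#' Normalized mutual information between two labelings
#'
#' Mutual information of the two partitions' contingency table, normalized
#' by the arithmetic mean of the two label entropies (natural log
#' internally; the normalization cancels the base). Identical partitions
#' score 1; a labeling carrying no information about the truth scores 0.
#' When both labelings are the same single cluster the value is defined as
#' 1 (perfect, if trivial, agreement).
#'
#' @param truth,pred Equal-length label vectors (any atomic type).
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("labelings must have equal length")
  if (length(truth) == 0L) abort("labelings must be nonempty")
  n <- length(truth)
  tab <- table(truth, pred)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  h_t <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h_p <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  denom <- (h_t + h_p) / 2
  if (denom == 0) return(1) # both are the same single cluster
  min(max(mi / denom, 0), 1)
}

#' Neighbor affinity between a cluster and a reference complex
#'
#' `|C intersect R|^2 / (|C| * |R|)`: the product of the two directional
#' overlap fractions. Equals 1 only when the sets coincide.
#'
#' @param C,R Nonempty character vectors (treated as sets).
#' @return Affinity in \[0, 1\].
#' @export
neighbor_affinity <- function(C, R) {
  C <- unique(C)
  R <- unique(R)
  if (length(C) == 0L || length(R) == 0L) abort("sets must be nonempty")
  length(intersect(C, R))^2 / (length(C) * length(R))
}

#' Complex-prediction precision, recall, and F-measure
#'
#' A cluster matches a reference complex when their neighbor affinity is
#' strictly greater than `threshold` (default 0.25). Precision is the
#' fraction of clusters matching some reference; recall is the fraction of
#' references matched by some cluster; F is their harmonic mean (0 when
#' both are 0).
#'
#' @param clusters List of nonempty character vectors (predicted
#'   complexes), e.g. `project_clusters(fit)$clusters`.
#' @param refs Reference complexes: a tibble from [read_complexes()] or a
#'   list of character vectors.
#' @param threshold Neighbor-affinity matching threshold (strict `>`).
#' @return One-row tibble: `precision`, `recall`, `f_measure`,
#'   `matched_clusters`, `matched_references`.
#' @export
complex_prediction <- function(clusters, refs, threshold = 0.25) {
  if (is.data.frame(refs)) refs <- refs$members
  if (length(refs) == 0L) abort("`refs` must be nonempty")
  if (length(clusters) == 0L) abort("`clusters` must be nonempty")
  na_mat <- vapply(
    refs,
    function(R) vapply(clusters, neighbor_affinity, 0, R = R),
    numeric(length(clusters))
  )
  na_mat <- matrix(na_mat, nrow = length(clusters))
  hit <- na_mat > threshold
  matched_clusters <- sum(rowSums(hit) > 0)
  matched_references <- sum(colSums(hit) > 0)
  precision <- matched_clusters / length(clusters)
  recall <- matched_references / length(refs)
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble(
    precision = precision, recall = recall, f_measure = f,
    matched_clusters = matched_clusters, matched_references = matched_references
  )
}

#' Information content of an annotation term
#'
#' `-log10(term_size / root_size)`: how specific a GO term is relative to
#' its root category. Base 10, so IC >= 2 keeps terms annotating at most 1%
#' of the category — the "specific cellular functions" filter.
#'
#' @param term_size Number of proteins annotated with the term (> 0).
#' @param root_size Number of annotated proteins in the term's category.
#' @return Nonnegative IC value(s).
#' @export
information_content <- function(term_size, root_size) {
  if (any(term_size <= 0)) abort("`term_size` must be positive")
  if (any(term_size > root_size)) abort("`term_size` cannot exceed `root_size`")
  -log10(term_size / root_size)
}

#' Upper-tail hypergeometric p-value
#'
#' The probability of observing at least `m` annotated proteins in a
#' cluster of `n` proteins drawn from a universe of `N` proteins of which
#' `M` carry the annotation:
#' `sum_{i = m}^{min(M, n)} choose(M, i) choose(N - M, n - i) / choose(N, n)`.
#' Computed in log space via [stats::phyper()].
#'
#' @param N Universe size.
#' @param M Number of annotated proteins in the universe.
#' @param n Cluster size.
#' @param m Observed overlap.
#' @return p-value in (0, 1\]; `m = 0` gives exactly 1.
#' @export
hypergeom_pvalue <- function(N, M, n, m) {
  if (M > N || n > N) abort("`M` and `n` cannot exceed `N`")
  if (m > min(M, n)) abort("`m` cannot exceed min(M, n)")
  if (m < 0) abort("`m` must be nonnegative")
  phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' GO-term enrichment of a set of clusters
#'
#' Terms are first filtered to those with information content at least
#' `min_ic` (relative to their own `root_size`). For every retained term
#' and every cluster, an upper-tail hypergeometric p-value is computed with
#' the cluster size as the draw; each cluster is summarized by its minimum
#' p-value (and the term attaining it), and a term counts as enriched when
#' any cluster reaches `p < alpha` (strict; no multiple-testing
#' correction).
#'
#' @param clusters Named list of character vectors (or unnamed; indices are
#'   used as names).
#' @param ann Annotation tibble from [read_annotations()] (`term`,
#'   `root_size`, `members`).
#' @param universe Number of proteins in the whole network (the
#'   hypergeometric `N`).
#' @param alpha Enrichment threshold on the raw p-value.
#' @param min_ic Minimum information content of a term to be tested.
#' @return An `enrichment_report`: `clusters` (tibble: `cluster`, `size`,
#'   `p_min`, `best_term`), `enriched_terms` (character), `n_enriched`.
#' @export
enrichment <- function(clusters, ann, universe, alpha = 1e-3, min_ic = 2) {
  if (length(clusters) == 0L) abort("`clusters` must be nonempty")
  if (is.null(names(clusters))) names(clusters) <- as.character(seq_along(clusters))
  ic <- information_content(lengths(ann$members), ann$root_size)
  ann <- ann[ic >= min_ic, ]
  if (nrow(ann) == 0L) {
    warn("no annotation term passes the information-content filter")
    return(structure(
      list(
        clusters = tibble(
          cluster = names(clusters), size = lengths(clusters),
          p_min = rep(NA_real_, length(clusters)),
          best_term = rep(NA_character_, length(clusters))
        ),
        enriched_terms = character(0), n_enriched = 0L
      ),
      class = "enrichment_report"
    ))
  }
  pmat <- vapply(seq_len(nrow(ann)), function(t) {
    members <- ann$members[[t]]
    M <- length(members)
    vapply(clusters, function(C) {
      C <- unique(C)
      hypergeom_pvalue(universe, M, length(C), length(intersect(C, members)))
    }, 0)
  }, numeric(length(clusters)))
  pmat <- matrix(pmat, nrow = length(clusters))
  best <- apply(pmat, 1, which.min)
  enriched <- ann$term[colSums(pmat < alpha) > 0]
  structure(
    list(
      clusters = tibble(
        cluster = names(clusters),
        size = lengths(clusters),
        p_min = pmat[cbind(seq_along(clusters), best)],
        best_term = ann$term[best]
      ),
      enriched_terms = enriched,
      n_enriched = length(enriched)
    ),
    class = "enrichment_report"
  )
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(
    "<enrichment_report> %d cluster(s) scored, %d enriched term(s)\n",
    nrow(x$clusters), x$n_enriched
  ))
  invisible(x)
}
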