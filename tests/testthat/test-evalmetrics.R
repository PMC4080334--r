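test_that("NMI matches closed forms and the contingency-table oracle", {
  expect_equal(nmi(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(nmi(rep(1:4, each = 5), rep(1, 20)), 0)
  expect_equal(nmi(c(1, 1), c(1, 1)), 1) # both trivial single-cluster
  expect_error(nmi(1:3, 1:4), "equal length")

  # hand-built 2x2 contingency case
  expect_equal(
    nmi(c(0, 0, 1, 1), c(0, 1, 1, 1)),
    nmi_oracle(c(0, 0, 1, 1), c(0, 1, 1, 1)),
    tolerance = 1e-12
  )

  withr::with_seed(99, {
    for (rep in 1:50) {
      n <- sample(5:40, 1)
      truth <- sample.int(4, n, replace = TRUE)
      pred <- sample.int(5, n, replace = TRUE)
      expect_equal(nmi(truth, pred), nmi_oracle(truth, pred), tolerance = 1e-10)
    }
  })
})

test_that("neighbor affinity is the squared-overlap ratio", {
  expect_equal(neighbor_affinity(letters[1:4], letters[1:4]), 1)
  expect_equal(neighbor_affinity(c("a", "b", "c", "d"), c("a", "b", "x", "y")), 0.25)
  expect_equal(neighbor_affinity(c("a", "b"), c("x", "y")), 0)
  expect_error(neighbor_affinity(character(0), "a"), "nonempty")
})

test_that("complex prediction reproduces the worked toy exactly", {
  clusters <- list(c("a", "b", "c", "d"), c("e", "f"))
  refs <- list(c("a", "b", "c", "d"), c("g", "h"), c("e", "x"))
  rep_ <- complex_prediction(clusters, refs)
  expect_equal(rep_$precision, 1 / 2)
  expect_equal(rep_$recall, 1 / 3)
  expect_equal(rep_$f_measure, 0.4)
  expect_equal(rep_$matched_clusters, 1L)
  expect_equal(rep_$matched_references, 1L)

  # identical sets: everything perfect
  perfect <- complex_prediction(refs, refs)
  expect_equal(perfect$f_measure, 1)
  # disjoint: all zero, F defined 0
  none <- complex_prediction(list(c("q", "r")), refs[2])
  expect_equal(none$f_measure, 0)

  # invariant to ordering of clusters and references
  shuffled <- complex_prediction(rev(clusters), refs[c(3, 1, 2)])
  expect_equal(shuffled$f_measure, rep_$f_measure)
})

test_that("information content uses base 10 so the 1% filter sits at 2", {
  expect_equal(information_content(50, 50), 0)
  expect_equal(information_content(1, 100), 2)
  expect_true(information_content(1, 1000) > information_content(10, 1000))
  expect_error(information_content(0, 10), "positive")
})

test_that("hypergeometric p-values match exhaustive enumeration", {
  expect_equal(hypergeom_pvalue(10, 5, 5, 5), 1 / 252, tolerance = 1e-15)
  expect_equal(hypergeom_pvalue(10, 5, 5, 0), 1)
  # strictly decreasing in the overlap
  ps <- vapply(0:5, function(m) hypergeom_pvalue(12, 6, 6, m), 0)
  expect_true(all(diff(ps) < 0))
  expect_error(hypergeom_pvalue(10, 5, 5, 6), "min")

  for (N in 1:12) {
    for (M in 0:N) {
      for (n in 0:N) {
        for (m in max(0, n + M - N):min(M, n)) {
          expect_equal(
            hypergeom_pvalue(N, M, n, m),
            hyper_oracle(N, M, n, m),
            tolerance = 1e-12
          )
        }
      }
    }
  }
})

test_that("enrichment filters by IC, takes minima, and applies the strict threshold", {
  ann <- tibble::tibble(
    term = c("GO:specific", "GO:broad"),
    root_size = c(500L, 500L),
    members = list(sprintf("p%d", 1:5), sprintf("p%d", 1:100))
  )
  # GO:broad has IC = -log10(100/500) < 2 and must be filtered out
  clusters <- list(big = sprintf("p%d", 1:5))
  rep_ <- enrichment(clusters, ann, universe = 10)
  expect_equal(rep_$clusters$best_term, "GO:specific")
  expect_equal(rep_$clusters$p_min, 1 / 252, tolerance = 1e-12)
  # 1/252 ~ 3.97e-3 is NOT below the strict 1e-3 threshold
  expect_equal(rep_$n_enriched, 0L)
  # but is below a 5e-3 threshold
  expect_equal(enrichment(clusters, ann, universe = 10, alpha = 5e-3)$n_enriched, 1L)

  # clusters with no annotated proteins enrich nothing
  rep0 <- enrichment(list(c("q1", "q2", "q3")), ann, universe = 10)
  expect_equal(rep0$n_enriched, 0L)
  expect_equal(rep0$clusters$p_min, 1)

  expect_warning(
    repNA <- enrichment(clusters, ann[2, ], universe = 500),
    "information-content"
  )
  expect_equal(repNA$n_enriched, 0L)
})

test_that("a strongly over-represented cluster is enriched below 1e-3", {
  ann <- tibble::tibble(
    term = "GO:x", root_size = 1000L,
    members = list(sprintf("p%d", 1:8))
  )
  p <- hypergeom_pvalue(50, 8, 8, 8)
  expect_lt(p, 1e-3)
  rep_ <- enrichment(list(sprintf("p%d", 1:8)), ann, universe = 50)
  expect_equal(rep_$n_enriched, 1L)
  expect_equal(rep_$clusters$p_min, p)
})

test_that("benchmark tables summarize and plot", {
  cfg <- synthetic_pair_config(modules1 = c(6, 6), modules2 = c(5, 5), edge_density = 0.8, sim_density = 0.3)
  bm <- benchmark_noise(cfg, noise_grid = c(0, 0.3), replicates = 2, seed = 1)
  expect_s3_class(bm, "noise_benchmark")
  expect_equal(nrow(bm), 2 * 2 * 3)
  s <- summary(bm)
  expect_named(s, c("noise", "method", "mean_nmi", "sd_nmi", "n"))
  expect_true(all(s$n == 2))
  expect_s3_class(autoplot(bm), "ggplot")
})
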