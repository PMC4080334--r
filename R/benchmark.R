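#' Noise-sweep benchmark: joint clustering vs single-network baselines
#'
#' For each noise level, generates `replicates` synthetic pairs (seeds
#' `seed + 0 ... seed + replicates - 1`, the same batch at every level),
#' runs the joint model on the pair and the normalized-cut baseline on each
#' constituent network, and scores every run by NMI against the planted
#' modules. The joint model is scored on all `N1 + N2` nodes against the
#' joint truth (orthologous module pairs share a label); each baseline is
#' scored on its own network's truth.
#'
#' @param config Base [synthetic_pair_config()]; its `noise` field is
#'   overridden by `noise_grid`.
#' @param noise_grid Noise levels to sweep.
#' @param replicates Replicate pairs per level.
#' @param k Number of clusters; defaults to the module count.
#' @param seed Base seed.
#' @param methods Subset of `c("asmodel", "ncut1", "ncut2")`.
#' @return A tibble of class `noise_benchmark`: `noise`, `replicate`,
#'   `method`, `nmi`.
#' @export
benchmark_noise <- function(config = synthetic_pair_config(),
                            noise_grid = seq(0, 0.5, by = 0.1),
                            replicates = 30L,
                            k = NULL,
                            seed = 1L,
                            methods = c("asmodel", "ncut1", "ncut2")) {
  methods <- match.arg(methods, several.ok = TRUE)
  k <- k %||% length(config$modules1)
  rows <- list()
  for (noise in noise_grid) {
    cfg <- synthetic_pair_config(
      modules1 = config$modules1, modules2 = config$modules2,
      edge_density = config$edge_density, sim_density = config$sim_density,
      noise = noise
    )
    for (r in seq_len(replicates)) {
      pair <- generate_pair(cfg, seed = seed + r - 1L)
      scores <- benchmark_one(pair, k = k, seed = seed, methods = methods)
      rows[[length(rows) + 1L]] <- tibble(
        noise = noise, replicate = r,
        method = names(scores), nmi = unname(scores)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("noise_benchmark", class(out))
  out
}

benchmark_one <- function(pair, k, seed, methods) {
  scores <- c()
  if ("asmodel" %in% methods) {
    fit <- suppressWarnings(asmodel(pair$net1, pair$net2, pair$sim, k = k, seed = seed))
    truth <- c(pair$truth1$module, pair$truth2$module)
    scores <- c(scores, asmodel = nmi(truth, fit$assignment$cluster))
  }
  if ("ncut1" %in% methods) {
    fit <- suppressWarnings(ncut_single(pair$net1, k = k, seed = seed))
    scores <- c(scores, ncut1 = nmi(pair$truth1$module, fit$assignment$cluster))
  }
  if ("ncut2" %in% methods) {
    fit <- suppressWarnings(ncut_single(pair$net2, k = k, seed = seed))
    scores <- c(scores, ncut2 = nmi(pair$truth2$module, fit$assignment$cluster))
  }
  scores
}

#' Summarize a noise benchmark
#'
#' @param object A `noise_benchmark` tibble from [benchmark_noise()].
#' @param ... Unused.
#' @return Tibble with mean and SD of NMI per noise level and method.
#' @export
summary.noise_benchmark <- function(object, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(object), .data$noise, .data$method),
    mean_nmi = mean(.data$nmi),
    sd_nmi = stats::sd(.data$nmi),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' @describeIn benchmark_noise Mean-NMI-vs-noise curves with one-SD error
#'   bars, one curve per method.
#' @param object A `noise_benchmark`.
#' @param ... Unused.
#' @export
autoplot.noise_benchmark <- function(object, ...) {
  s <- summary(object)
  ggplot2::ggplot(s, ggplot2::aes(
    x = .data$noise, y = .data$mean_nmi,
    color = .data$method, group = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_nmi - .data$sd_nmi,
        ymax = .data$mean_nmi + .data$sd_nmi
      ),
      width = 0.01
    ) +
    ggplot2::labs(
      x = "noise level (fraction of edges rewired)",
      y = "NMI vs planted modules",
      color = "method"
    ) +
    ggplot2::ylim(0, 1)
}
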