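# Benchmark harness: run the loop under several acquisition strategies and
# seeds on synthetic data and compare labeling effort.

#' Benchmark acquisition strategies on synthetic data
#'
#' For each seed a fresh pool is generated from `spec` (imbalanced 3-class
#' preset by default), embedded with the oracle embedding, and the loop is
#' run once per strategy in benchmark evaluation mode (`eval = "pool"`:
#' accuracy against the full pool's ground truth, as when replaying a fully
#' annotated dataset). Every strategy sees the same pools.
#'
#' @param spec A [dataset_spec()]; `n_items` etc. define the fixture. The
#'   spec's own seed is ignored — seeds come from `seeds`.
#' @param strategies Character vector of [select_batch()] strategies.
#' @param seeds Integer vector of seeds (one run per strategy per seed).
#' @param cfg A [loop_config()]; `strategy`, `seed` and `eval` are
#'   overridden per run.
#' @return An `al_benchmark` list: `results` (one row per run, see
#'   [glance.al_run()]), `curves` (long tibble of all learning curves),
#'   `target_accuracy`.
#' @export
run_benchmark <- function(spec,
                          strategies = c("random", "entropy", "beta_mi"),
                          seeds = 1:10,
                          cfg = loop_config(max_rounds = 1000L)) {
  results <- list(); curves <- list()
  for (s in seeds) {
    pool_spec <- spec
    pool_spec$seed <- as.integer(s)
    pool <- generate_latent(pool_spec)
    emb <- oracle_embed(pool)
    for (strat in strategies) {
      run_cfg <- cfg
      run_cfg$strategy <- strat
      run_cfg$seed <- as.integer(s)
      run_cfg$eval <- "pool"
      run <- run_al(pool, emb, run_cfg)
      results[[length(results) + 1L]] <- glance(run)
      curves[[length(curves) + 1L]] <- run$curve %>%
        dplyr::mutate(strategy = strat, seed = s)
    }
  }
  structure(
    list(results = dplyr::bind_rows(results),
         curves = dplyr::bind_rows(curves),
         target_accuracy = cfg$target_accuracy),
    class = "al_benchmark"
  )
}

#' @export
tidy.al_benchmark <- function(x, ...) x$curves

#' Per-strategy summary of a benchmark
#'
#' Fractions-to-reach of `Inf` (target never reached) are counted as 1 — the
#' campaign would have had to label everything.
#'
#' @param object An `al_benchmark`.
#' @param ... Unused.
#' @return A tibble with one row per strategy: mean/sd fraction-to-reach,
#'   mean AUC, mean final accuracy, number of seeds.
#' @export
summary.al_benchmark <- function(object, ...) {
  object$results %>%
    dplyr::mutate(ftr = pmin(.data$fraction_to_reach, 1)) %>%
    dplyr::group_by(.data$strategy) %>%
    dplyr::summarise(
      mean_fraction_to_reach = mean(.data$ftr),
      sd_fraction_to_reach = stats::sd(.data$ftr),
      mean_auc = mean(.data$auc),
      mean_final_accuracy = mean(.data$final_accuracy),
      n_seeds = dplyr::n(),
      .groups = "drop"
    )
}

#' Paired one-sided comparison of labeling effort between two strategies
#'
#' Wilcoxon signed-rank test, paired by seed, of the hypothesis that
#' `strategy_a` reaches the target accuracy with a *smaller* labeled
#' fraction than `strategy_b`. `Inf` fractions are treated as 1.
#'
#' @param bench An `al_benchmark` containing both strategies.
#' @param strategy_a The strategy claimed to be more label-efficient.
#' @param strategy_b The baseline (e.g. `"random"`).
#' @return A one-row tibble: mean fractions for both strategies, their
#'   difference, and the one-sided p-value.
#' @export
compare_strategies <- function(bench, strategy_a = "beta_mi", strategy_b = "random") {
  res <- bench$results %>%
    dplyr::mutate(ftr = pmin(.data$fraction_to_reach, 1)) %>%
    dplyr::filter(.data$strategy %in% c(strategy_a, strategy_b)) %>%
    dplyr::select("strategy", "seed", "ftr") %>%
    tidyr::pivot_wider(names_from = "strategy", values_from = "ftr")
  a <- res[[strategy_a]]; b <- res[[strategy_b]]
  p <- if (all(a == b)) 1 else {
    suppressWarnings(
      stats::wilcox.test(b, a, paired = TRUE, alternative = "greater")$p.value
    )
  }
  tibble::tibble(
    strategy_a = strategy_a, strategy_b = strategy_b,
    mean_a = mean(a), mean_b = mean(b),
    mean_saving = mean(b) - mean(a), p_value = p, n_seeds = length(a)
  )
}

#' Plot a single learning curve
#'
#' @param object A `learning_curve` tibble.
#' @param ... Unused.
#' @return A ggplot: accuracy against fraction of the pool labeled.
#' @export
autoplot.learning_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction_labeled,
                                       y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Fraction of pool labeled", y = "Accuracy") +
    ggplot2::theme_minimal()
}

#' Plot mean benchmark curves with 2-SD ribbons
#'
#' Curves are averaged over seeds at each recorded labeled fraction; the
#' ribbon spans two standard deviations about the mean, the convention used
#' to display run-to-run variability of labeling campaigns.
#'
#' @param object An `al_benchmark`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.al_benchmark <- function(object, ...) {
  agg <- object$curves %>%
    dplyr::group_by(.data$strategy, .data$fraction_labeled) %>%
    dplyr::summarise(mean = mean(.data$accuracy),
                     sd = stats::sd(.data$accuracy),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(sd = ifelse(is.na(.data$sd), 0, .data$sd))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$fraction_labeled, y = .data$mean,
                                    colour = .data$strategy,
                                    fill = .data$strategy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                                      ymax = .data$mean + 2 * .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$target_accuracy, linetype = "dashed") +
    ggplot2::labs(x = "Fraction of pool labeled", y = "Accuracy",
                  colour = "Strategy", fill = "Strategy") +
    ggplot2::theme_minimal()
}
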