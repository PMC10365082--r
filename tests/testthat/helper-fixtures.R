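# Shared fixtures, built in code and cached across test files (helpers are
# sourced once per test session). The heavier fixtures — the strategy
# benchmark and the lesion-localization evaluation — are computed lazily on
# first use.

.al_test_cache <- new.env(parent = emptyenv())

# Benchmark on the standard imbalanced fixture: N = 600 items with the
# 8,851/6,063/601 class-proportion preset, oracle embeddings, batch 20,
# 10 seeds, target accuracy 0.90.
cached_benchmark <- function() {
  if (is.null(.al_test_cache$bench)) {
    .al_test_cache$bench <- run_benchmark(
      dataset_spec(n_items = 600),
      strategies = c("random", "entropy", "beta_mi"),
      seeds = 1:10,
      cfg = loop_config(batch_size = 20L, max_rounds = 1000L,
                        target_accuracy = 0.9)
    )
  }
  .al_test_cache$bench
}

# 50 seeded lesion images and their top-1 proposal IoUs vs the true boxes.
cached_lesion_eval <- function() {
  if (is.null(.al_test_cache$lesion)) {
    pool <- generate_images(dataset_spec(n_items = 50, lesion_frac = 1,
                                         image_size = c(64L, 64L), seed = 11))
    props <- propose_boxes(pool, seed = 42)
    top1 <- props %>%
      dplyr::group_by(image_id) %>%
      dplyr::slice(1) %>%
      dplyr::ungroup()
    iou <- vapply(seq_len(nrow(top1)), function(i) {
      truth <- pool$lesion[[match(top1$image_id[i], pool$id)]]
      box_iou(unlist(top1[i, c("x", "y", "w", "h")]), truth)
    }, numeric(1))
    .al_test_cache$lesion <- list(pool = pool, props = props,
                                  top1 = top1, iou = iou)
  }
  .al_test_cache$lesion
}

# A small well-separated 3-class latent pool for learner/cold-start tests.
separable_pool <- function(n = 300, separation = 6, noise_sd = 0.5, seed = 2) {
  generate_latent(dataset_spec(n_items = n, class_proportions = c(1, 1, 1),
                               separation = separation, noise_sd = noise_sd,
                               seed = seed))
}

# Squared cross-distances, written out independently of the package internals.
cross_dist2_test <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

# Build an al_posterior by hand from top-class means/variances (2 classes).
manual_posterior <- function(ids, mu_top, var_top) {
  prob <- cbind(mu_top, 1 - mu_top)
  structure(list(ids = ids, mean = prob, var = cbind(var_top, var_top),
                 prob = prob), class = "al_posterior")
}
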