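test_that("the stopping rule follows its truth table", {
  cfg <- loop_config(target_accuracy = 0.9, patience_rounds = 2, min_gain = 0.01)
  expect_identical(stopping_rule(c(0.5, 0.93), cfg),
                   list(stop = TRUE, reason = "target_reached"))
  expect_identical(stopping_rule(c(0.80, 0.801, 0.802), cfg),
                   list(stop = TRUE, reason = "plateau"))

  cfg2 <- loop_config(target_accuracy = 0.99, patience_rounds = 3, min_gain = 0.01)
  expect_false(stopping_rule(seq(0.5, 0.8, by = 0.05), cfg2)$stop)
  expect_false(stopping_rule(c(0.5), cfg2)$stop)   # too short for a plateau call
  expect_error(stopping_rule(numeric(0), cfg), class = "activelabel_usage_error")
})

test_that("loop configs are validated", {
  expect_error(loop_config(test_fraction = 0), class = "activelabel_config_error")
  expect_error(loop_config(target_accuracy = 1.2), class = "activelabel_config_error")
  expect_error(loop_config(patience_rounds = 0), class = "activelabel_config_error")
  expect_error(loop_config(batch_size = 0), class = "activelabel_config_error")
})

test_that("a single-round budget human-labels one batch and auto-labels the rest", {
  pool <- generate_latent(dataset_spec(n_items = 120, seed = 31))
  emb <- oracle_embed(pool)
  run <- run_al(pool, emb, loop_config(batch_size = 20, max_rounds = 1,
                                       target_accuracy = 0.999, seed = 1))
  expect_identical(run$state$n_human, 20L)
  expect_identical(run$state$n_auto, 100L)
  expect_true(all(run$pool$status %in% c("human", "auto")))
})

test_that("a batch covering the pool human-labels everything", {
  pool <- generate_latent(dataset_spec(n_items = 50, seed = 32))
  emb <- oracle_embed(pool)
  run <- run_al(pool, emb, loop_config(batch_size = 60, max_rounds = 3,
                                       target_accuracy = 0.999))
  expect_identical(run$state$n_human, 50L)
  expect_identical(run$state$n_auto, 0L)
  expect_identical(run$state$stopped_reason, "pool_exhausted")
})

test_that("after any run the status partition is exhaustive and rounds grow", {
  pool <- generate_latent(dataset_spec(n_items = 200, seed = 33))
  emb <- oracle_embed(pool)
  for (strategy in c("random", "beta_mi")) {
    run <- run_al(pool, emb, loop_config(batch_size = 20, max_rounds = 6,
                                         target_accuracy = 0.95,
                                         strategy = strategy, seed = 4))
    expect_true(all(run$pool$status %in% c("human", "auto")))
    expect_true(all(!is.na(run$pool$label)))
    # labeled fraction strictly grows round over round
    expect_true(all(diff(run$curve$fraction_labeled) > 0))
    # no item is labeled twice: human rounds partition the human set
    human <- run$pool[run$pool$status == "human", ]
    expect_identical(nrow(human), run$state$n_human)
    expect_true(all(table(human$round) <= run$config$batch_size))
  }
})

test_that("the loop reaches target accuracy before exhausting a learnable pool", {
  bench <- cached_benchmark()
  res <- bench$results
  for (strategy in unique(res$strategy)) {
    expect_true(any(res$fraction_to_reach[res$strategy == strategy] < 1))
  }
})

test_that("pre-labeling transfers from a disjoint same-generator dataset", {
  train_pool <- generate_latent(dataset_spec(n_items = 300, seed = 41))
  train_emb <- oracle_embed(train_pool)
  model <- gp_fit(train_emb, train_pool$true_label)

  new_pool <- generate_latent(dataset_spec(n_items = 200, seed = 42))
  new_emb <- oracle_embed(new_pool)
  prop <- apply_prelabels(model, new_pool, new_pool$id, new_emb)
  expect_identical(nrow(prop), 200L)
  expect_true(all(prop$confidence > 0 & prop$confidence <= 1))
  acc <- mean(prop$proposed_label == new_pool$true_label)
  prior_max <- max(table(new_pool$true_label)) / 200
  expect_gte(acc, prior_max)

  # no model configured: identity, no proposals, no error
  none <- apply_prelabels(NULL, new_pool, new_pool$id, new_emb)
  expect_identical(nrow(none), 0L)
})

test_that("the review pass corrects exactly the wrong auto-labels", {
  pool <- generate_latent(dataset_spec(n_items = 1000, class_proportions = c(1, 1),
                                       seed = 51))
  # construct a pool whose auto-labels are wrong at a known binomial rate
  for (s in 1:5) {
    p <- pool
    p$status <- "auto"
    p$round <- 0L
    flips <- withr::with_seed(s, runif(1000) < 0.1)
    p$label <- ifelse(flips, 3L - p$true_label, p$true_label)
    rep <- review_pass(p)
    expect_identical(rep$n_auto, 1000L)
    expect_identical(rep$n_corrected, sum(flips))
    expect_lt(abs(rep$n_corrected / rep$n_auto - 0.1), 0.03)
    expect_true(all(rep$pool$status == "reviewed"))
    expect_identical(rep$pool$label, rep$pool$true_label)
  }
  # perfect learner: nothing to correct
  perfect <- pool
  perfect$status <- "auto"; perfect$label <- perfect$true_label
  expect_identical(review_pass(perfect)$n_corrected, 0L)
  # adversarial learner: everything corrected
  wrong <- pool
  wrong$status <- "auto"; wrong$label <- 3L - wrong$true_label
  expect_identical(review_pass(wrong)$n_corrected, 1000L)
})

test_that("curve metrics match hand computations", {
  curve <- tibble::tibble(fraction_labeled = 0.1, accuracy = 0.95)
  m <- curve_metrics(curve, 0.9)
  expect_equal(m$fraction_to_reach, 0.1)

  flat <- tibble::tibble(fraction_labeled = c(0.1, 0.3, 0.6), accuracy = 0.8)
  expect_equal(curve_metrics(flat, 0.9)$auc, 0.8 * 0.5, tolerance = 1e-12)
  expect_identical(curve_metrics(flat, 0.9)$fraction_to_reach, Inf)

  hand <- tibble::tibble(fraction_labeled = c(0.1, 0.2, 0.4, 0.5),
                         accuracy = c(0.5, 0.7, 0.8, 0.9))
  expect_equal(curve_metrics(hand, 0.9)$auc,
               0.1 * 0.6 + 0.2 * 0.75 + 0.1 * 0.85, tolerance = 1e-12)
  expect_equal(curve_metrics(hand, 0.9)$fraction_to_reach, 0.5)
  expect_equal(curve_metrics(hand, 0.9)$final_accuracy, 0.9)
})

test_that("label request/response files round-trip a human labeling round", {
  pool <- generate_latent(dataset_spec(n_items = 30, seed = 61))
  dir <- withr::local_tempdir()
  ids <- pool$id[1:5]
  path <- write_label_request(ids, round = 0, dir = dir)
  expect_true(file.exists(path))
  resp <- data.frame(id = ids, label = pool$true_label[1:5])
  resp_path <- file.path(dir, "labels_round_0.csv")
  utils::write.csv(resp, resp_path, row.names = FALSE)
  pool2 <- read_label_response(pool, resp_path, round = 0)
  expect_identical(pool2$label[1:5], pool2$true_label[1:5])
  expect_true(all(pool2$status[1:5] == "human"))
})

test_that("tidy and glance expose the run as tables", {
  pool <- generate_latent(dataset_spec(n_items = 100, seed = 71))
  emb <- oracle_embed(pool)
  run <- run_al(pool, emb, loop_config(batch_size = 20, max_rounds = 3,
                                       target_accuracy = 0.95))
  expect_s3_class(tidy(run), "tbl_df")
  g <- glance(run)
  expect_identical(nrow(g), 1L)
  expect_identical(g$n_human + g$n_auto, 100L)
})
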