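# Independent oracle: dense one-vs-rest GP regression by explicit matrix
# inversion, written with none of the package's linear-algebra helpers.
dense_gp_oracle <- function(X, labels, Xs, ls, jitter, n_classes) {
  rbf <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    exp(-pmax(d2, 0) / (2 * ls^2))
  }
  K <- rbf(X, X) + diag(jitter, nrow(X))
  Kinv <- solve(K)
  Y <- matrix(0, nrow(X), n_classes)
  Y[cbind(seq_along(labels), labels)] <- 1
  Ks <- rbf(Xs, X)
  list(mean = Ks %*% Kinv %*% Y,
       var = 1 - diag(Ks %*% Kinv %*% t(Ks)))
}

test_that("the GP posterior matches a dense linear-algebra oracle", {
  withr::with_seed(3, {
    X <- matrix(rnorm(36), 12, 3)
    labels <- rep(1:3, each = 4)
    Xs <- matrix(rnorm(24), 8, 3)
  })
  emb <- activelabel:::embedding_tibble(sprintf("t%02d", 1:12), X)
  new <- activelabel:::embedding_tibble(sprintf("q%02d", 1:8), Xs)
  cfg <- gp_config(length_scale = 1.5, noise_jitter = 1e-4)
  model <- gp_fit(emb, labels, cfg)
  post <- predict(model, new)
  oracle <- dense_gp_oracle(X, labels, Xs, ls = 1.5, jitter = 1e-4, n_classes = 3)
  expect_equal(post$mean, oracle$mean, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(post$var[, 1], oracle$var, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the noiseless GP interpolates its training targets", {
  withr::with_seed(4, X <- matrix(rnorm(20), 10, 2))
  labels <- rep(1:2, 5)
  emb <- activelabel:::embedding_tibble(letters[1:10], X)
  model <- gp_fit(emb, labels, gp_config(length_scale = 1, noise_jitter = 1e-9))
  post <- predict(model, emb)
  onehot <- matrix(0, 10, 2)
  onehot[cbind(1:10, labels)] <- 1
  expect_equal(post$mean, onehot, tolerance = 1e-3, ignore_attr = TRUE)
  expect_true(all(post$var <= 1e-3))
})

test_that("a query equidistant from two opposite-class points is undecided", {
  emb <- activelabel:::embedding_tibble(c("a", "b"), rbind(c(-1, 0), c(1, 0)))
  model <- gp_fit(emb, c(1, 2), gp_config(length_scale = 1))
  post <- predict(model, activelabel:::embedding_tibble("q", rbind(c(0, 0))))
  expect_equal(as.numeric(post$prob), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("far queries revert to the prior and probabilities are proper", {
  pool <- separable_pool(n = 60, separation = 4, noise_sd = 0.5)
  emb <- oracle_embed(pool)
  model <- gp_fit(emb, pool$true_label, gp_config(length_scale = 1))
  far <- activelabel:::embedding_tibble("far", matrix(100, 1, 8))
  post <- predict(model, far)
  expect_equal(as.numeric(post$mean), rep(0, 3), tolerance = 1e-6)
  expect_equal(post$var[1, 1], 1, tolerance = 1e-6)
  pool_post <- predict(model, emb)
  expect_true(all(abs(rowSums(pool_post$prob) - 1) < 1e-9))
  expect_true(all(pool_post$prob >= 0 & pool_post$prob <= 1))
  expect_true(all(pool_post$var >= 0))
})

test_that("variance at training points is below variance far away", {
  pool <- separable_pool(n = 40, separation = 4, noise_sd = 0.5)
  emb <- oracle_embed(pool)
  model <- gp_fit(emb, pool$true_label)
  at_train <- predict(model, emb)
  far <- activelabel:::embedding_tibble("far", matrix(1e3, 1, 8))
  expect_true(all(at_train$var[, 1] <= predict(model, far)$var[1, 1]))
})

test_that("fit and predict are deterministic", {
  pool <- separable_pool(n = 80, separation = 3, noise_sd = 1)
  emb <- oracle_embed(pool)
  p1 <- predict(gp_fit(emb, pool$true_label), emb)
  p2 <- predict(gp_fit(emb, pool$true_label), emb)
  expect_identical(p1, p2)
})

test_that("accuracy is invariant under consistent class relabeling", {
  pool <- separable_pool(n = 120, separation = 3, noise_sd = 1, seed = 9)
  emb <- oracle_embed(pool)
  train <- 1:80; test <- 81:120
  acc <- gp_evaluate(gp_fit(emb[train, ], pool$true_label[train]),
                     emb[test, ], pool$true_label[test])
  perm <- c(3L, 1L, 2L)
  acc_perm <- gp_evaluate(gp_fit(emb[train, ], perm[pool$true_label[train]]),
                          emb[test, ], perm[pool$true_label[test]])
  expect_equal(acc, acc_perm)
})

test_that("the learner separates a 3-class oracle-embedded fixture", {
  pool <- generate_latent(dataset_spec(n_items = 300, class_proportions = c(1, 1, 1),
                                       separation = 6, noise_sd = 0.5, seed = 12))
  emb <- oracle_embed(pool)
  withr::with_seed(1, train <- sample(300, 100))
  model <- gp_fit(emb[train, ], pool$true_label[train])
  acc <- gp_evaluate(model, emb[-train, ], pool$true_label[-train])
  expect_gte(acc, 0.95)
})

test_that("degenerate and malformed inputs raise the documented errors", {
  pool <- separable_pool(n = 30)
  emb <- oracle_embed(pool)
  expect_error(gp_fit(emb, rep(1L, 30)), class = "activelabel_degenerate_model")
  model <- gp_fit(emb, pool$true_label)
  wrong_dim <- activelabel:::embedding_tibble("x", matrix(0, 1, 3))
  expect_error(predict(model, wrong_dim), class = "activelabel_usage_error")
  expect_error(gp_evaluate(model, emb[0, ], integer(0)), class = "activelabel_usage_error")
})

test_that("hand-built evaluation counts match", {
  # 7 of 10 argmax predictions equal the labels -> accuracy 0.7
  emb <- activelabel:::embedding_tibble(sprintf("p%d", 1:4),
                                        rbind(c(0, 0), c(0, 1), c(4, 4), c(4, 5)))
  model <- gp_fit(emb, c(1, 1, 2, 2), gp_config(length_scale = 1))
  test_emb <- activelabel:::embedding_tibble(
    sprintf("t%02d", 1:10),
    rbind(c(0, 0.5), c(0, 0.4), c(0.2, 0), c(4, 4.5), c(4.2, 4), c(3.8, 4.4),
          c(0.1, 0.6), c(0, 0.2), c(4, 4.2), c(3.9, 4.6))
  )
  pred <- apply(predict(model, test_emb)$prob, 1, which.max)
  truth <- ifelse(pred == 1, 1L, 2L)          # start from all-correct labels
  truth[c(1, 5, 9)] <- 3L - truth[c(1, 5, 9)] # then force exactly 3 mismatches
  expect_equal(gp_evaluate(model, test_emb, truth), 0.7)
})
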