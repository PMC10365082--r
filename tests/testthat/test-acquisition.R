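test_that("entropy_score reproduces reference values", {
  expect_equal(entropy_score(rep(1 / 3, 3)), log(3), tolerance = 1e-12)
  expect_equal(entropy_score(c(1, 0, 0)), 0)
  expect_equal(entropy_score(c(0.5, 0.3, 0.2)),
               -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)),
               tolerance = 1e-12)
  expect_error(entropy_score(c(-0.1, 1.1)), class = "activelabel_usage_error")
})

test_that("beta_match solves the moment equations", {
  uniform <- beta_match(0.5, 1 / 12)
  expect_equal(uniform$alpha, 1, tolerance = 1e-12)
  expect_equal(uniform$beta, 1, tolerance = 1e-12)

  # sigma2 -> 0 concentrates the Beta
  tight <- beta_match(0.5, 1e-8)
  expect_gt(tight$alpha, 1e6)
  expect_equal(tight$alpha, tight$beta, tolerance = 1e-9)

  # round trip: matched Beta reproduces the requested mean and variance
  withr::with_seed(21, {
    mu <- runif(100, 0.01, 0.99)
    s2 <- runif(100) * mu * (1 - mu) * 0.98 + 1e-8
    m <- beta_match(mu, s2)
    mean_back <- m$alpha / (m$alpha + m$beta)
    var_back <- m$alpha * m$beta /
      ((m$alpha + m$beta)^2 * (m$alpha + m$beta + 1))
    expect_equal(mean_back, mu, tolerance = 1e-9)
    expect_equal(var_back, s2, tolerance = 1e-9)
  })

  # over-dispersed variance is clipped, out-of-range mean warns
  clipped <- beta_match(0.5, 0.4)
  expect_equal(clipped$var, 0.999 * 0.25, tolerance = 1e-12)
  expect_warning(beta_match(1.5, 0.01), "clipping")
  expect_error(beta_match(0.5, -1), class = "activelabel_usage_error")
})

test_that("beta_mi_score has its closed-form values and limits", {
  # uniform Beta: E int -p log p dp = 1/4 twice, so MI = log 2 - 1/2
  expect_equal(beta_mi_score(beta_match(0.5, 1 / 12)), log(2) - 0.5,
               tolerance = 1e-9)
  # vanishing epistemic uncertainty: MI -> 0
  expect_lt(beta_mi_score(beta_match(0.3, 1e-10)), 1e-6)
  # bounded by the binary entropy of the mean
  m <- beta_match(0.3, 0.05)
  mi <- beta_mi_score(m)
  expect_gte(mi, 0)
  expect_lte(mi, -0.3 * log(0.3) - 0.7 * log(0.7))
})

test_that("closed-form Beta mutual information agrees with Monte Carlo", {
  withr::with_seed(33, {
    for (i in 1:50) {
      alpha <- runif(1, 0.3, 20)
      beta <- runif(1, 0.3, 20)
      m <- tibble::tibble(mu = alpha / (alpha + beta),
                          var = alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1)),
                          alpha = alpha, beta = beta)
      class(m) <- c("beta_moments", class(m))
      closed <- beta_mi_score(m)

      draws <- rbeta(1e5, alpha, beta)
      hb <- function(p) {
        out <- -p * log(p) - (1 - p) * log(1 - p)
        out[p <= 0 | p >= 1] <- 0
        out
      }
      mc <- hb(mean(draws)) - mean(hb(draws))
      # standard error: MC error of E[H_b] plus delta-method error of H_b(mean)
      se <- sqrt(var(hb(draws)) / 1e5 +
                   (log((1 - mean(draws)) / mean(draws)))^2 * var(draws) / 1e5)
      expect_lt(abs(closed - mc), 3 * se + 1e-6)
    }
  })
})

test_that("beta_mi_score increases strictly with epistemic variance", {
  for (mu in c(0.2, 0.4, 0.5, 0.7, 0.9)) {
    s2 <- mu * (1 - mu) * seq(0.05, 0.9, by = 0.05)
    scores <- beta_mi_score(beta_match(rep(mu, length(s2)), s2))
    expect_true(all(diff(scores) > 0))
  }
})

test_that("Monte-Carlo BALD matches exact truncated-normal integration", {
  # independent oracle: numerical quadrature of the truncated-normal MI
  tn_mi <- function(mu, s2, eps = 1e-6) {
    sd <- sqrt(s2)
    Z <- pnorm((1 - eps - mu) / sd) - pnorm((eps - mu) / sd)
    dens <- function(p) dnorm((p - mu) / sd) / (sd * Z)
    hb <- function(p) ifelse(p > 0 & p < 1, -p * log(p) - (1 - p) * log(1 - p), 0)
    Ep <- integrate(function(p) p * dens(p), eps, 1 - eps, rel.tol = 1e-10)$value
    Eh <- integrate(function(p) hb(p) * dens(p), eps, 1 - eps, rel.tol = 1e-10)$value
    hb(Ep) - Eh
  }
  for (mu in c(0.2, 0.35, 0.5, 0.65, 0.8)) {
    for (f in c(0.1, 0.3, 0.5)) {
      s2 <- f * mu * (1 - mu)
      expect_lt(abs(bald_mc_score(mu, s2, n_samples = 20000, seed = 3) -
                      tn_mi(mu, s2)), 0.01)
    }
  }
  expect_lt(bald_mc_score(0.5, 1e-12, n_samples = 1000, seed = 1), 1e-4)
  expect_identical(bald_mc_score(0.4, 0.02, seed = 5),
                   bald_mc_score(0.4, 0.02, seed = 5))
  expect_error(bald_mc_score(0.5, 0.1, n_samples = 1), class = "activelabel_usage_error")
})

test_that("Beta-MI and Monte-Carlo BALD agree at moderate relative variance", {
  # the two scores share moments but not shape; they stay within 0.05 nats
  # of each other while the variance is a modest fraction of mu(1 - mu)
  for (mu in c(0.2, 0.35, 0.5, 0.65, 0.8)) {
    for (f in c(0.05, 0.1, 0.2)) {
      s2 <- f * mu * (1 - mu)
      expect_lt(abs(bald_mc_score(mu, s2, n_samples = 5000, seed = 3) -
                      beta_mi_score(beta_match(mu, s2))), 0.05)
    }
  }
})

test_that("select_batch ranks by score with id tie-breaks and respects the pool", {
  withr::with_seed(8, {
    ids <- sprintf("u%02d", 1:20)
    mu <- runif(20, 0.4, 0.95)
    s2 <- runif(20, 0.001, 0.1)
  })
  post <- manual_posterior(ids, mu, s2)

  sel <- select_batch(post, ids, "beta_mi", batch_size = 6)
  # brute-force oracle: sort per-item scores computed one at a time
  brute <- vapply(seq_along(ids), function(i) {
    beta_mi_score(beta_match(max(mu[i], 1 - mu[i]), s2[i]))
  }, numeric(1))
  expect_identical(sel$ranking, ids[order(-brute, ids)])
  expect_identical(sel$selected, ids[order(-brute, ids)][1:6])

  # an undecided item outranks confident ones under entropy
  mu2 <- c(0.5, rep(0.999, 9))
  post2 <- manual_posterior(sprintf("v%02d", 1:10), mu2, rep(0.01, 10))
  sel2 <- select_batch(post2, sprintf("v%02d", 1:10), "entropy", 1)
  expect_identical(sel2$selected, "v01")

  # batch >= pool returns every unlabeled id
  expect_setequal(select_batch(post, ids, "entropy", 50)$selected, ids)
  expect_error(select_batch(post, ids, "magic", 5), class = "activelabel_usage_error")
})

test_that("every strategy returns a permutation prefix of the unlabeled set", {
  withr::with_seed(9, {
    ids <- sprintf("w%02d", 1:15)
    post <- manual_posterior(ids, runif(15, 0.34, 0.99), runif(15, 0.001, 0.2))
  })
  for (strategy in c("random", "entropy", "variance", "bald", "beta_mi")) {
    sel <- select_batch(post, ids, strategy, 4, seed = 2, mc_samples = 200)
    expect_length(sel$selected, 4)
    expect_true(all(sel$selected %in% ids))
    expect_setequal(sel$ranking, ids)
    expect_false(anyDuplicated(sel$ranking) > 0)
    expect_true(all(is.finite(sel$scores$score)))
  }
})

test_that("Beta-MI acquisition dominates random and entropy on the imbalanced fixture", {
  bench <- cached_benchmark()
  s <- summary(bench)
  ftr <- setNames(s$mean_fraction_to_reach, s$strategy)
  expect_lte(ftr[["beta_mi"]], ftr[["random"]])
  expect_lte(ftr[["beta_mi"]], ftr[["entropy"]])
})
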