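# Acquisition: rank unlabeled items by informativeness from the learner's
# posterior. Strategies: random, entropy, variance, Monte-Carlo BALD, and a
# Beta-moment-matched mutual-information score (Bayesian acquisition with a
# Beta approximation of the top-class probability).

#' Shannon entropy of a class-probability row
#'
#' @param prob Nonnegative probabilities summing to 1.
#' @return Entropy in nats, with the convention `0 * log(0) = 0`.
#' @examples
#' entropy_score(rep(1 / 3, 3)) # log(3)
#' @export
entropy_score <- function(prob) {
  if (any(prob < 0)) stop_usage("probabilities must be nonnegative")
  if (abs(sum(prob) - 1) > 1e-6) stop_usage("probabilities must sum to 1")
  -sum(ifelse(prob > 0, prob * log(prob), 0))
}

#' Match a Beta distribution to a mean and variance
#'
#' Given the predictive mean \eqn{\mu} and variance \eqn{\sigma^2} of a
#' probability (the learner's top-class probability), returns the Beta(\eqn{\alpha,
#' \beta}) with those first two moments:
#' \eqn{\nu = \mu(1-\mu)/\sigma^2 - 1}, \eqn{\alpha = \mu\nu},
#' \eqn{\beta = (1-\mu)\nu}. A variance at or above the Bernoulli bound
#' \eqn{\mu(1-\mu)} is clipped to \eqn{0.999\,\mu(1-\mu)} so the match stays
#' proper; a mean outside (0, 1) is clipped to `[1e-6, 1 - 1e-6]` with a
#' warning. Vectorized over `mu` and `sigma2`.
#'
#' @param mu Mean(s) of the probability, ideally in (0, 1).
#' @param sigma2 Positive variance(s).
#' @return A `beta_moments` tibble with columns `mu`, `var`, `alpha`, `beta`
#'   (post-clipping moments; the Beta reproduces them exactly).
#' @examples
#' beta_match(0.5, 1 / 12) # alpha = beta = 1, the uniform Beta
#' @export
beta_match <- function(mu, sigma2) {
  if (any(sigma2 <= 0)) stop_usage("sigma2 must be positive")
  if (any(mu <= 0 | mu >= 1)) {
    rlang::warn("mu outside (0, 1); clipping to [1e-6, 1 - 1e-6]")
    mu <- pmin(1 - 1e-6, pmax(1e-6, mu))
  }
  cap <- mu * (1 - mu)
  sigma2 <- ifelse(sigma2 >= cap, 0.999 * cap, sigma2)
  nu <- cap / sigma2 - 1
  out <- tibble::tibble(mu = mu, var = sigma2, alpha = mu * nu, beta = (1 - mu) * nu)
  class(out) <- c("beta_moments", class(out))
  out
}

# E[H_b(p)] for p ~ Beta(alpha, beta), closed form via digamma.
beta_expected_entropy <- function(alpha, beta) {
  s <- alpha + beta
  -(alpha / s) * (digamma(alpha + 1) - digamma(s + 1)) -
    (beta / s) * (digamma(beta + 1) - digamma(s + 1))
}

#' Beta-approximated mutual-information acquisition score
#'
#' Mutual information between the (binary) label and its probability
#' parameter under the matched Beta:
#' \deqn{MI = H_b(\mu) - E_{p \sim Beta(\alpha, \beta)}[H_b(p)]}
#' with \eqn{H_b} the binary entropy in nats and the expectation in closed
#' form via the digamma function. Large when the model is both uncertain
#' about the item (\eqn{\mu} near 1/2) and uncertain about its own estimate
#' (large \eqn{\sigma^2}) — epistemic, not just aleatoric, uncertainty.
#'
#' @param m A `beta_moments` tibble from [beta_match()].
#' @return Nonnegative score(s) in nats, at most \eqn{H_b(\mu)}; strictly
#'   increasing in \eqn{\sigma^2} at fixed \eqn{\mu}.
#' @examples
#' beta_mi_score(beta_match(0.5, 1 / 12)) # log(2) - 1/2
#' @export
beta_mi_score <- function(m) {
  stopifnot(inherits(m, "beta_moments"))
  mu_b <- m$alpha / (m$alpha + m$beta)
  pmax(0, binary_entropy(mu_b) - beta_expected_entropy(m$alpha, m$beta))
}

#' Monte-Carlo BALD score for a binary reduction
#'
#' Draws the top-class probability from a Normal(\eqn{\mu}, \eqn{\sigma^2})
#' truncated to `[eps, 1 - eps]` and returns the BALD mutual information
#' \eqn{H_b(\bar p) - \overline{H_b(p)}}, floored at 0. The sampling-based
#' counterpart of [beta_mi_score()], used as the state-of-the-art baseline.
#'
#' @param mu Mean of the probability.
#' @param sigma2 Positive variance.
#' @param n_samples Number of Monte-Carlo draws (>= 2).
#' @param seed Seed for the draws.
#' @param eps Truncation bound.
#' @return A nonnegative scalar in nats.
#' @export
bald_mc_score <- function(mu, sigma2, n_samples = 1000L, seed = 1L, eps = 1e-6) {
  if (n_samples < 2L) stop_usage("n_samples must be at least 2")
  if (sigma2 <= 0) stop_usage("sigma2 must be positive")
  sdv <- sqrt(sigma2)
  lo <- stats::pnorm((eps - mu) / sdv)
  hi <- stats::pnorm((1 - eps - mu) / sdv)
  p <- with_seed(seed, {
    u <- runif(n_samples, lo, hi)
    mu + sdv * stats::qnorm(u)        # inverse-CDF truncated-normal draws
  })
  p <- pmin(1 - eps, pmax(eps, p))
  max(0, binary_entropy(mean(p)) - mean(binary_entropy(p)))
}

#' Rank unlabeled items and select the next labeling batch
#'
#' Scores every unlabeled item from the learner's posterior and returns the
#' top `batch_size` ids. For the Beta-based strategies (`bald`, `beta_mi`)
#' the multi-class posterior is reduced per item to a binary split — the top
#' class against the rest — using that class's predictive mean (as `prob`)
#' and variance. Ties are broken by ascending item id for reproducibility.
#'
#' @param posterior An `al_posterior` from [predict.al_gp()].
#' @param unlabeled_ids Ids eligible for selection (must appear in the
#'   posterior; labeled items must be excluded by the caller).
#' @param strategy One of `"random"`, `"entropy"`, `"variance"`, `"bald"`,
#'   `"beta_mi"`.
#' @param batch_size Number of items to select (all unlabeled if larger).
#' @param seed Seed for the random strategy and the BALD draws.
#' @param mc_samples Monte-Carlo draws per item for `"bald"`.
#' @return An `acquisition_result`: list with `scores` (tibble `id`, `score`),
#'   `ranking` (ids by descending score), `selected` (the batch), `strategy`,
#'   `seed`.
#' @export
select_batch <- function(posterior, unlabeled_ids, strategy, batch_size,
                         seed = 1L, mc_samples = 1000L) {
  strategies <- c("random", "entropy", "variance", "bald", "beta_mi")
  if (!strategy %in% strategies) {
    stop_usage(paste0("unknown strategy '", strategy, "'"))
  }
  if (batch_size < 1L) stop_usage("batch_size must be at least 1")
  idx <- match(unlabeled_ids, posterior$ids)
  if (anyNA(idx)) stop_usage("unlabeled ids missing from the posterior")
  prob <- posterior$prob[idx, , drop = FALSE]
  var <- posterior$var[idx, , drop = FALSE]
  top <- max.col(prob, ties.method = "first")
  mu_top <- prob[cbind(seq_along(idx), top)]
  var_top <- pmax(var[cbind(seq_along(idx), top)], 1e-12)
  score <- switch(
    strategy,
    random = with_seed(seed, runif(length(idx))),
    entropy = apply(prob, 1, entropy_score),
    variance = var_top,
    beta_mi = beta_mi_score(beta_match(mu_top, var_top)),
    bald = with_seed(seed, {
      vapply(seq_along(idx), function(i) {
        bald_mc_score(mu_top[i], var_top[i], n_samples = mc_samples,
                      seed = sample.int(.Machine$integer.max, 1L))
      }, numeric(1))
    })
  )
  ord <- order(-score, unlabeled_ids)
  ranking <- unlabeled_ids[ord]
  structure(
    list(scores = tibble::tibble(id = unlabeled_ids, score = score),
         ranking = ranking,
         selected = utils::head(ranking, batch_size),
         strategy = strategy, seed = as.integer(seed)),
    class = "acquisition_result"
  )
}

#' @export
tidy.acquisition_result <- function(x, ...) {
  x$scores %>%
    dplyr::mutate(rank = match(.data$id, x$ranking),
                  selected = .data$id %in% x$selected,
                  strategy = x$strategy) %>%
    dplyr::arrange(.data$rank)
}
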