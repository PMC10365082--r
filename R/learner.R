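# The AL model: one-vs-rest Gaussian-process regression on one-hot class
# targets over the embedding space ("least-squares classification").
# Closed-form and deterministic; the predictive variance feeds acquisition.

#' Gaussian-process learner configuration
#'
#' @param kernel Covariance kernel; only `"rbf"` is implemented.
#' @param length_scale Positive scalar, or `"median-heuristic"` to use the
#'   median pairwise distance of the training embeddings.
#' @param noise_jitter Observation-noise variance added to the kernel
#'   diagonal (keeps the solve well-conditioned).
#' @param max_train Cap on training points; larger labeled sets are uniformly
#'   subsampled (deterministically) before fitting.
#' @return A `gp_config` list.
#' @export
gp_config <- function(kernel = "rbf",
                      length_scale = "median-heuristic",
                      noise_jitter = 1e-4,
                      max_train = 2000L) {
  if (!identical(kernel, "rbf")) stop_usage("only the rbf kernel is supported")
  if (is.numeric(length_scale) && length_scale <= 0) {
    stop_usage("length_scale must be positive")
  }
  if (noise_jitter <= 0) stop_usage("noise_jitter must be positive")
  structure(list(kernel = kernel, length_scale = length_scale,
                 noise_jitter = noise_jitter, max_train = as.integer(max_train)),
            class = "gp_config")
}

rbf_kernel <- function(a, b, ls) exp(-cross_dist2(a, b) / (2 * ls^2))

#' Fit the Gaussian-process learner
#'
#' One independent GP regression per class on one-hot targets: for class c
#' the posterior of \eqn{f_c} under kernel \eqn{K + \sigma_n^2 I}. The class
#' with the largest predictive mean is the predicted (auto-)label, and the
#' predictive variance expresses the model's confidence.
#'
#' @param embeddings Embedding tibble of the labeled items.
#' @param labels Integer class labels (1-based), one per embedding row; at
#'   least two distinct classes must be present.
#' @param cfg A [gp_config()].
#' @param n_classes Total number of classes; defaults to `max(labels)` so
#'   classes unseen so far still get a posterior column.
#' @return An `al_gp` model.
#' @export
gp_fit <- function(embeddings, labels, cfg = gp_config(), n_classes = NULL) {
  X <- embedding_matrix(embeddings)
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) stop_usage("labels must match embedding rows")
  if (length(unique(labels)) < 2L) {
    rlang::abort(
      "training labels contain a single class; label a more diverse batch first",
      class = "activelabel_degenerate_model"
    )
  }
  if (nrow(X) > cfg$max_train) {
    keep <- with_seed(760561L, sort(sample.int(nrow(X), cfg$max_train)))
    X <- X[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  C <- if (is.null(n_classes)) max(labels) else as.integer(n_classes)
  ls <- cfg$length_scale
  if (identical(ls, "median-heuristic")) {
    ls <- stats::median(stats::dist(X))
    if (!is.finite(ls) || ls <= 0) ls <- 1
  }
  K <- rbf_kernel(X, X, ls) + diag(cfg$noise_jitter, nrow(X))
  L <- chol(K)
  Y <- matrix(0, nrow(X), C)
  Y[cbind(seq_along(labels), labels)] <- 1
  alpha <- backsolve(L, forwardsolve(t(L), Y))
  structure(
    list(X = X, L = L, alpha = alpha, length_scale = ls, cfg = cfg,
         n_classes = C, n_train = nrow(X)),
    class = "al_gp"
  )
}

#' Predict class posteriors for an embedded pool
#'
#' @param object An `al_gp` model.
#' @param newdata Embedding tibble to predict at.
#' @param ... Unused.
#' @return An `al_posterior`: list with `ids`, `mean` and `var` (N x C
#'   matrices; the variance, a function of the query location only, is shared
#'   across classes), and `prob`, the means clipped to `[1e-6, 1 - 1e-6]` and
#'   renormalized per row. `argmax(prob)` is the auto-label.
#' @export
predict.al_gp <- function(object, newdata, ...) {
  Xs <- embedding_matrix(newdata)
  if (ncol(Xs) != ncol(object$X)) stop_usage("embedding dimension mismatch")
  Ks <- rbf_kernel(Xs, object$X, object$length_scale)
  mu <- Ks %*% object$alpha
  v <- forwardsolve(t(object$L), t(Ks))
  var1 <- pmax(0, 1 - colSums(v^2))
  eps <- 1e-6
  p <- pmin(pmax(mu, eps), 1 - eps)   # argument order keeps the dim attribute
  p <- p / rowSums(p)
  structure(
    list(ids = newdata$id,
         mean = mu,
         var = matrix(var1, nrow(Xs), object$n_classes),
         prob = p),
    class = "al_posterior"
  )
}

#' @export
tidy.al_posterior <- function(x, ...) {
  n <- length(x$ids); C <- ncol(x$prob)
  tibble::tibble(
    id = rep(x$ids, each = C),
    class = rep(seq_len(C), n),
    mean = as.numeric(t(x$mean)),
    var = as.numeric(t(x$var)),
    prob = as.numeric(t(x$prob))
  )
}

# Hard labels from a posterior (ties broken toward the lower class index).
posterior_labels <- function(posterior) {
  as.integer(max.col(posterior$prob, ties.method = "first"))
}

#' Top-1 accuracy of the learner on held-out data
#'
#' @param model An `al_gp` model.
#' @param embeddings Embedding tibble of the test items.
#' @param labels True integer labels of the test items.
#' @return Fraction of items whose argmax prediction equals the label.
#' @export
gp_evaluate <- function(model, embeddings, labels) {
  if (nrow(embeddings) == 0L) stop_usage("test set is empty")
  pred <- posterior_labels(predict(model, embeddings))
  mean(pred == as.integer(labels))
}

#' @export
glance.al_gp <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, n_classes = x$n_classes,
                 length_scale = x$length_scale,
                 noise_jitter = x$cfg$noise_jitter)
}
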