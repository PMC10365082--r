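# Contrastive embeddings: the NT-Xent loss, a small trainable encoder, and
# the no-training "oracle embedding" used by the benchmark harness.

# Per-anchor NT-Xent terms. z is 2B x d with consecutive rows forming the B
# positive pairs ((1,2), (3,4), ...). Returns a length-2B vector.
nt_xent_terms <- function(z, temperature) {
  n <- nrow(z)
  pos <- ifelse(seq_len(n) %% 2 == 1, seq_len(n) + 1L, seq_len(n) - 1L)
  s <- tcrossprod(z) / temperature
  # log-sum-exp over k != i, stabilized per row
  off <- s
  diag(off) <- -Inf
  m <- apply(off, 1, max)
  lse <- m + log(rowSums(exp(off - m)))
  lse - s[cbind(seq_len(n), pos)]
}

#' Normalized-temperature cross-entropy (NT-Xent) contrastive loss
#'
#' The SimCLR objective over a batch of B positive pairs: for anchor i with
#' positive j,
#' \deqn{\ell_i = -\log \frac{\exp(\cos(z_i, z_j)/\tau)}
#'   {\sum_{k \ne i} \exp(\cos(z_i, z_k)/\tau)}}
#' and the loss is the mean of \eqn{\ell_i} over all 2B anchors. Rows of `z`
#' must be unit vectors; consecutive rows form the positive pairs.
#'
#' @param z A 2B x d matrix of embeddings, rows (1,2), (3,4), ... being the
#'   positive pairs. Non-unit rows are normalized with a warning.
#' @param temperature Softmax temperature \eqn{\tau > 0}.
#' @return A nonnegative scalar. If all 2B embeddings coincide the loss is
#'   `log(2B - 1)`, the uniform-softmax baseline.
#' @examples
#' z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
#' nt_xent_loss(z, temperature = 1)
#' @export
nt_xent_loss <- function(z, temperature = 0.5) {
  z <- as.matrix(z)
  if (nrow(z) < 4L || nrow(z) %% 2L != 0L) {
    stop_usage("z must have an even number of rows and at least 2 pairs")
  }
  if (temperature <= 0) stop_usage("temperature must be positive")
  nrm <- sqrt(rowSums(z^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    rlang::warn("rows of z are not unit-normalized; normalizing internally")
    z <- unit_rows(z)
  }
  mean(nt_xent_terms(z, temperature))
}

#' Contrastive-training configuration
#'
#' @param temperature Softmax temperature of the NT-Xent loss.
#' @param batch_pairs Number of positive pairs per training batch (B >= 2).
#' @param augmentations Subset of `"crop-resize"`, `"flip"`,
#'   `"intensity-jitter"`, `"gaussian-noise"`. The default pairing suits
#'   grayscale radiology-like images (no hue transforms).
#' @param epochs Training epochs.
#' @param encoder_width Hidden width of the encoder perceptron.
#' @param embed_dim Output embedding dimension d.
#' @param learning_rate Gradient-descent step size.
#' @param seed Seed controlling initialization, batching and augmentation.
#' @return A `contrastive_config` list.
#' @export
contrastive_config <- function(temperature = 0.5,
                               batch_pairs = 16L,
                               augmentations = c("crop-resize", "intensity-jitter"),
                               epochs = 5L,
                               encoder_width = 32L,
                               embed_dim = 8L,
                               learning_rate = 0.05,
                               seed = 1L) {
  if (temperature <= 0) stop_usage("temperature must be positive")
  if (batch_pairs < 2L) stop_usage("batch_pairs must be at least 2")
  ok <- c("crop-resize", "flip", "intensity-jitter", "gaussian-noise")
  if (!all(augmentations %in% ok)) stop_usage("unknown augmentation name")
  structure(
    list(temperature = temperature, batch_pairs = as.integer(batch_pairs),
         augmentations = augmentations, epochs = as.integer(epochs),
         encoder_width = as.integer(encoder_width),
         embed_dim = as.integer(embed_dim),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "contrastive_config"
  )
}

# --- augmentations (H x W matrices in [0,1]) -------------------------------

augment_image <- function(img, kinds) {
  h <- nrow(img); w <- ncol(img)
  for (kind in kinds) {
    img <- switch(
      kind,
      "crop-resize" = {
        ch <- max(2L, round(h * runif(1, 0.7, 1)))
        cw <- max(2L, round(w * runif(1, 0.7, 1)))
        y0 <- sample.int(h - ch + 1L, 1L); x0 <- sample.int(w - cw + 1L, 1L)
        crop <- img[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), drop = FALSE]
        # nearest-neighbour resize back to H x W
        crop[round(seq(1, ch, length.out = h)), round(seq(1, cw, length.out = w)),
             drop = FALSE]
      },
      "flip" = if (runif(1) < 0.5) img[, rev(seq_len(w)), drop = FALSE] else img,
      "intensity-jitter" = pmin(pmax(img * runif(1, 0.8, 1.2) +
                                       runif(1, -0.1, 0.1), 0), 1),
      "gaussian-noise" = pmin(pmax(img + matrix(rnorm(h * w, sd = 0.05), h, w), 0), 1)
    )
  }
  img
}

# --- two-layer perceptron encoder ------------------------------------------

encoder_forward <- function(enc, X) {
  H <- tanh(sweep(X %*% enc$W1, 2, enc$b1, "+"))
  E <- sweep(H %*% enc$W2, 2, enc$b2, "+")
  list(H = H, E = E, Z = unit_rows(E))
}

# Gradient of the batch NT-Xent loss w.r.t. encoder parameters.
encoder_grad <- function(enc, X, temperature) {
  fw <- encoder_forward(enc, X)
  Z <- fw$Z; E <- fw$E; H <- fw$H
  n <- nrow(Z)
  pos <- ifelse(seq_len(n) %% 2 == 1, seq_len(n) + 1L, seq_len(n) - 1L)
  s <- tcrossprod(Z) / temperature
  off <- s; diag(off) <- -Inf
  m <- apply(off, 1, max)
  P <- exp(off - m) / rowSums(exp(off - m))   # softmax over k != i
  M <- matrix(0, n, n); M[cbind(seq_len(n), pos)] <- 1
  A <- P - M
  dZ <- ((A + t(A)) %*% Z) / (n * temperature)
  r <- sqrt(rowSums(E^2)); r[r == 0] <- 1
  dE <- (dZ - Z * rowSums(dZ * Z)) / r        # through row normalization
  dW2 <- crossprod(H, dE); db2 <- colSums(dE)
  dH <- dE %*% t(enc$W2)
  dpre <- dH * (1 - H^2)
  dW1 <- crossprod(X, dpre); db1 <- colSums(dpre)
  list(loss = mean(nt_xent_terms(Z, temperature)),
       dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

#' Train a small contrastive encoder on an image pool
#'
#' Fits a flatten + two-layer perceptron encoder by full-gradient descent on
#' the NT-Xent loss over augmented positive pairs. After every epoch the loss
#' is evaluated on a fixed set of augmented pairs; an epoch that worsens it is
#' rejected (weights reverted, step size halved), so the accepted loss
#' trajectory is nonincreasing. Deterministic given the config seed.
#'
#' @param pool An `image_pool` tibble with at least `2 * batch_pairs` images.
#' @param cfg A [contrastive_config()].
#' @return An `al_encoder` object; use [embed_images()] or `predict()` to map
#'   images to embeddings. The per-epoch evaluation losses are stored in
#'   `$loss_history` (entry 1 is the pre-training loss).
#' @export
train_encoder <- function(pool, cfg = contrastive_config()) {
  n <- nrow(pool)
  if (n < 2L * cfg$batch_pairs) stop_usage("pool too small for the requested batch size")
  h <- nrow(pool$image[[1]]); w <- ncol(pool$image[[1]])
  p <- h * w
  with_seed(cfg$seed, {
    enc <- list(
      W1 = matrix(rnorm(p * cfg$encoder_width, sd = 1 / sqrt(p)), p, cfg$encoder_width),
      b1 = numeric(cfg$encoder_width),
      W2 = matrix(rnorm(cfg$encoder_width * cfg$embed_dim,
                        sd = 1 / sqrt(cfg$encoder_width)),
                  cfg$encoder_width, cfg$embed_dim),
      b2 = numeric(cfg$embed_dim)
    )
    batchify <- function(ids) {
      X <- matrix(0, 2L * length(ids), p)
      for (j in seq_along(ids)) {
        img <- pool$image[[ids[j]]]
        X[2L * j - 1L, ] <- as.numeric(augment_image(img, cfg$augmentations))
        X[2L * j, ] <- as.numeric(augment_image(img, cfg$augmentations))
      }
      X
    }
    # fixed evaluation pairs for the accept/reject rule
    eval_ids <- sample.int(n, min(n, 4L * cfg$batch_pairs))
    X_eval <- batchify(eval_ids)
    eval_loss <- function(e) {
      mean(nt_xent_terms(encoder_forward(e, X_eval)$Z, cfg$temperature))
    }
    lr <- cfg$learning_rate
    best <- eval_loss(enc)
    history <- best
    for (ep in seq_len(cfg$epochs)) {
      prev <- enc
      order <- sample.int(n)
      chunks <- split(order, ceiling(seq_along(order) / cfg$batch_pairs))
      for (ids in chunks) {
        if (length(ids) < 2L) next
        g <- encoder_grad(enc, batchify(ids), cfg$temperature)
        enc$W1 <- enc$W1 - lr * g$dW1; enc$b1 <- enc$b1 - lr * g$db1
        enc$W2 <- enc$W2 - lr * g$dW2; enc$b2 <- enc$b2 - lr * g$db2
      }
      cur <- eval_loss(enc)
      if (cur <= best) {
        best <- cur
      } else {                       # reject: revert and shrink the step
        enc <- prev
        lr <- lr / 2
        cur <- best
      }
      history <- c(history, cur)
    }
    structure(
      list(W1 = enc$W1, b1 = enc$b1, W2 = enc$W2, b2 = enc$b2,
           image_size = c(h, w), embed_dim = cfg$embed_dim,
           cfg = cfg, loss_history = history),
      class = "al_encoder"
    )
  })
}

#' Embed images with a trained encoder
#'
#' @param encoder An `al_encoder` from [train_encoder()].
#' @param pool An `image_pool` tibble (image sizes must match training).
#' @param normalize Unit-normalize the embedding rows.
#' @return An embedding tibble (`id` + `e1 ... ed` columns).
#' @export
embed_images <- function(encoder, pool, normalize = TRUE) {
  h <- encoder$image_size[1]; w <- encoder$image_size[2]
  bad <- vapply(pool$image, function(m) nrow(m) != h || ncol(m) != w, logical(1))
  if (any(bad)) stop_usage("image size does not match the encoder's training size")
  X <- t(vapply(pool$image, as.numeric, numeric(h * w)))
  E <- encoder_forward(encoder, X)$E
  if (normalize) E <- unit_rows(E)
  embedding_tibble(pool$id, E, normalized = normalize)
}

#' @export
predict.al_encoder <- function(object, newdata, ...) {
  embed_images(object, newdata, ...)
}

#' Oracle embedding of a latent pool
#'
#' Returns the generator's latent vectors plus fresh isotropic noise — a
#' stand-in for a trained encoder in fast desk-scale experiments where the
#' latent space is known by construction.
#'
#' @param pool A `latent_pool` tibble from [generate_latent()].
#' @param noise_sd Standard deviation of the added noise (0 = identity).
#' @param normalize Unit-normalize the rows.
#' @param seed Seed for the noise draw.
#' @return An embedding tibble (`id` + `e1 ... ed`).
#' @export
oracle_embed <- function(pool, noise_sd = 0, normalize = FALSE, seed = 1L) {
  m <- embedding_matrix(pool)
  if (noise_sd > 0) {
    m <- m + with_seed(seed, matrix(rnorm(length(m), sd = noise_sd), nrow(m), ncol(m)))
  }
  if (normalize) m <- unit_rows(m)
  embedding_tibble(pool$id, m, normalized = normalize)
}
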