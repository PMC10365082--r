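# Cold start: cluster the unsupervised embeddings and spread the first
# labeling batch across clusters so it carries maximal diversity.

#' Cluster an embedded pool
#'
#' k-means over the embedding space, the structure model used to initialize
#' the labeling loop before any labels exist. Empty clusters (possible when
#' k-means converges degenerately) are dropped with a warning.
#'
#' @param embeddings An embedding tibble (`id` + `e*` columns).
#' @param k Number of clusters, `1 <= k <= N`. Default
#'   `max(2, round(sqrt(2 * batch_size)))` is chosen by [coldstart_k()].
#' @param seed Seed for the k-means initialization.
#' @return A `cluster_model`: list with `k`, `centers` (k x d), and
#'   `assignment`, a tibble of `id`, `cluster`.
#' @export
fit_clusters <- function(embeddings, k, seed = 1L) {
  m <- embedding_matrix(embeddings)
  if (k < 1L || k > nrow(m)) stop_usage("k must lie in [1, N]")
  if (k == 1L) {
    centers <- matrix(colMeans(m), 1L, ncol(m))
    cl <- rep(1L, nrow(m))
  } else {
    km <- with_seed(seed, stats::kmeans(m, centers = k, nstart = 5L, iter.max = 50L))
    cl <- km$cluster
    centers <- km$centers
    keep <- sort(unique(cl))
    if (length(keep) < k) {
      rlang::warn("k-means produced empty clusters; dropping them")
      centers <- centers[keep, , drop = FALSE]
      cl <- match(cl, keep)
    }
  }
  structure(
    list(k = nrow(centers), centers = centers,
         assignment = tibble::tibble(id = embeddings$id, cluster = as.integer(cl)),
         seed = as.integer(seed)),
    class = "cluster_model"
  )
}

#' Default cluster count for a cold-start batch
#'
#' Tied to the batch size so that the first batch can span several clusters:
#' `max(2, round(sqrt(2 * batch_size)))`.
#'
#' @param batch_size The cold-start batch size.
#' @return An integer k.
#' @export
coldstart_k <- function(batch_size) {
  max(2L, as.integer(round(sqrt(2 * batch_size))))
}

#' Draw a maximally diverse first batch across clusters
#'
#' Items are taken round-robin over the clusters (ordered largest first so
#' big clusters win ties), which guarantees the batch touches
#' `min(k, batch_size)` distinct clusters and per-cluster multiplicities
#' differ by at most one while clusters still have items. Within a cluster
#' the item nearest the center is picked first (a prototypical exemplar),
#' then remaining items in random order.
#'
#' @param model A `cluster_model` from [fit_clusters()].
#' @param embeddings The embedding tibble the model was fitted on.
#' @param batch_size Number of items to draw (all items if `>= N`).
#' @param seed Seed for the within-cluster ordering.
#' @return Character vector of selected item ids (no duplicates).
#' @export
diverse_batch <- function(model, embeddings, batch_size, seed = 1L) {
  if (batch_size < 1L) stop_usage("batch_size must be at least 1")
  m <- embedding_matrix(embeddings)
  ids <- embeddings$id
  n <- length(ids)
  if (batch_size >= n) return(ids)
  cl <- model$assignment$cluster[match(ids, model$assignment$id)]
  with_seed(seed, {
    queues <- lapply(seq_len(model$k), function(c) {
      idx <- which(cl == c)
      if (length(idx) == 0L) return(character(0))
      d2 <- colSums((t(m[idx, , drop = FALSE]) - model$centers[c, ])^2)
      proto <- idx[which.min(d2)]
      rest <- setdiff(idx, proto)
      ids[c(proto, if (length(rest)) sample(rest) else integer(0))]
    })
    sizes <- lengths(queues)
    order_cl <- order(sizes, decreasing = TRUE)
    picked <- character(0)
    depth <- 1L
    while (length(picked) < batch_size) {
      for (c in order_cl) {
        if (length(queues[[c]]) >= depth) picked <- c(picked, queues[[c]][depth])
        if (length(picked) == batch_size) break
      }
      depth <- depth + 1L
    }
    picked
  })
}
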