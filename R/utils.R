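# Internal helpers shared across modules.

# Run `code` under a locally seeded RNG so package functions are
# deterministic given `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_config <- function(msg) rlang::abort(msg, class = "activelabel_config_error")
stop_usage  <- function(msg) rlang::abort(msg, class = "activelabel_usage_error")

#' Extract the embedding matrix from an embedding tibble
#'
#' Embeddings travel as tibbles with an `id` column followed by numeric
#' coordinate columns (`e1`, `e2`, ...). This returns the coordinates as a
#' plain numeric matrix with ids as row names.
#'
#' @param embeddings A tibble with an `id` column and numeric `e*` columns.
#' @return A numeric matrix, one row per item.
#' @export
embedding_matrix <- function(embeddings) {
  cols <- grep("^e[0-9]+$", names(embeddings), value = TRUE)
  if (length(cols) == 0L) stop_usage("no embedding columns (e1, e2, ...) found")
  m <- as.matrix(embeddings[cols])
  rownames(m) <- as.character(embeddings$id)
  storage.mode(m) <- "double"
  m
}

# Build an embedding tibble from ids + matrix.
embedding_tibble <- function(ids, m, normalized = FALSE) {
  colnames(m) <- paste0("e", seq_len(ncol(m)))
  out <- dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(m))
  attr(out, "normalized") <- normalized
  class(out) <- c("al_embedding", class(out))
  out
}

# Row-wise unit normalization; zero rows are left untouched.
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# Squared Euclidean cross-distances between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Binary entropy in nats, safe at 0 and 1.
binary_entropy <- function(p) {
  term <- function(q) ifelse(q > 0, -q * log(q), 0)
  term(p) + term(1 - p)
}
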