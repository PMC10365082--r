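#' Specify a synthetic labeling dataset
#'
#' Describes a seeded synthetic dataset emulating an imbalanced multi-class
#' radiology classification task, either as latent vectors (fast, used by the
#' benchmark harness) or as small textured images with optional bright
#' elliptical "lesions" (used by object discovery).
#'
#' The default class proportions mirror a public chest x-ray composition of
#' 8,851 normal / 6,063 pneumonia / 601 Covid-19 examples, the kind of heavy
#' imbalance the workflow is designed to survive.
#'
#' @param n_items Number of items to generate.
#' @param class_proportions Nonnegative class weights (at least two); they are
#'   normalized internally. Defaults to the imbalanced 3-class preset.
#' @param separation Distance between class centers in latent units.
#' @param latent_dim Dimension of the latent space.
#' @param noise_sd Isotropic noise standard deviation around class centers.
#' @param image_size Integer `c(height, width)` in pixels (image mode).
#' @param lesion_frac Fraction of images carrying a lesion object, in `[0, 1]`.
#' @param seed Integer seed; equal specs with equal seeds generate identical
#'   data.
#' @return A `dataset_spec` list.
#' @examples
#' spec <- dataset_spec(n_items = 120, seed = 1)
#' pool <- generate_latent(spec)
#' table(pool$true_label)
#' @export
dataset_spec <- function(n_items,
                         class_proportions = c(8851, 6063, 601),
                         separation = 3.5,
                         latent_dim = 8,
                         noise_sd = 1,
                         image_size = c(64L, 64L),
                         lesion_frac = 0,
                         seed = 1L) {
  if (length(class_proportions) < 2L) {
    stop_config("class_proportions needs at least two entries")
  }
  if (any(class_proportions < 0) || sum(class_proportions) <= 0) {
    stop_config("class_proportions must be nonnegative and sum to a positive value")
  }
  n_pos <- sum(class_proportions > 0)
  if (n_items < n_pos) {
    stop_config("n_items must be at least the number of classes with positive weight")
  }
  if (separation < 0 || noise_sd <= 0) {
    stop_config("separation must be nonnegative and noise_sd positive")
  }
  if (lesion_frac < 0 || lesion_frac > 1) stop_config("lesion_frac must lie in [0, 1]")
  structure(
    list(
      n_items = as.integer(n_items),
      class_proportions = as.numeric(class_proportions),
      separation = separation,
      latent_dim = as.integer(latent_dim),
      noise_sd = noise_sd,
      image_size = as.integer(image_size),
      lesion_frac = lesion_frac,
      seed = as.integer(seed)
    ),
    class = "dataset_spec"
  )
}

#' Largest-remainder apportionment of items to classes
#'
#' Rounds `n * p_c` to integers so that the counts always sum to `n` exactly;
#' the preset composition (8,851 / 6,063 / 601) is reproduced without drift.
#'
#' @param n Total number of items.
#' @param proportions Nonnegative class weights.
#' @return Integer vector of per-class counts summing to `n`.
#' @export
class_counts <- function(n, proportions) {
  p <- proportions / sum(proportions)
  raw <- n * p
  base <- floor(raw)
  short <- as.integer(round(n - sum(base)))
  rem <- raw - base
  cnt <- as.integer(base)
  if (short > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    cnt[take] <- cnt[take] + 1L
  }
  cnt
}

# Vertices of a regular simplex with the requested pairwise distance,
# embedded in d dimensions (requires d >= k - 1).
simplex_centers <- function(k, d, separation) {
  if (k == 1L) return(matrix(0, 1, d))
  if (d < k - 1L) stop_config("latent_dim must be at least n_classes - 1")
  v <- diag(k) - 1 / k            # centered unit-basis simplex, pairwise dist sqrt(2)
  basis <- svd(v, nu = 0, nv = k - 1L)$v
  coords <- v %*% basis * separation / sqrt(2)
  cbind(coords, matrix(0, k, d - (k - 1L)))
}

#' Generate a latent-vector pool
#'
#' Places class centers at the vertices of a regular simplex scaled to the
#' requested separation, assigns items to classes by largest-remainder
#' rounding of the class proportions, and draws each item as its class center
#' plus isotropic Gaussian noise. Deterministic given the spec's seed.
#'
#' @param spec A [dataset_spec()].
#' @return A tibble of class `latent_pool` with columns `id`, `true_label`
#'   (integer class, 1-based), `status` (`"unlabeled"`), `label`, `round`, and
#'   latent coordinates `e1 ... ed`. Class centers are attached as the
#'   `"centers"` attribute.
#' @export
generate_latent <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  k <- length(spec$class_proportions)
  cnt <- class_counts(spec$n_items, spec$class_proportions)
  centers <- simplex_centers(k, spec$latent_dim, spec$separation)
  labels <- rep(seq_len(k), cnt)
  vec <- with_seed(spec$seed, {
    centers[labels, , drop = FALSE] +
      matrix(rnorm(spec$n_items * spec$latent_dim, sd = spec$noise_sd),
             spec$n_items, spec$latent_dim)
  })
  pool <- dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("item_%05d", seq_len(spec$n_items)),
      true_label = as.integer(labels),
      status = "unlabeled",
      label = NA_integer_,
      round = NA_integer_
    ),
    tibble::as_tibble(matrix(vec, spec$n_items, spec$latent_dim,
                             dimnames = list(NULL, paste0("e", seq_len(spec$latent_dim)))))
  )
  attr(pool, "centers") <- centers
  attr(pool, "spec") <- spec
  class(pool) <- c("latent_pool", "al_pool", class(pool))
  pool
}

# Separable moving-average smoothing with reflected edges.
smooth_field <- function(m, w) {
  if (w <= 1L) return(m)
  k <- rep(1 / w, w)
  pad <- w %/% 2
  smooth1 <- function(x) {
    xp <- c(rev(x[seq_len(pad)]), x, rev(x[length(x) - seq_len(pad) + 1L]))
    as.numeric(stats::filter(xp, k, sides = 2))[pad + seq_along(x)]
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

# Draw one lesion ellipse for an H x W image. Lesions are compact (aspect
# ratio <= 2.5) and kept 2 px inside the image so they are genuinely
# surrounded by background; the bounding box covers <= 10% of the image.
draw_lesion <- function(img, min_size = 6L, max_aspect = 2.5, margin = 2L) {
  h <- nrow(img); w <- ncol(img)
  max_area <- 0.1 * h * w
  max_w <- min(w - 2L * margin, floor(sqrt(max_area * max_aspect)))
  if (max_w < min_size) stop_config("lesion does not fit in the image")
  bw <- sample(min_size:max_w, 1L)
  bh_lo <- max(min_size, ceiling(bw / max_aspect))
  bh_hi <- min(h - 2L * margin, floor(max_area / bw), floor(bw * max_aspect))
  if (bh_hi < bh_lo) bh_hi <- bh_lo
  bh <- sample(bh_lo:bh_hi, 1L)
  x <- sample(margin:(w - bw - margin), 1L)   # 0-based, half-open box
  y <- sample(margin:(h - bh - margin), 1L)
  cx <- x + bw / 2; cy <- y + bh / 2
  cols <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  rows <- matrix(rep(seq_len(h) - 0.5, w), h, w)
  r2 <- ((cols - cx) / (bw / 2))^2 + ((rows - cy) / (bh / 2))^2
  bump <- pmax(1 - r2, 0)            # smooth radial falloff inside the ellipse
  img <- pmin(img + 0.55 * sqrt(bump), 1)
  list(img = img, box = c(x = x, y = y, w = bw, h = bh))
}

#' Generate an image pool with optional lesions
#'
#' Each image is a low-frequency textured background whose smoothness and
#' base intensity depend on the class (so classification is learnable from
#' pixels), with values in `[0, 1]`. A fraction `lesion_frac` of images
#' additionally receive one bright ellipse occupying at most 10% of the image
#' area; its bounding box (0-based `x, y, w, h`, half-open) is recorded.
#'
#' @param spec A [dataset_spec()] with `image_size` set.
#' @return A tibble of class `image_pool` with columns `id`, `image` (list of
#'   H x W matrices), `true_label`, `status`, `label`, `round`, `lesion`
#'   (list; `NULL` or named box vector).
#' @export
generate_images <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  k <- length(spec$class_proportions)
  cnt <- class_counts(spec$n_items, spec$class_proportions)
  labels <- rep(seq_len(k), cnt)
  n_lesion <- round(spec$lesion_frac * spec$n_items)
  with_seed(spec$seed, {
    lesion_items <- if (n_lesion > 0) sample(spec$n_items, n_lesion) else integer(0)
    images <- vector("list", spec$n_items)
    boxes <- vector("list", spec$n_items)
    for (i in seq_len(spec$n_items)) {
      cls <- labels[i]
      base <- 0.25 + 0.12 * (cls - 1)           # class-dependent mean intensity
      width <- 3L + 2L * ((cls - 1L) %% 3L)     # class-dependent texture scale
      field <- smooth_field(matrix(rnorm(h * w), h, w), width)
      field <- (field - mean(field)) / max(sd(field), 1e-12)
      img <- pmin(pmax(base + 0.08 * field, 0), 1)
      if (i %in% lesion_items) {
        les <- draw_lesion(img)
        img <- les$img
        boxes[[i]] <- les$box
      }
      images[[i]] <- img
    }
    pool <- tibble::tibble(
      id = sprintf("img_%05d", seq_len(spec$n_items)),
      image = images,
      true_label = as.integer(labels),
      status = "unlabeled",
      label = NA_integer_,
      round = NA_integer_,
      lesion = boxes
    )
    attr(pool, "spec") <- spec
    class(pool) <- c("image_pool", "al_pool", class(pool))
    pool
  })
}

#' Simulated labeling team
#'
#' Reveals the hidden ground-truth labels of the requested items, optionally
#' corrupted at a given error rate (symmetric over the wrong classes), marks
#' them `status = "human"` and records the labeling round. Items may be
#' human-labeled only once.
#'
#' @param pool A pool tibble from [generate_latent()] or [generate_images()].
#' @param item_ids Ids of the items to label.
#' @param round Round index recorded on the labeled items.
#' @param error_rate Probability that a returned label is flipped to a
#'   uniformly chosen wrong class. Default 0 (perfect oracle).
#' @param seed Seed for the label-noise draw.
#' @return The pool with `label`, `status` and `round` updated for the
#'   requested items.
#' @export
labeling_oracle <- function(pool, item_ids, round = 0L, error_rate = 0, seed = 1L) {
  idx <- match(item_ids, pool$id)
  if (anyNA(idx)) stop_usage("unknown item ids passed to the labeling oracle")
  if (any(pool$status[idx] == "human")) {
    stop_usage("some items are already human-labeled; items are labeled once")
  }
  truth <- pool$true_label[idx]
  k <- max(pool$true_label)
  lab <- truth
  if (error_rate > 0) {
    lab <- with_seed(seed, {
      flip <- runif(length(truth)) < error_rate
      wrong <- vapply(truth, function(t) {
        others <- setdiff(seq_len(k), t)
        if (length(others) == 1L) others else sample(others, 1L)
      }, integer(1))
      ifelse(flip, wrong, truth)
    })
  }
  pool$label[idx] <- as.integer(lab)
  pool$status[idx] <- "human"
  pool$round[idx] <- as.integer(round)
  pool
}

#' Export an image pool to a directory of PNGs plus a label table
#'
#' Writes one 8-bit grayscale PNG per image and a `labels.csv` with columns
#' `id,path,true_label` (benchmark mode) or `id,path,label,status,round`
#' (run mode).
#'
#' @param pool An `image_pool` tibble.
#' @param dir Output directory (created if needed).
#' @param mode `"benchmark"` (ground truth) or `"run"` (working labels).
#' @return Invisibly, the path of the written `labels.csv`.
#' @export
export_pool <- function(pool, dir, mode = c("benchmark", "run")) {
  mode <- match.arg(mode)
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_usage("the 'png' package is required to export images")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(pool$id, ".png"))
  for (i in seq_len(nrow(pool))) {
    png::writePNG(pool$image[[i]], paths[i])
  }
  tab <- if (mode == "benchmark") {
    data.frame(id = pool$id, path = basename(paths), true_label = pool$true_label)
  } else {
    data.frame(id = pool$id, path = basename(paths), label = pool$label,
               status = pool$status, round = pool$round)
  }
  out <- file.path(dir, "labels.csv")
  utils::write.csv(tab, out, row.names = FALSE)
  invisible(out)
}
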