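# Unsupervised object discovery: sample rectangular patches, embed them
# (histogram fallback needs no training), and score candidate boxes on two
# assumptions — objects are small and surrounded by background, and the
# intensity distribution inside an object's box differs from the ring
# around it.
#
# Box convention throughout: (x, y, w, h), 0-based pixel indices, half-open
# on both axes; x runs along columns, y along rows.

#' Sample random rectangular patches from every image
#'
#' Positions are uniform over valid placements and side lengths log-uniform
#' over `size_range`, independently per axis. Deterministic given `seed`.
#'
#' @param pool An `image_pool` tibble.
#' @param n_per_image Number of patches per image.
#' @param size_range Integer `c(min, max)` side length in pixels.
#' @param seed Seed for the draws.
#' @return A tibble of patches: `image_id`, `x`, `y`, `w`, `h`.
#' @export
sample_patches <- function(pool, n_per_image = 150L, size_range = c(8L, 24L),
                           seed = 1L) {
  h <- nrow(pool$image[[1]]); w <- ncol(pool$image[[1]])
  if (size_range[1] < 2L || size_range[2] > min(h, w) ||
      size_range[1] > size_range[2]) {
    stop_config("size_range is impossible for these image dimensions")
  }
  if (n_per_image == 0L) {
    return(tibble::tibble(image_id = character(0), x = integer(0), y = integer(0),
                          w = integer(0), h = integer(0)))
  }
  with_seed(seed, {
    purrr::map_dfr(pool$id, function(id) {
      pw <- round(exp(runif(n_per_image, log(size_range[1]), log(size_range[2]))))
      ph <- round(exp(runif(n_per_image, log(size_range[1]), log(size_range[2]))))
      px <- floor(runif(n_per_image) * (w - pw + 1))
      py <- floor(runif(n_per_image) * (h - ph + 1))
      tibble::tibble(image_id = id, x = as.integer(px), y = as.integer(py),
                     w = as.integer(pw), h = as.integer(ph))
    })
  })
}

# Pixels of `img` inside a half-open box.
box_pixels <- function(img, box) {
  img[(box[["y"]] + 1):(box[["y"]] + box[["h"]]),
      (box[["x"]] + 1):(box[["x"]] + box[["w"]]), drop = FALSE]
}

# Normalized intensity histogram over fixed [0,1] bins.
intensity_hist <- function(values, bins = 32L) {
  cuts <- pmin(bins, 1L + floor(values * bins))
  tabulate(cuts, nbins = bins) / length(values)
}

# Ring around a box: the outer box scaled by sqrt(2) per axis (clipped at
# the image edges) minus the inner box — equal nominal area to the inside.
ring_pixels <- function(img, box) {
  h <- nrow(img); w <- ncol(img)
  gx <- ceiling(box[["w"]] * (sqrt(2) - 1) / 2)
  gy <- ceiling(box[["h"]] * (sqrt(2) - 1) / 2)
  x0 <- max(0, box[["x"]] - gx); x1 <- min(w, box[["x"]] + box[["w"]] + gx)
  y0 <- max(0, box[["y"]] - gy); y1 <- min(h, box[["y"]] + box[["h"]] + gy)
  outer <- img[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  mask <- matrix(TRUE, nrow(outer), ncol(outer))
  ry <- (box[["y"]] - y0 + 1):(box[["y"]] - y0 + box[["h"]])
  rx <- (box[["x"]] - x0 + 1):(box[["x"]] - x0 + box[["w"]])
  mask[ry, rx] <- FALSE
  outer[mask]
}

#' Jensen-Shannon divergence between two histograms
#'
#' Measures how distinct the intensity distribution inside a candidate box is
#' from the distribution in the surrounding ring. Bounded by `log(2)` nats,
#' attained for disjoint supports; 0 for identical histograms.
#'
#' @param p,q Normalized histograms over identical bins.
#' @return A scalar in `[0, log(2)]` nats.
#' @export
color_divergence <- function(p, q) {
  if (length(p) != length(q)) stop_usage("histograms must share the same bins")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop_usage("histograms must be normalized")
  }
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Cross-image rarity of patch embeddings
#'
#' Mean Euclidean distance from each patch embedding to its `k` nearest
#' neighbours among patches drawn from *other* images. Common background
#' patterns recur across images and score near 0; object-like patches are
#' rare and score high.
#'
#' @param emb Numeric matrix of patch embeddings (one row per patch).
#' @param image_ids Image id of each patch row.
#' @param k Number of cross-image neighbours (default 5).
#' @return Numeric vector of rarity scores, one per patch.
#' @export
patch_rarity <- function(emb, image_ids, k = 5L) {
  if (length(unique(image_ids)) < 2L) {
    stop_usage("rarity needs patches from at least two images")
  }
  n <- nrow(emb)
  d2 <- cross_dist2(emb, emb)
  same <- outer(image_ids, image_ids, "==")
  d2[same] <- Inf
  vapply(seq_len(n), function(i) {
    dd <- sqrt(sort(d2[i, ])[seq_len(k)])
    if (!all(is.finite(dd))) stop_usage("k exceeds the number of cross-image patches")
    mean(dd)
  }, numeric(1))
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes as named vectors `c(x, y, w, h)` (0-based, half-open).
#' @return IoU in `[0, 1]`; 1 iff the boxes are identical.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a[["x"]] + a[["w"]], b[["x"]] + b[["w"]]) - max(a[["x"]], b[["x"]]))
  iy <- max(0, min(a[["y"]] + a[["h"]], b[["y"]] + b[["h"]]) - max(a[["y"]], b[["y"]]))
  inter <- ix * iy
  inter / (a[["w"]] * a[["h"]] + b[["w"]] * b[["h"]] - inter)
}

# IoU of one box against the rows of an (x, y, w, h) matrix.
iou_many <- function(box, m) {
  ix <- pmax(pmin(box[["x"]] + box[["w"]], m[, "x"] + m[, "w"]) -
               pmax(box[["x"]], m[, "x"]), 0)
  iy <- pmax(pmin(box[["y"]] + box[["h"]], m[, "y"] + m[, "h"]) -
               pmax(box[["y"]], m[, "y"]), 0)
  inter <- ix * iy
  inter / (box[["w"]] * box[["h"]] + m[, "w"] * m[, "h"] - inter)
}

# Greedy non-maximum suppression; returns indices of surviving boxes.
nms_keep <- function(boxes, scores, iou_thresh = 0.5) {
  m <- cbind(x = boxes$x, y = boxes$y, w = boxes$w, h = boxes$h)
  ord <- order(-scores)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L ||
        all(iou_many(m[i, ], m[keep, , drop = FALSE]) <= iou_thresh)) {
      keep <- c(keep, i)
    }
  }
  keep
}

# Snap a candidate box to the bright region it covers: inside a window
# around the box, take the bounding box of pixels above
# median + frac * (max - median) of the window. The window is grown until
# the bright region no longer touches its border (or the image edge),
# so a seed box partly inside a blob still recovers the whole blob.
refine_box <- function(img, box, frac = 0.3, expand = 0.6, max_grow = 4L) {
  h <- nrow(img); w <- ncol(img)
  gx <- ceiling(box[["w"]] * expand); gy <- ceiling(box[["h"]] * expand)
  for (step in seq_len(max_grow)) {
    x0 <- max(0, box[["x"]] - gx); x1 <- min(w, box[["x"]] + box[["w"]] + gx)
    y0 <- max(0, box[["y"]] - gy); y1 <- min(h, box[["y"]] + box[["h"]] + gy)
    win <- img[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
    med <- stats::median(win)
    thr <- med + frac * (max(win) - med)
    hits <- which(win >= thr, arr.ind = TRUE)
    if (nrow(hits) < 4L) return(box)
    touches <- (min(hits[, 2]) == 1L && x0 > 0) ||
      (max(hits[, 2]) == ncol(win) && x1 < w) ||
      (min(hits[, 1]) == 1L && y0 > 0) ||
      (max(hits[, 1]) == nrow(win) && y1 < h)
    if (!touches || step == max_grow) {
      return(c(x = x0 + min(hits[, 2]) - 1L, y = y0 + min(hits[, 1]) - 1L,
               w = diff(range(hits[, 2])) + 1L, h = diff(range(hits[, 1])) + 1L))
    }
    gx <- gx * 2L; gy <- gy * 2L
  }
  box
}

# Grow a box (centered, clipped to the image) so both sides reach the
# minimum patch size; proposals never degenerate into pixel speckles.
enforce_min_box <- function(box, min_side, W, H) {
  grow <- function(pos, len, min_len, limit) {
    if (len >= min_len) return(c(pos, len))
    pos <- max(0, min(limit - min_len, pos - (min_len - len) %/% 2))
    c(pos, min_len)
  }
  xw <- grow(box[["x"]], box[["w"]], min(min_side, W), W)
  yh <- grow(box[["y"]], box[["h"]], min(min_side, H), H)
  c(x = xw[1], y = yh[1], w = xw[2], h = yh[2])
}

# Score one box on one image: the three components and their product.
score_box <- function(img, box, rarity, bins) {
  inside <- intensity_hist(as.numeric(box_pixels(img, box)), bins)
  ring_px <- ring_pixels(img, box)
  # a box flush with every image edge has no ring: nothing surrounds it
  cd <- if (length(ring_px) == 0L) 0 else {
    color_divergence(inside, intensity_hist(ring_px, bins))
  }
  sp <- exp(-(box[["w"]] * box[["h"]]) / (0.1 * nrow(img) * ncol(img)))
  c(color_divergence = cd, rarity = rarity, size_prior = sp,
    objectness = cd * rarity * sp)
}

#' Propose object boxes for every image in a pool
#'
#' The full discovery pipeline: sample random patches, embed each patch as a
#' normalized intensity histogram (a training-free pattern embedding), then
#' score every candidate as
#' `objectness = color_divergence * rarity * size_prior` where
#' `size_prior = exp(-area / (0.1 * image_area))` encodes that objects are
#' small relative to the image. The top candidates per image are optionally
#' snapped to the bright region they cover ([refine_box]) and rescored,
#' greedy non-maximum suppression at IoU 0.5 removes duplicates, and
#' proposals are returned sorted by descending objectness within each image.
#'
#' @param pool An `image_pool` tibble.
#' @param n_per_image Random patches sampled per image.
#' @param size_range Patch side-length range in pixels.
#' @param k Cross-image neighbours for the rarity term.
#' @param bins Histogram bins for embeddings and divergence.
#' @param refine Snap candidates to the bright region they cover before
#'   scoring (the sampled patches then act as localization seeds).
#' @param iou_thresh Non-maximum-suppression overlap threshold.
#' @param seed Seed for patch sampling.
#' @return A tibble of proposals: `image_id`, `x`, `y`, `w`, `h`,
#'   `color_divergence`, `rarity`, `size_prior`, `objectness`.
#' @export
propose_boxes <- function(pool, n_per_image = 100L, size_range = c(8L, 24L),
                          k = 5L, bins = 32L, refine = TRUE,
                          iou_thresh = 0.5, seed = 1L) {
  patches <- sample_patches(pool, n_per_image, size_range, seed)
  # reference corpus for rarity: histogram embeddings of the raw patches
  emb <- t(vapply(seq_len(nrow(patches)), function(i) {
    img <- pool$image[[match(patches$image_id[i], pool$id)]]
    intensity_hist(as.numeric(box_pixels(img, unlist(patches[i, c("x", "y", "w", "h")]))),
                   bins)
  }, numeric(bins)))
  purrr::map_dfr(pool$id, function(id) {
    img <- pool$image[[match(id, pool$id)]]
    rows <- which(patches$image_id == id)
    boxes <- unlist(lapply(rows, function(i) {
      box <- c(x = patches$x[i], y = patches$y[i], w = patches$w[i], h = patches$h[i])
      if (!refine) return(list(box))
      # several snap strengths; the objectness score arbitrates between them
      lapply(c(0.2, 0.35, 0.5), function(f) {
        enforce_min_box(refine_box(img, box, frac = f), size_range[1],
                        ncol(img), nrow(img))
      })
    }), recursive = FALSE)
    boxes <- unique(boxes)
    cand <- tibble::tibble(
      image_id = id,
      x = vapply(boxes, `[[`, 0, "x"), y = vapply(boxes, `[[`, 0, "y"),
      w = vapply(boxes, `[[`, 0, "w"), h = vapply(boxes, `[[`, 0, "h")
    )
    cand_emb <- t(vapply(boxes, function(b) {
      intensity_hist(as.numeric(box_pixels(img, b)), bins)
    }, numeric(bins)))
    other <- emb[patches$image_id != id, , drop = FALSE]
    d2 <- cross_dist2(cand_emb, other)
    rar <- apply(d2, 1, function(r) mean(sqrt(sort(r)[seq_len(k)])))
    comp <- t(vapply(seq_along(boxes), function(j) {
      score_box(img, boxes[[j]], rar[j], bins)
    }, numeric(4)))
    cand <- dplyr::bind_cols(cand, tibble::as_tibble(comp))
    keep <- nms_keep(cand, cand$objectness, iou_thresh)
    cand[keep, ][order(-cand$objectness[keep]), ]
  })
}

#' Write box proposals to CSV
#'
#' Columns `image_id,x,y,w,h,objectness` (0-based, half-open boxes).
#'
#' @param proposals Tibble from [propose_boxes()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_proposals <- function(proposals, path) {
  utils::write.csv(
    proposals[, c("image_id", "x", "y", "w", "h", "objectness")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' Objectness-weighted contrastive loss over patch pairs
#'
#' The NT-Xent loss with per-pair weights proportional to objectness, so
#' object-like patches dominate the embedding objective. With equal weights
#' it reduces exactly to [nt_xent_loss()].
#'
#' @param z A 2B x d matrix of unit patch embeddings, consecutive rows being
#'   the positive pairs (two augmentations of the same patch).
#' @param weights Nonnegative weights, length B (per pair) or 2B (per
#'   anchor); not all zero.
#' @param temperature Softmax temperature.
#' @return The weighted mean of the per-anchor NT-Xent terms.
#' @export
weighted_patch_loss <- function(z, weights, temperature = 0.5) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (length(weights) == n / 2) weights <- rep(weights, each = 2L)
  if (length(weights) != n) stop_usage("weights must have length B or 2B")
  if (any(weights < 0) || sum(weights) == 0) {
    stop_usage("weights must be nonnegative and not all zero")
  }
  nrm <- sqrt(rowSums(z^2))
  if (any(abs(nrm - 1) > 1e-6)) z <- unit_rows(z)
  sum(weights * nt_xent_terms(z, temperature)) / sum(weights)
}
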