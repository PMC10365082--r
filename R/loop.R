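# The active-learning loop: cold start, iterate label -> train -> score ->
# select, decide stopping, auto-label the remainder, simulate review, and
# emit the learning curve.

#' Configuration of the active-learning loop
#'
#' @param batch_size Items labeled per round (a day's work for the team).
#' @param max_rounds Hard cap on labeling rounds.
#' @param target_accuracy Accuracy at which labeling stops, in (0, 1].
#' @param patience_rounds Rounds of the plateau ("elbow") test.
#' @param min_gain Minimum accuracy gain per round; if the best gain over the
#'   last `patience_rounds` rounds falls below it, the curve has plateaued.
#' @param test_fraction Fraction of human-labeled items held out (stratified,
#'   resampled each round) to track accuracy.
#' @param strategy Acquisition strategy, see [select_batch()].
#' @param eval `"holdout"` scores accuracy on the held-out labeled split (all
#'   a real campaign can see); `"pool"` scores against the full pool's ground
#'   truth (benchmark mode, as when replaying a fully annotated dataset).
#' @param prelabel_model Optional previously fitted `al_gp` used to propose
#'   labels before the human pass (see [apply_prelabels()]).
#' @param gp A [gp_config()] for the learner.
#' @param mc_samples Monte-Carlo draws for the `"bald"` strategy.
#' @param seed Master seed for the run.
#' @return A `loop_config` list.
#' @export
loop_config <- function(batch_size = 20L,
                        max_rounds = 50L,
                        target_accuracy = 0.9,
                        patience_rounds = 3L,
                        min_gain = 0.005,
                        test_fraction = 0.2,
                        strategy = "beta_mi",
                        eval = c("holdout", "pool"),
                        prelabel_model = NULL,
                        gp = gp_config(),
                        mc_samples = 1000L,
                        seed = 1L) {
  eval <- match.arg(eval)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_config("test_fraction must lie strictly between 0 and 1")
  }
  if (patience_rounds < 1L) stop_config("patience_rounds must be at least 1")
  if (target_accuracy <= 0 || target_accuracy > 1) {
    stop_config("target_accuracy must lie in (0, 1]")
  }
  if (batch_size < 1L || max_rounds < 1L) {
    stop_config("batch_size and max_rounds must be at least 1")
  }
  structure(
    list(batch_size = as.integer(batch_size), max_rounds = as.integer(max_rounds),
         target_accuracy = target_accuracy, patience_rounds = as.integer(patience_rounds),
         min_gain = min_gain, test_fraction = test_fraction, strategy = strategy,
         eval = eval, prelabel_model = prelabel_model, gp = gp,
         mc_samples = as.integer(mc_samples), seed = as.integer(seed)),
    class = "loop_config"
  )
}

#' Decide whether the labeling loop should stop
#'
#' Stops when the latest tracked accuracy reaches the target
#' (`"target_reached"`), or when the best per-round gain over the last
#' `patience_rounds` rounds falls below `min_gain` — the accuracy curve has
#' hit its elbow (`"plateau"`). Otherwise the loop continues.
#'
#' @param accuracy_history Per-round accuracies so far (non-empty).
#' @param cfg A [loop_config()] (only the stopping fields are used).
#' @return A list with `stop` (logical) and `reason` (`"target_reached"`,
#'   `"plateau"`, or `NA` while continuing).
#' @export
stopping_rule <- function(accuracy_history, cfg) {
  if (length(accuracy_history) == 0L) stop_usage("accuracy history is empty")
  n <- length(accuracy_history)
  if (accuracy_history[n] >= cfg$target_accuracy) {
    return(list(stop = TRUE, reason = "target_reached"))
  }
  if (n > cfg$patience_rounds) {
    gains <- diff(accuracy_history)[(n - cfg$patience_rounds):(n - 1L)]
    if (max(gains) < cfg$min_gain) {
      return(list(stop = TRUE, reason = "plateau"))
    }
  }
  list(stop = FALSE, reason = NA_character_)
}

# Stratified split of labeled ids into train/test; at least one test item,
# never an empty train set, and each class keeps >= 1 training example.
split_labeled <- function(ids, labels, test_fraction, seed) {
  with_seed(seed, {
    test <- character(0)
    for (cls in unique(labels)) {
      cls_ids <- ids[labels == cls]
      n_test <- floor(length(cls_ids) * test_fraction)
      if (n_test > 0 && n_test < length(cls_ids)) {
        test <- c(test, sample(cls_ids, n_test))
      }
    }
    if (length(test) == 0L && length(ids) > 2L) test <- sample(ids, 1L)
    list(train = setdiff(ids, test), test = test)
  })
}

#' Run the active-learning labeling loop
#'
#' Round 0 labels a maximally diverse cold-start batch chosen across k-means
#' clusters of the embeddings. Each round then: (1) has the labeler label the
#' batch (optionally correcting pre-labels), (2) refits the GP learner on the
#' human-labeled items minus a stratified held-out split, (3) records
#' accuracy, (4) checks the stopping rule, and (5) ranks the remaining
#' unlabeled items with the acquisition strategy to form the next batch.
#' After stopping, every remaining item is auto-labeled with the learner's
#' argmax prediction (`status = "auto"`), ready for the review pass.
#'
#' @param pool A pool tibble with hidden `true_label` (all unlabeled, or a
#'   resumable partially labeled state).
#' @param embeddings Embedding tibble aligned to the pool.
#' @param cfg A [loop_config()].
#' @param labeler Function `(pool, ids, round)` returning the pool with those
#'   items labeled; defaults to the ground-truth [labeling_oracle()]. Supply
#'   your own to plug in a real labeling team (e.g. via
#'   [write_label_request()] / [read_label_response()]).
#' @return An `al_run` list: `pool` (fully labeled), `model` (final learner),
#'   `curve` (a `learning_curve` tibble of `fraction_labeled`, `accuracy`),
#'   `state` (rounds, accuracy history, stop reason), `config`.
#' @export
run_al <- function(pool, embeddings, cfg = loop_config(), labeler = NULL) {
  stopifnot(inherits(cfg, "loop_config"))
  if (is.null(labeler)) {
    labeler <- function(pool, ids, round) {
      labeling_oracle(pool, ids, round = round)
    }
  }
  n <- nrow(pool)
  if (!all(pool$id %in% embeddings$id)) stop_usage("embeddings must cover the pool")
  if (sum(pool$status == "unlabeled") == 0L) stop_usage("no unlabeled items remain")
  emb_of <- function(ids) embeddings[match(ids, embeddings$id), , drop = FALSE]

  accuracy_history <- numeric(0)
  curve <- tibble::tibble(round = integer(0), fraction_labeled = numeric(0),
                          accuracy = numeric(0))
  model <- NULL
  stopped <- NA_character_

  # cold start: diverse batch over clusters of the unlabeled embeddings
  unl <- pool$id[pool$status == "unlabeled"]
  k <- min(coldstart_k(cfg$batch_size), length(unl))
  cm <- fit_clusters(emb_of(unl), k = k, seed = cfg$seed)
  batch <- diverse_batch(cm, emb_of(unl), cfg$batch_size, seed = cfg$seed)

  round <- 0L
  repeat {
    if (!is.null(cfg$prelabel_model)) {
      apply_prelabels(cfg$prelabel_model, pool, batch, embeddings)
      # proposals only affect labeling-time accounting; the labeler decides
    }
    pool <- labeler(pool, batch, round)
    labeled <- pool$id[pool$status == "human"]
    lab_labels <- pool$label[match(labeled, pool$id)]

    if (length(unique(lab_labels)) >= 2L) {
      sp <- split_labeled(labeled, lab_labels, cfg$test_fraction,
                          seed = cfg$seed + 7919L * round)
      model <- gp_fit(emb_of(sp$train), pool$label[match(sp$train, pool$id)],
                      cfg$gp, n_classes = max(pool$true_label))
      acc <- if (cfg$eval == "pool") {
        gp_evaluate(model, embeddings[match(pool$id, embeddings$id), ],
                    pool$true_label)
      } else if (length(sp$test) > 0L) {
        gp_evaluate(model, emb_of(sp$test), pool$label[match(sp$test, pool$id)])
      } else {
        NA_real_
      }
    } else {
      acc <- 0          # a single-class labeled set predicts nothing useful yet
    }
    accuracy_history <- c(accuracy_history, acc)
    curve <- dplyr::bind_rows(curve, tibble::tibble(
      round = round, fraction_labeled = length(labeled) / n, accuracy = acc))

    unl <- pool$id[pool$status == "unlabeled"]
    dec <- stopping_rule(accuracy_history, cfg)
    if (dec$stop) { stopped <- dec$reason; break }
    if (length(unl) == 0L) { stopped <- "pool_exhausted"; break }
    if (round + 1L >= cfg$max_rounds) { stopped <- "budget_exhausted"; break }

    if (is.null(model)) {
      batch <- with_seed(cfg$seed + round, sample(unl, min(cfg$batch_size, length(unl))))
    } else {
      post <- predict(model, emb_of(unl))
      sel <- select_batch(post, unl, cfg$strategy, cfg$batch_size,
                          seed = cfg$seed + 104729L * (round + 1L),
                          mc_samples = cfg$mc_samples)
      batch <- sel$selected
    }
    round <- round + 1L
  }

  # auto-label everything still unlabeled with the learner's argmax
  unl <- pool$id[pool$status == "unlabeled"]
  if (length(unl) > 0L && !is.null(model)) {
    pred <- posterior_labels(predict(model, emb_of(unl)))
    idx <- match(unl, pool$id)
    pool$label[idx] <- pred
    pool$status[idx] <- "auto"
    pool$round[idx] <- round
  }

  class(curve) <- c("learning_curve", class(curve))
  attr(curve, "strategy") <- cfg$strategy
  attr(curve, "seed") <- cfg$seed
  structure(
    list(pool = pool, model = model, curve = curve,
         state = list(rounds = round + 1L, accuracy_history = accuracy_history,
                      stopped_reason = stopped,
                      n_human = sum(pool$status == "human"),
                      n_auto = sum(pool$status == "auto")),
         config = cfg),
    class = "al_run"
  )
}

#' Propose labels with a previously trained model
#'
#' The pre-labeling enhancement: a model trained earlier on a similar dataset
#' supplies a first-guess label for each item so the labeling team merely
#' corrects it. Downstream cost accounting charges the review rate for
#' correct proposals and the full labeling rate for corrected ones.
#'
#' @param model A fitted `al_gp` (or `NULL`, meaning no pre-labeling).
#' @param pool The pool tibble.
#' @param item_ids Items to propose labels for.
#' @param embeddings Embedding tibble covering the pool.
#' @return A tibble `id`, `proposed_label`, `confidence` (top-class
#'   probability); zero rows when `model` is `NULL`.
#' @export
apply_prelabels <- function(model, pool, item_ids, embeddings) {
  if (is.null(model)) {
    return(tibble::tibble(id = character(0), proposed_label = integer(0),
                          confidence = numeric(0)))
  }
  emb <- embeddings[match(item_ids, embeddings$id), , drop = FALSE]
  post <- predict(model, emb)
  lab <- posterior_labels(post)
  tibble::tibble(id = item_ids, proposed_label = lab,
                 confidence = post$prob[cbind(seq_along(lab), lab)])
}

#' Review the auto-labeled items
#'
#' Compares every auto-label to the ground truth, corrects the wrong ones,
#' and marks all auto items `status = "reviewed"`. In cost accounting the
#' confirmed items take review seconds and the corrected items full labeling
#' minutes.
#'
#' @param run_or_pool An `al_run` or a pool tibble containing auto items.
#' @return A `review_report` list: `pool` (reviewed), `n_auto`, `n_correct`,
#'   `n_corrected`.
#' @export
review_pass <- function(run_or_pool) {
  pool <- if (inherits(run_or_pool, "al_run")) run_or_pool$pool else run_or_pool
  auto <- which(pool$status == "auto")
  if (length(auto) == 0L) {
    return(structure(list(pool = pool, n_auto = 0L, n_correct = 0L,
                          n_corrected = 0L), class = "review_report"))
  }
  wrong <- pool$label[auto] != pool$true_label[auto]
  pool$label[auto[wrong]] <- pool$true_label[auto[wrong]]
  pool$status[auto] <- "reviewed"
  structure(
    list(pool = pool, n_auto = length(auto),
         n_correct = sum(!wrong), n_corrected = sum(wrong)),
    class = "review_report"
  )
}

#' Summarize a learning curve against an accuracy target
#'
#' `fraction_to_reach` is the smallest recorded labeled fraction whose
#' accuracy meets the target (`Inf` if never reached — the campaign would
#' have labeled everything). The area under the curve is the trapezoid rule
#' over the fraction axis.
#'
#' @param curve A `learning_curve` tibble (`fraction_labeled`, `accuracy`).
#' @param target_accuracy Accuracy target.
#' @return A one-row tibble: `fraction_to_reach`, `auc`, `final_accuracy`.
#' @export
curve_metrics <- function(curve, target_accuracy = 0.9) {
  if (nrow(curve) == 0L) stop_usage("curve is empty")
  hit <- which(curve$accuracy >= target_accuracy)
  frac <- if (length(hit)) min(curve$fraction_labeled[hit]) else Inf
  auc <- if (nrow(curve) > 1L) {
    f <- curve$fraction_labeled; a <- curve$accuracy
    sum(diff(f) * (utils::head(a, -1) + a[-1]) / 2)
  } else 0
  tibble::tibble(fraction_to_reach = frac, auc = auc,
                 final_accuracy = curve$accuracy[nrow(curve)])
}

#' Write a labeling request for a human team
#'
#' Emits `request_round_<k>.csv` with the item ids (and any pre-label
#' proposals) for a round, so a real labeling team can work without a UI.
#'
#' @param ids Item ids to label.
#' @param round Round index.
#' @param dir Directory for the request file.
#' @param prelabels Optional tibble from [apply_prelabels()].
#' @return Invisibly, the written path.
#' @export
write_label_request <- function(ids, round, dir, prelabels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(id = ids)
  if (!is.null(prelabels) && nrow(prelabels) > 0L) {
    tab$proposed_label <- prelabels$proposed_label[match(ids, prelabels$id)]
  }
  path <- file.path(dir, sprintf("request_round_%d.csv", round))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a human labeling response into the pool
#'
#' Reads a CSV with columns `id,label`, records the labels and marks the
#' items `status = "human"` for the given round.
#'
#' @param pool The pool tibble.
#' @param path CSV path with the team's labels.
#' @param round Round index to record.
#' @return The updated pool.
#' @export
read_label_response <- function(pool, path, round) {
  tab <- utils::read.csv(path)
  idx <- match(tab$id, pool$id)
  if (anyNA(idx)) stop_usage("label response contains unknown ids")
  pool$label[idx] <- as.integer(tab$label)
  pool$status[idx] <- "human"
  pool$round[idx] <- as.integer(round)
  pool
}

#' @export
tidy.al_run <- function(x, ...) x$curve

#' @export
glance.al_run <- function(x, ...) {
  cm <- curve_metrics(x$curve, x$config$target_accuracy)
  tibble::tibble(
    strategy = x$config$strategy, seed = x$config$seed,
    rounds = x$state$rounds, stopped_reason = x$state$stopped_reason,
    n_human = x$state$n_human, n_auto = x$state$n_auto,
    fraction_labeled = x$state$n_human / nrow(x$pool),
    fraction_to_reach = cm$fraction_to_reach, auc = cm$auc,
    final_accuracy = cm$final_accuracy
  )
}
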