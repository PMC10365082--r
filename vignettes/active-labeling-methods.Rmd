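---
title: "Methods: active-learning labeling campaigns, their cost model, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active-learning labeling campaigns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activelabel)
```

# The problem

Supervised image classification in radiology needs expert labels, and
expert time is the binding constraint: minutes per image, across tens of
thousands of images, across multiple annotators. Active learning (AL)
attacks the problem by ordering the images so that the most informative
ones are labeled first. Once an intermediate model trained on the labeled
prefix is accurate enough, the remaining images are labeled automatically
and only *reviewed* by humans — and reviewing a proposed label takes
seconds where producing one takes minutes. The package implements this
workflow end to end, together with the person-year arithmetic that turns
labeled fractions into project cost, and a synthetic generator so the
entire pipeline can be exercised and benchmarked offline.

# The labeling loop

`run_al()` drives the canonical loop:

1. **Cold start.** Before any labels exist, the only usable structure is
   unsupervised. The embeddings are clustered with k-means
   (`fit_clusters()`) and the first batch is drawn round-robin across
   clusters (`diverse_batch()`), taking each cluster's most prototypical
   item (nearest the center) first. We use `k = max(2, round(sqrt(2 B)))`
   for batch size B: enough clusters that the first batch spans the
   coarse modes of the data, few enough that every cluster contributes
   more than one item as the batch grows. The draw order is largest
   cluster first, so multiplicities differ by at most one while clusters
   still have items.
2. **Label.** The batch goes to the labeler — in benchmark mode the
   simulated oracle (`labeling_oracle()`), which can optionally flip
   labels at a configurable error rate (symmetric over the wrong classes,
   default off); in a real campaign a function wired to
   `write_label_request()` / `read_label_response()` files.
3. **Train and track.** The learner is refit on the human-labeled items
   minus a stratified 20% held-out split (resampled each round under the
   run seed). Held-out accuracy is what a real campaign can observe, so
   it drives stopping. The split fraction is a judgment call; 80/20 is
   the conventional default and the test split never starves a class of
   its last training example.
4. **Stop or select.** The loop stops when the tracked accuracy reaches
   `target_accuracy`, or when the accuracy curve has hit its elbow:
   the best per-round gain over the last `patience_rounds` rounds falls
   below `min_gain` (defaults 3 rounds and 0.005). Otherwise the
   acquisition strategy ranks the unlabeled pool and the top batch goes
   back to step 2.
5. **Auto-label and review.** On stopping, every remaining item receives
   the learner's argmax label (`status = "auto"`), and `review_pass()`
   simulates the reviewer team: wrong auto-labels are corrected, all auto
   items end `status = "reviewed"`. Downstream cost accounting charges
   review seconds for confirmed items and full labeling minutes for
   corrected ones.

Items are labeled exactly once; the status machine only allows
`unlabeled → human`, `unlabeled → auto`, and `auto → reviewed`.

## Evaluation modes

`loop_config(eval = "holdout")` (default) scores the model on the
held-out labeled split — all that is observable in production.
`eval = "pool"` scores against the full pool's hidden ground truth, which
is only meaningful for benchmark replays of fully annotated data; the
benchmark harness uses it because it gives low-noise learning curves on
fixtures of a few hundred items, where a 20% split of the labeled prefix
would make early accuracy estimates jump in steps of 1/4.

# The learner

The AL model is a Gaussian process over the embedding space. We commit to
one-vs-rest GP *regression* on one-hot class targets (least-squares
classification): for class $c$ with targets $y_c \in \{0,1\}^n$,

$$\mu_c(x_*) = k_*^\top (K + \sigma_n^2 I)^{-1} y_c, \qquad
  v(x_*) = k(x_*, x_*) - k_*^\top (K + \sigma_n^2 I)^{-1} k_*,$$

with an RBF kernel. This is closed-form, deterministic, and exact — no
Laplace or EP approximation, no sampling — which matters both for
reproducibility and for testability (the posterior is checked against a
dense matrix-inversion oracle to 1e-8). Class probabilities are the means
clipped to $[10^{-6}, 1-10^{-6}]$ and renormalized per row: a monotone,
assumption-light map from regression outputs to a probability simplex.
The predictive variance depends only on the query location under a shared
kernel, and is the epistemic signal consumed by acquisition.

Defaults: median-heuristic length scale (median pairwise training
distance — scale-free and stable across rounds), $\sigma_n^2 = 10^{-4}$
(numerical jitter; large enough to keep Cholesky factorizations
well-conditioned, small enough not to smooth the interpolant visibly),
and a 2,000-point training cap with deterministic uniform subsampling
(never binding in the shipped fixtures).

# Acquisition

`select_batch()` implements five strategies. `random` is the baseline;
`entropy` scores the Shannon entropy of the predicted class
probabilities; `variance` the winning class's predictive variance. The
two Bayesian scores reduce the multi-class posterior per item to a binary
split — top class against the rest — keeping a single uncertainty model
per item:

* `beta_mi`: the top-class probability's mean $\mu$ and variance
  $\sigma^2$ are moment-matched to a Beta distribution
  ($\nu = \mu(1-\mu)/\sigma^2 - 1$, $\alpha = \mu\nu$,
  $\beta = (1-\mu)\nu$; a variance at or above the Bernoulli bound
  $\mu(1-\mu)$ is clipped to 0.999 of it so the match stays proper), and
  the item is scored by the mutual information between label and
  probability parameter,
  $MI = H_b(\mu) - E_{p\sim\text{Beta}}[H_b(p)]$, whose expectation has a
  digamma closed form. $MI$ is zero when the model is merely *aleatorically*
  uncertain ($\sigma^2 \to 0$ at any $\mu$) and grows strictly with
  $\sigma^2$ at fixed $\mu$ — labels are spent where they can change the
  model's mind.
* `bald`: the same quantity with the probability drawn from a truncated
  normal instead, estimated by Monte Carlo. It is the sampling-based
  state-of-the-art reference; the closed form and the Monte Carlo
  estimate agree to a few hundredths of a nat at moderate relative
  variance, and diverge by design as $\sigma^2$ approaches the Bernoulli
  bound, where the matched Beta turns bimodal and the truncated normal
  cannot.

Ties are broken by ascending item id so rankings are reproducible.
Scores are in nats throughout.

# Object discovery

The unsupervised localizer encodes two assumptions: objects are small and
surrounded by background, and the intensity distribution inside an
object's box differs from the distribution just outside it. Concretely,
`propose_boxes()`:

1. samples random rectangles per image (uniform positions, log-uniform
   sizes) as *seeds*;
2. snaps each seed to the bright region it covers (`refine_box()`): the
   bounding box of pixels above `median + f·(max − median)` of a window
   around the seed, with the window grown until the bright region is
   interior. Several snap strengths `f ∈ {0.2, 0.35, 0.5}` are kept as
   separate candidates and the scorer arbitrates; refined boxes are
   expanded to the minimum patch size so proposals never degenerate into
   pixel speckles;
3. scores every candidate as
   `objectness = color_divergence × rarity × size_prior`, where
   `color_divergence` is the Jensen–Shannon divergence (nats, bounded by
   ln 2) between 32-bin intensity histograms inside the box and in an
   equal-area surrounding ring, `rarity` is the mean distance to the k = 5
   nearest histogram embeddings of patches from *other* images (background
   texture recurs across images; objects do not), and
   `size_prior = exp(−area/(0.1·image area))`;
4. applies greedy non-maximum suppression at IoU 0.5 and sorts by
   descending objectness.

Histogram embeddings make the module run with no training at all; an
objectness-weighted contrastive loss over patch pairs
(`weighted_patch_loss()`) is provided for encoder-based refinement and
reduces exactly to the plain NT-Xent loss at equal weights.

# Contrastive embeddings

`nt_xent_loss()` is the standard normalized-temperature cross-entropy
over B positive pairs (cosine similarities, default τ = 0.5). The
shipped encoder (`train_encoder()`) is a flatten + two-layer perceptron
trained by full-gradient descent with analytic gradients (verified
against finite differences in the tests) and an accept/reject rule per
epoch — an epoch that worsens the loss on a fixed evaluation set is
reverted and the step size halved, so the accepted loss trajectory is
nonincreasing by construction. This is deliberately desk-scale: the
benchmark harness instead uses `oracle_embed()`, which returns the
generator's latent coordinates (optionally noised), standing in for a
well-trained encoder so the AL machinery can be studied without GPU
training in the loop.

# The synthetic generator

`dataset_spec()` defines the study conditions:

* **Latent mode** (`generate_latent()`): class centers at the vertices of
  a regular simplex with pairwise distance `separation`; items are
  centers plus isotropic Gaussian noise (`noise_sd`). Class counts come
  from largest-remainder rounding, so they always sum to `n_items` and
  the imbalanced preset — class weights 8,851 : 6,063 : 601, the
  composition of a public chest x-ray corpus — is reproduced exactly when
  `n_items` equals the sum of those weights (15,515).
* **Image mode** (`generate_images()`): low-frequency textured
  backgrounds whose smoothness and base intensity depend on the class, so
  classification is learnable from pixels; an optional bright elliptical
  lesion per image with a recorded ground-truth box. Lesions are compact
  (aspect ratio ≤ 2.5), kept 2 px inside the frame, and their bounding
  box covers at most 10% of the image — degenerate full-width streaks or
  edge-clipped blobs would contradict the "small object surrounded by
  background" premise the discovery module encodes.

Defaults for the benchmark fixture are `separation = 3.5`,
`noise_sd = 1`, `latent_dim = 8`. These were chosen once, from the
geometry: with centers 3.5 noise-units apart the Bayes-optimal accuracy
of the 3-class problem is roughly 0.94–0.95, comfortably above the 0.90
campaign target but far from trivial, so learning curves rise over many
rounds rather than saturating in one batch — the regime in which
acquisition strategies can be told apart. The generator emulates class
imbalance, class-dependent structure, and seeded reproducibility; it does
*not* emulate label noise between experts (available but off by default),
intra-class multimodality, scanner effects, or any real anatomy. Passing
benchmarks here shows the machinery ranks and stops correctly under known
geometry — not that any particular saving will materialize on a given
clinical dataset.

# Labeling economics

The cost model is exact closed-form arithmetic under the campaign
calendar 8 h/day × 21 days/month × 12 months/year = 2,016 working hours
per person-year. Full labeling costs
`n_images · n_labelers · minutes_per_label`; the AL scenario costs
`f·N·L·m` for the labeled fraction plus `(1−f)·N·R·s/60` for review, and
`saving_percent()` compares the two on unrounded values. Display
conventions (committed once, in `cost_summary()`): headline person-years
floor to an integer (24.8 → 24), scenario person-years round to one
decimal (3.224 → 3.2, 2.728 → 2.7), savings round to integer percent
computed on unrounded inputs (87, 89). Reviewer corrections of wrong
auto-labels are deliberately *not* part of the headline arithmetic — the
reference scenario assumes pure review — but `review_pass()` reports the
correction counts needed to price them.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: a 600-item, 10-seed,
batch-20 benchmark for strategy comparison (paired one-sided Wilcoxon on
fraction-to-target, with "never reached" counted as labeling everything);
50 images of 64×64 px for lesion localization (top-1 IoU ≥ 0.5 against
the generator's ground truth); 12-point fixtures for the GP-vs-dense-
oracle equivalence at 1e-8; and $10^5$-draw Monte Carlo for the Beta
mutual-information cross-check at 3 standard errors. These sizes keep a
full run in minutes on one CPU while leaving every comparison
statistically meaningful.

Degenerate inputs are handled explicitly: a single-class training set
raises a dedicated error instructing a more diverse batch; empty k-means
clusters are dropped with a warning; a box flush with every image edge
has no ring and scores zero divergence; probabilities are clipped before
renormalization; all seeds flow through `withr::with_seed()` so package
functions never disturb the caller's RNG state.

# Known limitations

* The GP is exact and dense: fitting is cubic in the training count. The
  `max_train` cap (default 2,000) keeps rounds tractable but turns the
  learner into a subsampled approximation on very large labeled sets.
* The Beta-MI score reduces multi-class uncertainty to top-class-vs-rest;
  items whose confusion is spread over three or more classes are scored
  only through their top class.
* Batch selection is pointwise: the top-B items by score may be mutually
  redundant. Batch-aware acquisition is out of scope.
* The final clinical model, multi-annotator disagreement, and labeling
  UIs are out of scope; the loop's output is a fully labeled, reviewed
  dataset and the cost ledger of producing it.
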