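# activelabel

Expert labeling is the dominant cost of building image-classification
models in medical imaging: a dataset of 100,000 images labeled by three
radiologists at 10 minutes per image consumes on the order of 24
person-years before any model training starts. **activelabel** is an R
toolkit for planning and benchmarking *active-learning (AL)* labeling
campaigns that cut this cost by an order of magnitude: the model chooses
which images the labeling team sees next, stops when accuracy is high
enough, auto-labels the remainder, and hands the auto-labels to a
reviewing team who confirm at seconds — rather than minutes — per image.

It is aimed at teams planning annotation campaigns (what will labeling
cost? how much does AL save?) and at methods researchers who want a small,
fully reproducible sandbox for batch-acquisition strategies.

## What is inside

The package implements the full advanced-AL workflow on top of a seeded
synthetic-data generator that emulates an imbalanced radiology
classification task (default class proportions 8,851 : 6,063 : 601):

* **Cold start** — k-means over unsupervised embeddings; the first batch is
  drawn round-robin across clusters for maximal diversity
  (`fit_clusters()`, `diverse_batch()`).
* **Learner** — one-vs-rest Gaussian-process regression on one-hot class
  targets over the embedding space, with an RBF kernel `K + σ_n²I` and
  median-heuristic length scale. Per-item predictive means give the
  auto-label; predictive variances feed acquisition (`gp_fit()`,
  `predict()`, `gp_evaluate()`).
* **Acquisition** — `select_batch()` ranks unlabeled items by `random`,
  `entropy`, `variance`, Monte-Carlo `bald`, or `beta_mi`: the top-class
  probability's mean μ and variance σ² are moment-matched to a
  Beta(α, β) with ν = μ(1−μ)/σ² − 1, α = μν, β = (1−μ)ν, and the item is
  scored by the mutual information

      MI = H_b(μ) − E_{p∼Beta(α,β)}[H_b(p)],

  where `H_b` is the binary entropy and the expectation has a digamma
  closed form. MI is large only when the model is uncertain *and* unsure
  of its own uncertainty — epistemic, not just aleatoric, doubt.
* **Loop** — `run_al()` orchestrates label → train → score → select,
  stops at a target accuracy or at the accuracy curve's elbow
  (plateau rule), auto-labels the rest, and `review_pass()` simulates the
  reviewer team. `run_benchmark()` replays the loop across strategies and
  seeds and `compare_strategies()` tests label-efficiency differences with
  a paired Wilcoxon test.
* **Object discovery** — unsupervised lesion localization: random patches
  are embedded as intensity histograms and candidate boxes scored
  `objectness = color_divergence × rarity × size_prior` (Jensen–Shannon
  divergence of inside-vs-ring histograms; mean distance to the k nearest
  cross-image patches; `exp(−area/(0.1·image area))`), with greedy NMS
  (`propose_boxes()`).
* **Economics** — `cost_scenario()`, `full_labeling_cost()`,
  `al_scenario_cost()` and `saving_percent()` convert counts and rates
  into person-years under an 8 h/day, 21 day/month work calendar
  (2,016 h per person-year).

## Worked example

```r
library(activelabel)

# 1. What does the reference campaign cost?
cost_summary(cost_scenario())
#>   full_person_years full_person_years_exact al_person_years al_person_years_exact
#> 1                24                    24.8             3.2                  3.22
#>   ... saving_pct 87, effort_reduction_pct 90
```

Labeling 100,000 images in full costs 24.8 person-years (headline: 24).
Labeling 10% and reviewing the rest at 20 s per image with three
reviewers costs 3.2 person-years — an 87% saving (89% with a single
reviewer).

```r
# 2. How many labels does each acquisition strategy need to hit 90% accuracy?
bench <- run_benchmark(dataset_spec(n_items = 600),
                       strategies = c("random", "entropy", "beta_mi"),
                       seeds = 1:10)
summary(bench)
#>   strategy mean_fraction_to_reach sd_fraction_to_reach mean_auc
#> 1 beta_mi                   0.193                0.138    0.139
#> 2 entropy                   0.323                0.102    0.247
#> 3 random                    0.537                0.405    0.167

compare_strategies(bench, "beta_mi", "random")
#>   strategy_a strategy_b mean_a mean_b mean_saving p_value n_seeds
#> 1 beta_mi    random      0.193  0.537       0.343  0.0263      10

autoplot(bench)   # mean accuracy curves ± 2 SD per strategy
```

On the imbalanced 3-class fixture the Beta-MI acquisition reaches the
0.90 accuracy target after labeling 19% of the pool on average, versus
54% for random-order labeling (paired one-sided Wilcoxon p = 0.026) —
the labeled-fraction saving is what drives the person-year arithmetic
above.

A thin CLI over the same functions lives in `inst/cli/alcli.R`
(`cost`, `generate`, `discover`, `benchmark` subcommands).

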