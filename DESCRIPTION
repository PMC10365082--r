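Package: activelabel
Title: Active-Learning Workflows for Image Labeling with Cost Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for planning and benchmarking active-learning (AL) labeling
    campaigns for image classification. Provides a diversity-based cold start
    from unsupervised clustering of embeddings, a Gaussian-process learner over
    contrastive (or synthetic oracle) embeddings, Bayesian batch acquisition
    including a Beta-moment-matched mutual-information score, unsupervised
    object discovery for lesion-like structures, a labeling-economics cost
    model in person-years, and a seeded synthetic-data generator emulating
    class-imbalanced radiology classification so the whole workflow can be
    benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
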