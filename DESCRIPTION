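Package: crossguild
Title: Hurdle Latent-Factor Joint Species Distribution Models for Paired
    Microbial Guilds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits hurdle (probit occurrence plus lognormal
    abundance-given-presence) joint species distribution models to paired
    community count tables, such as fungal and bacterial OTU tables from the
    same samples, by Gibbs sampling with sample-level latent factors.
    Residual species-to-species association networks are contrasted between
    null (sequencing-depth-only) and full (environmental) models, explained
    variance is partitioned among covariate groups and the random effect,
    and a conditional two-fold cross-validation quantifies the directional
    information value of one guild for predicting the other. Includes a
    generative simulator for paired zero-inflated communities with known
    ground truth, MCMC convergence diagnostics, tidy accessors, and plotting
    helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    coda,
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
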