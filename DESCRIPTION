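Package: riskclust
Title: Bayesian Clustering of Clinical Risk-Factor Profiles and
    Reference-Standardized Outcome Risk Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters subjects by binary clinical risk-factor profiles with a
    collapsed Beta-Bernoulli mixture model searched over partitions, then
    estimates cluster-specific risk ratios of binary pregnancy outcomes
    relative to general-population reference rates using exact binomial
    (Clopper-Pearson) inference with Benjamini-Hochberg and Bonferroni
    multiplicity control. Includes a logistic trend model of outcome risk
    against the number of risk factors, a composition-annotated cluster by
    outcome heat map, and a synthetic-cohort generator with known latent
    structure for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
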