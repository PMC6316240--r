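Package: mbrcampaign
Title: Design, Simulation and Multivariate Analytics for Parallel
    Mini-Bioreactor Fed-Batch Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing high-throughput fed-batch
    cultivation campaigns in 48-unit mini-bioreactor blocks. Computes
    two-phase bolus feed schedules (exponential, linear and constant
    profiles anchored to a common glucose total), simulates Crabtree-type
    overflow metabolism of recombinant Saccharomyces cerevisiae with
    staggered noisy at-line sampling, and provides the downstream
    multivariate chain: batch-wise-unfolded principal component analysis
    with Hotelling T2 outlier detection, k-means clustering of score
    space, classification and regression trees over the experimental
    design, and historical partial least squares regression with
    cross-validated forward variable selection for early prediction of
    volumetric enzyme activity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rpart,
    knitr
Config/testthat/edition: 3
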