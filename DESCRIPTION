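Package: zsustain
Type: Package
Title: Subtype and Stage Inference for Regional Brain Atrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Normative z-scoring of regional brain morphometry against a
    healthy-control regression model, z-score event-based subtype-and-stage
    modelling of gray-matter atrophy progression (greedy multi-start ascent,
    Markov chain Monte Carlo ordering uncertainty, hierarchical cluster
    splitting, cross-validated model-order selection), post-hoc assignment of
    individuals to trajectories and stages including a "no-atrophy" rule,
    subtype characterization statistics with false-discovery-rate control,
    and a subtype-stratified support-vector classifier of surgical prognosis
    with permutation testing. Includes a synthetic cohort generator with
    known ground truth for end-to-end recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
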