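Package: tselex
Title: Tissue-Selective Gene Expression Scoring from Integrated Microarray Compendia
Version: 0.1.0
Authors@R:
    person("Compendium", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous Affymetrix expression profiles into a
    single compendium (invariant-set normalization within tissue groups,
    model-based probe-set summarization with outlier-array exclusion, global
    median transformation) and ranks tissue-selective genes genome-wide with a
    two-part priority score that contrasts detection-call frequencies and mean
    expression levels between a target-tissue experiment set and an
    all-other-tissues control set, with permutation-based significance.
    Includes seeded simulators of multi-study, multi-tissue compendia with
    planted tissue-selective genes for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
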