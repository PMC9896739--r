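Package: dxrank
Title: Listwise Learning-to-Rank for Differential Diagnosis Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A clinical decision support core that maps a patient's observed
    symptoms to a ranked, scored list of candidate diseases. Training uses a
    one-hidden-layer neural scorer with a differentiable Approximate-NDCG
    listwise loss over graded case data (confirmed plus differential diseases),
    with a pointwise mean-squared-error baseline, exact graded-relevance ranking
    metrics (DCG, NDCG, NDCG@k, top-k hit), a seeded synthetic case-corpus
    generator, k-fold cross-validated system comparison, and progressive-input
    rank-trajectory reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
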