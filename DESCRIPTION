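Package: cooctraits
Title: Trait-Based Analysis of Pairwise Species Co-Occurrence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links pairwise species co-occurrence to trait dissimilarity in
    lake fish metacommunities. Computes the checkerboard C-score for every
    species pair in each watershed incidence matrix, standardizes it against a
    fixed-fixed null model sampled with the curveball Markov chain, pools the
    standardized effect sizes (SES) across watersheds, and regresses them on
    per-trait Euclidean distances (body size, temperature preference, trophic
    level) with Mantel-style permutation inference. Includes a synthetic
    metacommunity generator with tunable environmental filtering, predation
    and competition effects for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
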