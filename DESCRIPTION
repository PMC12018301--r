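Package: hdselect
Title: Hyperdimensional Computing Classification and Backward Feature
    Elimination for Microbial Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised classification with a Multiply-Add-Permute (MAP)
    vector-symbolic architecture: scalar feature values are quantized onto a
    family of correlated bipolar level hypervectors, samples are encoded by
    positional permutation and bundling, and one integer class vector per
    class is accumulated and refined by iterative error-mitigation
    (retraining). On top of the classifier, a stepwise backward variable
    elimination wrapper selects discriminative features under k-fold
    cross-validation, with band-based multi-feature removal, a stop rule on
    accuracy decrease, and a frontier of compact suboptimal models. Includes
    readers and preprocessing for MetaPhlAn-style merged relative-abundance
    tables (cross-study species intersection, low-abundance and
    low-prevalence filtering, presence/absence binarization, sex and age
    stratification), per-species differential-abundance statistics (prevalence,
    log2 fold change, Wilcoxon rank-sum with Benjamini-Hochberg correction),
    seeded synthetic data generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
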