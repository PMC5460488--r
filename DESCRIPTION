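Package: funcorr
Title: Functional Correlation of Expression Divergence with Noncoding Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links between-species differential gene expression to signals of
    adaptive noncoding sequence change through gene-set statistics. Provides
    negative-binomial GLM differential-expression scoring across tissues,
    squared-cosine tissue-specificity scores, rank-biserial gene-set
    enrichment with bootstrap standard errors, fixed-effects meta-analytic
    combination of enrichment across studies with Cochran heterogeneity
    filtering, and an overlap-aware gene-level permutation test for the
    per-collection Spearman correlation between enrichment profiles. Includes
    a negative-binomial synthetic-data generator with planted set-level
    coupling between differential expression and adaptation for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
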