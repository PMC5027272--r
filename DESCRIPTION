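Package: embryomix
Title: Binomial Mixture Exclusion Bounds and Combination-Enumeration
    Expression Nulls for Mixed Embryo Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tools for asking whether the full-term offspring of
    a phenotypically mixed embryo cohort could derive from a hidden,
    normally-developing subpopulation. Implements a two-phenotype binomial
    mixture model that bounds, worst-case over the unknown admixture
    fraction, the probability that at least n of the observed term offspring
    derive from the high-rate phenotype, combined with concordant-assay
    evidence factors. Also implements a combination-enumeration null for
    two-group microarray comparisons: exhaustive or sampled group
    reassignments, moderated t-statistics with empirical-Bayes variance
    shrinkage, Benjamini-Hochberg adjustment, probe disambiguation, and
    kernel-smoothed rank-versus-p density summaries. Ships synthetic
    generators for cohort outcomes and sibling-paired expression studies so
    every analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
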