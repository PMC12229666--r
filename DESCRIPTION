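Package: cismr
Title: Pleiotropy-Robust cis Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal inference between two traits from GWAS summary statistics in a
    single genomic region. Implements the MR-link-2 likelihood, which jointly
    estimates a causal effect and a horizontal-pleiotropy variance component from
    exposure and outcome association statistics together with a linkage
    disequilibrium (LD) reference, using an eigendecomposition of the regional LD
    matrix. Also provides the classical cis-MR estimators (Wald ratio, IVW, LD-aware
    IVW, and principal-component IVW), summary-statistic harmonization and
    standardization, P-value clumping and region merging, inverse-variance
    meta-analysis with Cochran's Q, a generative simulator for regional summary
    statistics (including Wishart-sampled imprecise LD references), and benchmark
    metrics (type-I error, power, AUC, precision/recall).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
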