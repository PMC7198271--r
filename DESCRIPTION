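Package: lbrmap
Title: Local Bayesian Regressions for Mapping Sex-Specific Genetic Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits spike-slab Bayesian multiple regressions on long, overlapping
    chromosome segments to estimate sex-specific SNP effects and gene-by-sex
    (GxS) interactions from biobank-style genotype and phenotype data.
    Posterior samples are post-processed into SNP-level posterior probabilities
    of nonzero male/female effects and of sex differences, and aggregated into
    LD-based window variances with corresponding window-level probabilities.
    Includes a PLINK 1 binary reader/writer, a single-marker-regression
    baseline with per-sex effect estimates and a sex-difference test, a
    synthetic genotype/trait simulator with controllable LD decay and
    sex-specific architectures, and power/FDR evaluation machinery with
    target-area (masked-causal) resolution and hypergeometric enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
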