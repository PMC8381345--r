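Package: locustriage
Title: Integrative Triage of GWAS Loci with CRISPR Screens and eQTL
    Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate causal genes in a GWAS locus by combining
    three independent lines of evidence: gene-level rankings of a pooled
    CRISPR loss-of-function screen from guide read counts (second-best
    score, robust rank aggregation, and a weighted-sum of guide ranks), a
    permutation test for inflation of GWAS association signal at lead
    cis-eQTLs of a target gene set (the quantile-based lambda statistic),
    and Bayesian colocalization of GWAS and cis-eQTL summary statistics
    under a single-causal-variant model (Wakefield approximate Bayes
    factors) with iterative LD masking of secondary signals. Includes
    readers and writers for the tabular summary-statistic formats the
    pipeline consumes, LD utilities, and seeded synthetic-data generators
    (AR(1) LD blocks, marginal regression summary statistics, negative
    binomial screen counts) so the full pipeline runs end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
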