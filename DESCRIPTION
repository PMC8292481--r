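Package: chek2mod
Title: Discovery and Validation Statistics for Genetic Modifiers of
    CHEK2 c.1100delC Breast Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for searching for genetic modifiers of the
    breast-cancer risk conferred by the CHEK2 c.1100delC protein-truncating
    allele. Implements the discovery-phase candidate filters
    (allele-frequency-ratio, reference-database enrichment, per-group call
    rate, and a recessive homozygote screen), the validation-phase
    contingency-table statistics (allelic and dominant odds ratios, Woolf and
    exact-conditional confidence intervals, Pearson chi-square and Fisher
    exact tests, conditional maximum-likelihood odds ratios), case-only
    gene-gene interaction analysis with study-stratified Mantel-Haenszel
    pooling, a logistic interaction model with likelihood-ratio testing, and
    a Hardy-Weinberg cohort simulator so that every stage is testable without
    external data. Ships transcribed multi-cohort genotype-count fixtures and
    a replication report that recomputes them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
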