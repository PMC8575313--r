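Package: obscan
Title: Homozygosity-Aware Rare-Variant Prioritisation and Case-Control
    Burden Scanning
Version: 0.1.0
Authors@R:
    person("OBScan", "Developers", email = "obscan@example.org",
           role = c("aut", "cre"))
Description: Tools for gene discovery in severe obesity cohorts with
    consanguineous ancestry. Implements site-level quality-control
    dialects for exome variant calls, tiered population allele-frequency
    and consequence filters, discovery of homozygous rare coding variants
    restricted to runs of homozygosity (ROH), karyotype-wide ROH coverage
    binning, gene prioritisation rules, human-to-fly orthologue mapping by
    DIOPT score, exact 2x2 carrier statistics (Fisher two-sided p-value,
    conditional-MLE odds ratio with exact confidence interval), a binary
    trait weighted burden score test, Benjamini-Hochberg and Holm
    adjustment, sliding-window association scanning over canonical
    transcript protein coordinates, kinship-based unrelated-subset
    selection, BMI dichotomisation, and a synthetic-cohort generator with
    inbreeding-driven homozygosity and region-localised carrier effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
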