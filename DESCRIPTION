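Package: sexmark
Title: Sex-Linked Marker Discovery and Genotypic Sexing from GBS/RAD Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens reduced-representation sequencing (GBS/RAD-seq) genotype
    catalogs for sex-linked markers using three per-sex criteria (allele
    frequency differentiation, heterozygosity contrast, and sex-limited tag
    presence), classifies the heterogametic system (XY versus ZW), applies
    E-value rules to alignment hits to confirm markers against a reference,
    proposes sequence-difference and allele-specific 3'-anchored validation
    primers, and calls genotypic sex from marker panels to flag putative sex
    reversals. Includes a truth-tracked genotype simulator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    Biostrings
Config/testthat/edition: 3
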