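Package: beetqtl
Title: QTL Detection and Comparison in Structured Sugar-Beet Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing quantitative trait locus (QTL) detection between
    a biparental (elite x exotic) sugar-beet progeny and a structured elite panel.
    Includes a synthetic-data generator for biparental crosses, structured panels
    and lattice field trials; per-environment mixed-model adjustment of plot data
    with generalized heritability; genotype quality-control filters; two-point
    linkage estimation and grouping with Haldane distances; NOIA additive and
    dominance kinships; multi-locus mixed-model association scans with forward
    selection and BIC/eBIC model choice; kinship- and structure-corrected linkage
    disequilibrium thresholds; and merging of detected SNPs into QTLs with
    favorable-allele labeling and cross-population colocation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lme4,
    igraph,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
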