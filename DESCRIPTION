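Package: cnvpop
Title: Population Genetics of Genic Copy Number Variation
Version: 0.1.0
Authors@R: person("cnvpop", "developers", role = c("aut", "cre"),
    email = "cnvpop@example.org")
Description: Downstream population-genetic analysis of copy number variant
    (CNV) call sets from short-read resequencing of structured natural
    populations. Starting from per-individual CNV calls (BED-like intervals
    with estimated diploid copy numbers), the package filters calls against
    assembly gaps and a minimum length, merges calls across individuals into
    CNV regions (CNVRs), partitions CNVRs by overlap with large segmental
    duplications, identifies CNV genes by whole-transcription-unit
    containment, genotypes gene copy number per individual with X-chromosome
    hemizygosity in males, and scans for population differentiation with the
    V_ST statistic, one-way ANOVA with Benjamini-Hochberg false discovery
    rate control and Tukey HSD post hoc tests, deletion allele frequencies,
    nonmetric multidimensional scaling of standardized copy numbers, and a
    genome-permutation null for CNVR-gene overlap. A seeded synthetic-data
    generator emulates the population structure these analyses assume so the
    whole pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
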