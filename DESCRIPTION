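Package: clonaltraj
Title: Clonal Allele-Frequency Trajectories and Multi-Omic Dynamics in
    Serially Passaged Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of clonal dynamics across serially passaged
    patient-derived xenograft (PDX) tumors under drug treatment.
    Computes per-generation alternate-allele frequencies from
    multi-sample VCFs, applies a monotone allele-frequency trajectory
    filter, embeds samples by classical multidimensional scaling on
    genotype Hamming distances, selects differentially expressed genes
    across generations by one-way ANOVA, tests genotype-expression
    association for loci mapped to genes, intersects candidate genes
    with immune gene sets, scores miRNA-target expression trend
    concordance, and computes in-vivo efficacy metrics (tumor volume,
    T/C, tumor growth inhibition).  Includes a deterministic
    synthetic-cohort generator emulating a five-generation,
    three-replicate study design with planted selection, expression and
    growth-response structure, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    cluster,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
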