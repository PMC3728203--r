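Package: ciseqtl
Title: Cis-eQTL Mapping at GWAS Loci with Discovery-Replication Design
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Refines disease susceptibility loci from genome-wide association
    studies by mapping cis-acting expression quantitative trait loci (eQTLs)
    within locus windows. Expression traits are adjusted for age, sex and
    smoking status by Huber robust regression, residual outliers beyond three
    standard deviations of the median are masked, and every SNP-probeset pair
    in a window is tested by simple linear regression on allele dosage with
    Wald p-values. Per-locus significance thresholds use a Bonferroni
    correction over the Li-Ji effective number of independent SNPs and
    probesets. Significant eQTLs are linked to GWAS SNPs through dosage
    r-squared and classified by replication status across additional cohorts.
    Includes a haplotype-block genotype and expression simulator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    MASS,
    VariantAnnotation,
    S4Vectors,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
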