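Package: haplofine
Title: Cross-Population Haplotype Fine-Mapping of Case/Control Association Regions
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fine-maps a disease-associated linkage-disequilibrium region by
    combining case/control cohorts from several populations. Provides per-SNP
    quality control (minor-allele frequency, exact Hardy-Weinberg test) and
    covariate-adjusted logistic association per population and jointly;
    EM haplotype-frequency estimation from unphased genotypes with
    per-individual posteriors, two-locus LD statistics (r-squared, D-prime)
    and confidence-interval haplotype blocks; haplotype logistic regression
    on expected dosages; cross-population core-haplotype intersection with
    identification of the SNPs whose minor alleles separate the protective
    from the risk haplotype; and regulatory prioritization of the refined
    SNP set via interval overlap and position-weight-matrix motif-disruption
    scoring. A synthetic multi-population cohort generator with truth records
    supports calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
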