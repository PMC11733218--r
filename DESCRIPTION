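Package: duoburden
Title: Rare-Variant Gene Burden Tests for Birth Weight with
    Maternal-Fetal Effect Deconvolution
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exome-style rare-variant association analysis of birth weight
    in mother-child designs. Provides genotype-call quality control (depth,
    genotype quality, heterozygous allele-balance binomial test, variant
    missingness, alternate-read-depth slope regression), variant collapsing
    masks (high-confidence protein-truncating variants, deleterious missense
    by CADD, experimental and clinical classifications), per-gene carrier
    burden tests with covariate adjustment, exome-wide and
    Benjamini-Hochberg multiple-testing procedures, weighted-linear-model
    deconvolution of marginal fetal and maternal effect estimates into
    approximately conditional ones, sexual-dimorphism and directional
    replication tests, GWAS-signal proximity mapping, and a mother-child
    duo simulator with read-level data and known truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, IRanges, GenomicRanges,
    vcfR, data.table, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
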