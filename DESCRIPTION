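Package: irscan
Title: Targeted-Sequencing Association Scan for Insecticide Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of targeted amplicon resequencing panels for
    genotype-phenotype association in insecticide-resistant mosquito
    cohorts. Annotates SNPs against a gene-panel model (region, codon,
    synonymous/nonsynonymous effect with strand handling), runs a
    carrier-based Fisher/AUC/Cochran-Armitage filtering cascade with
    population frequency reporting, detects gene copy-number variation
    from read depth via RPKM/ZRPKM/SVD denoising with group-level
    duplicated/deleted determination, mRMR ranking and qPCR fold-change
    validation math, and selects structural SNPs by discriminant analysis
    of principal components with snpzip-style loading clustering. A
    synthetic cohort generator with ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Biostrings,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
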