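Package: comprel
Title: Compression-Based Genetic Relatedness and Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates genetic relatedness between genotyped individuals from
    the normalized compression distance (NCD) of their SNP genotype strings,
    and turns those distances into compression relationship matrices (CRM1,
    CRM2 and CRM3) alongside the pedigree numerator relationship matrix (NRM)
    and the VanRaden genomic relationship matrix (GRM). A multi-kernel REML /
    BLUP engine estimates variance components, missing heritability and
    cross-validation prediction accuracy for any combination of relationship
    matrices, and a sliding-window scan combines population-level
    heterozygosity-corrected compression efficiency (CEh) with window-average
    FST to flag candidate selection sweeps. A seeded simulator (gene-dropping
    through pedigrees, Balding-Nichols population divergence, localized
    sweeps, phenotypes with a given heritability) makes every component
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), vcfR, jsonlite, optparse, withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
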