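Package: capripop
Title: Multi-Breed SNP-Array Population Genomics for Goats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for multi-breed SNP-array population genomics
    in goats and other livestock: PLINK-text genotype input and quality
    control, per-breed genetic diversity metrics, five genomic and pedigree
    inbreeding estimators, runs-of-homozygosity detection with a
    false-positive-controlled minimum-SNP bound, smoothed per-SNP FST
    selection-signature scans under breed-contrast scenarios, Reynolds
    distances with neighbour-joining population trees and a tree-kinship
    single-SNP FLK test, and a mixed-model genome-wide association scan with
    a genomic relationship matrix. Includes a Balding-Nichols multi-breed
    genotype simulator with planted sweeps, homozygous segments, pedigrees
    and a breed-coded phenotype so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
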