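Package: polysim
Title: Forward Simulation of Genotypes and Complex Phenotypes in Polyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-dropping simulator for polyploid species of arbitrary even
    ploidy. Inheritance along a pedigree is stored as sparse recombination
    breakpoints over founder haplotypes; meiotic pairing spans the
    autopolyploid-allopolyploid continuum through a preferential pairing
    factor. Simulates any number of additive/threshold-dominance traits
    calibrated to target heritabilities, builds polyploid genomic
    relationship matrices (true dosage, diploidized and haploidized
    scorings) and pedigree numerator relationship matrices, evaluates
    genomic selection accuracy by GBLUP, and converts sequencing read
    counts to allele dosages with the associated variant filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
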