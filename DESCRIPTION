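Package: crossgwas
Title: Epistasis-Aware GWAS for Crossbred Populations with Pedigree-Corrected Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome scans for additive, dominance and pairwise epistasis effects
    (additive x additive, additive x dominance, dominance x additive, dominance x
    dominance) in admixed or crossbred populations. Genotypic values of one- and
    two-locus SNP genotype classes are estimated by approximate generalized least
    squares: phenotypes are pre-corrected with pedigree breeding values (2 x PTA)
    and class means are fitted by least squares, with contrast t-tests of the
    Kempthorne orthogonal partition of genotypic values extended to Hardy-Weinberg
    and linkage disequilibria. Includes small-scale pedigree BLUP machinery
    (additive relationship matrix, mixed model equations), PLINK text/binary
    genotype input, and a crossbred-population simulator with planted single-locus
    and pairwise genetic architectures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
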