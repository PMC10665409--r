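Package: meiomap
Title: Individual Meiotic Recombination Phenotypes in Large Full-Sib Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Phenotyping of individual meiotic recombination from SNP
    genotypes in large full-sib pedigrees, modelled on aquaculture
    breeding designs.  Phases the gametes a focal parent transmits to
    its offspring, counts crossovers per meiosis, computes the
    intra-chromosomal allelic-shuffling statistic (r-bar), builds
    sex-specific Haldane linkage maps and fine-scale cM/Mb landscapes,
    estimates heritability and repeatability of recombination traits
    with an average-information REML animal model on a genomic
    relationship matrix, and runs a weighted leave-one-chromosome-out
    mixed-model GWAS.  Includes a gamete-level meiosis simulator with
    sex-dimorphic crossover landscapes that provides ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
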