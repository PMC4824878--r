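Package: hakecheck
Title: Distinguishing Hybridization from Homoplasy with Microsatellite Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether putative microsatellite hybrids between
    two divergent species reflect real heterospecific crosses, retained
    ancestral polymorphism, or size homoplasy. Provides genotype-table and
    sequence containers with GenePop and FASTA readers, a two-species
    synthetic-data generator with null alleles and species-diagnostic flanking
    haplotypes, descriptive and inferential population-genetic statistics
    (heterozygosity, rarefaction allelic richness, null-allele EM estimation,
    Weir-Cockerham FST with ENA correction, linkage and outlier scans),
    Hybridlab-style simulation of F1/F2/backcross genotypes, from-scratch
    Bayesian assignment samplers (admixture model variants and a six-class
    hybrid-category model), a validation pipeline producing accuracy and
    hybrid-call tables, and homoplasy verification via stepwise-mutation-model
    simulation with exact identity-by-descent bookkeeping, flanking-sequence
    diagnostics, and K80 neighbor-joining monophyly checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
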