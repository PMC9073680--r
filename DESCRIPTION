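Package: hornscan
Title: Population Genomic Scans for Segregating Inversions in the Tobacco Hornworm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-genome resequencing analysis of structured
    insect populations, built around the tobacco hornworm (Manduca sexta)
    three-population study design. Implements outgroup-parsimony
    polarization of ancestral alleles, Hudson-estimator F_ST in sliding
    windows with outlier-region merging, detection and genotyping of
    segregating chromosomal inversions from modal allele-frequency tracts
    (with Z-chromosome hemizygosity), coding-site degeneracy
    classification with pN/pS, nucleotide diversity and Tajima's D,
    synteny-vote anchoring of assembly scaffolds to chromosomes, and
    expression-specificity (SPM) profiling with enrichment tests. A
    Balding-Nichols synthetic-data generator emulates the study's sampling
    design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
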