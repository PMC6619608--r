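Package: larchvar
Title: Organelle Genome Variation, Diagnostic Markers and Haplotype
    Networks for Northern Larches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies variation (SNPs, InDels, homopolymer
    length differences, short stem-loop inversions) from whole-genome
    multiple alignments of near-identical circular organelle genomes,
    annotates coding effects of SNPs under the bacterial/plastid genetic
    code including amino-acid property-class changes, applies robustness
    and anti-paralogy filters to mitochondrial SNP matrices with missing
    data, screens allele matrices for group-diagnostic SNPs and evaluates
    short-amplicon windows for ancient-DNA assays, and builds statistical
    parsimony haplotype networks with inferred intermediate haplotypes.
    Includes a synthetic-data generator with a planted truth table so
    every pipeline stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
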