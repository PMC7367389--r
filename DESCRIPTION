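Package: mitostr
Title: Copy-Number Variation of Short Tandem Repeats in Circular
    Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Mito", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing intra-individual sequence heterogeneity of
    small circular (mitochondrial) genomes from deep amplicon sequencing.
    Catalogues short tandem repeats (STRs, including homopolymers) with the
    m x n unit-length/copy-number classification, parses per-position allele
    counts in the samtools pileup dialect, expands +/- indel labels into
    concrete STR alleles, computes alternative-allele ratios and applies a
    ratio threshold to call STR copy-number variation, predicts frameshift
    consequences of unit gains/losses inside protein-coding genes under the
    invertebrate mitochondrial genetic code, validates gap-free/overlap-free
    circular genome annotations with wrap-around coordinates, decomposes
    tandem-repeat arrays into named unit types, detects inverted-repeat
    flanked transposon-like elements with read-level inversion-junction
    support, and simulates genomes, pileups and reads under a replication
    slippage model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
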