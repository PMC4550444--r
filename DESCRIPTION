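Package: mitochar
Title: Characterization of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the standard descriptive analysis of animal
    mitochondrial genomes: base composition and AT/GC skew over
    annotation-defined partitions, codon usage and relative synonymous
    codon usage (RSCU) under the invertebrate mitochondrial code,
    overlap and intergenic-spacer ledgers on circular annotations,
    constrained cloverleaf folding of tRNA genes with G-U wobble
    pairing, motif/poly-tract/microsatellite/tandem-repeat scanning of
    A+T-rich control regions, gene-order rearrangement comparison, and
    a distance-based (neighbor-joining) phylogeny over concatenated
    protein-coding genes.  Includes a seeded synthetic mitogenome
    generator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
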