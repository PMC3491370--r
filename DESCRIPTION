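Package: macrosat
Title: Macrosatellite Tandem Repeat Discovery and Allele-Aware
    Epigenomic Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to discover and characterize macrosatellite tandem
    repeats from genomic sequence, modelled on the analysis of the mouse
    Dxz4 array. Includes seed-based self-alignment with tandem-array and
    inverted-repeat calling, anchor-phased monomer decomposition with
    inter-monomer divergence and internal VNTR copy-number estimation,
    CpG/GC composition metrics and CpG-island calling, bisulfite clone
    methylation profiling with an unequal-variance group comparison,
    strain-SNP based allele-specific read assignment, and cross-species
    conserved-window extraction with position weight matrix construction
    and IUPAC consensus matching. A synthetic-data generator with full
    planted ground truth makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
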