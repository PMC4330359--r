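Package: tfcoop
Title: DNA-Mediated Transcription-Factor Cooperativity from Gel, Motif and NMR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for dissecting cooperative binding of two
    transcription factors (a Sox HMG domain and a Pax paired domain) to
    composite enhancer DNA elements. Solves the four-microstate equilibrium
    (free DNA, each single-factor complex, the ternary complex) under full
    mass balance; estimates the cooperativity factor omega from quantified
    electrophoretic mobility shift assay (EMSA) band fractions with replicate
    statistics and dissociation-constant fitting; scans sequences for rigidly
    spaced composite sox-pax motifs written as degenerate IUPAC words,
    including spacer and nucleotide-switch variant construction and
    position-frequency-matrix information content; intersects ChIP-seq peak
    sets into co-bound regions and reports motif occurrence fractions; and
    computes weighted amide chemical-shift perturbations between NMR titration
    states. Synthetic-data generators with full ground truth (noisy gel lanes
    drawn from the equilibrium model, genomes with planted composite sites,
    paired NMR peak lists) stand in for wet-lab inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
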