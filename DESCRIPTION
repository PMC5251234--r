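Package: tvcurve
Title: Alignment-Free RNA Secondary-Structure Comparison via Triple-Vector
    Curves and Multi-Scale Wavelet Similarity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes an RNA sequence together with its secondary structure as a
    triple-vector curve (TV-curve): each of the eight characteristic symbols
    (A, C, G, U unpaired; A', C', G', U' paired) maps to three +/-1 vertical
    steps whose cumulative sum traces a 2D curve. Pairs of curves are compared
    by a multi-scale similarity, the weighted sum of Pearson correlations
    between their wavelet coefficient vectors at each decomposition level.
    On top of the resulting structural distance the package provides
    single-point mutation scanning (deleteriousness profiles, ranked mutant
    tables), all-pairs distance matrices and UPGMA phylogenetic trees with
    Newick export, a deterministic maximum-base-pairing folding fallback and
    an adapter for the ViennaRNA RNAfold predictor, readers and writers for a
    dot-bracket-extended FASTA dialect, a synthetic sequence-family generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
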