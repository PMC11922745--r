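Package: breakmapr
Title: Strand-Specific DNA Double-Strand-Break End-Map Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing strand-specific 5'-end maps of protein-induced
    DNA double-strand breaks, as produced by TDP2-seq-style sequencing of
    SPO11 cleavage products. Provides strand-separated per-nucleotide count
    tracks with RPM normalization, masking and Hann display smoothing;
    threshold-based single-nucleotide peak calling with an exclusion rule for
    incomplete 5'-overhang fill-in artifacts; strand cross-correlation
    analysis to verify break polarity and infer overhang length; dyad-centred
    base-composition matrices with G+C-corrected sequence-logo scores and
    averaged signal profiles; IUPAC degenerate-motif scanning with
    motif-centred signal averaging; and a synthetic break-map generator with
    a rotationally symmetric cleavage-preference model, fill-in artifact
    fraction and uniform background, supplying ground truth for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
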