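Package: dletools
Title: Composite Sequence-Structure Analysis of Nodal 3'UTR Dorsal
    Localization Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scans 3'UTRs for the composite dorsal localization element
    (DLE) of Nodal-pathway mRNAs -- a GCAC-anchored sequence motif
    followed by a short stem-loop -- and quantifies its structural
    context. Provides a constrained Boltzmann-ensemble folding model to
    compute the probability that the DLE hairpin forms in sequence
    context across temperatures, an analysis of dinucleotide-repeat
    masking of the hairpin, an orthologue conservation score based on
    alignment-averaged base-pair probabilities, and a two-channel
    fluorescent reporter ratio quantification pipeline with two-way
    ANOVA group statistics. Includes synthetic-data generators with
    known ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    EBImage,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
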