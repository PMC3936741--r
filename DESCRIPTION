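Package: splicefinder
Title: Spliced RNA-Seq Read Mapping and Splice-Junction Denoising for Compact Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps RNA-seq reads across splice junctions by anchor-and-extend
    gapped alignment against a k-mer genome index, rescues reads spanning short
    exons by realignment to pseudo-transcripts built around predicted junctions,
    characterises every candidate junction with nine alignment- and
    sequence-derived features, and separates functional junctions from splicing
    noise with a self-labelled RBF support vector machine whose decision values
    are calibrated to posterior probabilities. Sequence models (splice-site
    position-specific frequency matrices, intron length distribution, background
    composition) are estimated from labelled introns or supplied as a parameter
    file. Includes a synthetic-data generator producing compact genomes,
    expression-weighted transcripts, splicing-noise transcripts and error-bearing
    paired-end reads with full ground truth, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    e1071,
    Biostrings,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
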