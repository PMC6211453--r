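Package: clipHMM
Title: Protocol-Agnostic CLIP-Seq Peak Calling with a Non-Homogeneous HMM
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies protein-RNA interaction sites from CLIP-seq data of
    any flavour (PAR-CLIP, HITS-CLIP, iCLIP, eCLIP) by segmenting per-gene
    read profiles with a four-state non-homogeneous hidden Markov model.
    Emissions combine a negative-binomial generalized linear model of read
    coverage across CLIP and background libraries with a
    Dirichlet-multinomial mixture over diagnostic events (conversions,
    deletions, read ends), so the relevant crosslink chemistry is learned
    from the data rather than assumed. Includes a CLIP-seq read simulator
    with planted, motif-anchored crosslink sites for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Sequencing, Transcriptomics, PeakDetection, HiddenMarkovModel
RoxygenNote: 7.3.3
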