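Package: probeRemap
Title: Genomic Re-Annotation of Microarray Oligonucleotide Reporters
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Maps short oligonucleotide array reporters (probes) and their
    source ESTs to a genome and a predicted transcript set with a built-in
    ungapped seed-and-extend aligner, reconciles transcript-level and
    genome-level evidence through transcript genomic coordinates, and assigns
    each reporter to one of six genomic annotation groups (sense gene model,
    antisense gene model, gDNA, EST, ambiguous, inconclusive). Includes
    spliced two-block alignment for intron-spanning reporters, BLAST tabular
    import of externally computed searches, expression signal-to-noise
    flagging, GFF3 annotation-track export, and a deterministic synthetic
    fixture generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'probeRemap-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'hits.R'
    'oligoalign.R'
    'evidence.R'
    'agreement.R'
    'classify.R'
    'fixtures.R'
    'cli.R'
    'seqio.R'
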