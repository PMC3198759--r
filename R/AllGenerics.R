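#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small accessor generics for the S4 containers: configuration thresholds,
#' seed-index properties and transcript-model components.
#'
#' @param x a `PipelineConfig`, `SeedIndex` or `TranscriptModels` object.
#' @return The corresponding slot value; `nPostings()` returns the number
#'   of k-mer postings the index yields over its targets.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wordSize", function(x) standardGeneric("wordSize"))
#' @rdname accessors
#' @export
setGeneric("minContiguous", function(x) standardGeneric("minContiguous"))
#' @rdname accessors
#' @export
setGeneric("nPostings", function(x) standardGeneric("nPostings"))
#' @rdname accessors
#' @export
setGeneric("transcriptRanges", function(x) standardGeneric("transcriptRanges"))
#' @rdname accessors
#' @export
setGeneric("exonBlocks", function(x) standardGeneric("exonBlocks"))
#' @rdname accessors
#' @export
setGeneric("cdsBlocks", function(x) standardGeneric("cdsBlocks"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setMethod("wordSize", "PipelineConfig", function(x) x@wordSize)
#' @rdname accessors
#' @export
setMethod("minContiguous", "PipelineConfig", function(x) x@minContiguous)
#' @rdname accessors
#' @export
setMethod("wordSize", "SeedIndex", function(x) x@k)
#' @rdname accessors
#' @export
setMethod("nPostings", "SeedIndex",
          function(x) cpp_n_postings(unname(x@targets), x@k))
#' @rdname accessors
#' @export
setMethod("transcriptRanges", "TranscriptModels", function(x) x@transcripts)
#' @rdname accessors
#' @export
setMethod("exonBlocks", "TranscriptModels", function(x) x@exons)
#' @rdname accessors
#' @export
setMethod("cdsBlocks", "TranscriptModels", function(x) x@cds)
#' @rdname accessors
#' @export
setMethod("geneIds", "TranscriptModels",
          function(x) unique(S4Vectors::mcols(x@transcripts)$gene_id))

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  word size / min contiguous : %d / %d\n",
              object@wordSize, object@minContiguous))
  cat(sprintf("  multi-hit identity         : >= %d/%d\n",
              object@multiHitMinIdentity, object@reporterLength))
  cat(sprintf("  EST E-value (top / multi)  : %g / %g\n",
              object@estTopEvalue, object@estMultiEvalue))
  cat(sprintf("  spliced normalised score   : >= %g\n",
              object@exonerateNormScoreMin))
  cat(sprintf("  SNR threshold (strict >)   : %g\n", object@snrThreshold))
  cat(sprintf("  intron bracket             : %d..%d bp\n",
              object@minIntron, object@maxIntron))
})

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf("ScoringScheme: match %+g mismatch %+g (lambda %g, K %g)\n",
              object@match, object@mismatch,
              object@karlinLambda, object@karlinK))
})

setMethod("show", "SeedIndex", function(object) {
  cat(sprintf("SeedIndex: k = %d over %d target(s), %s bp total\n",
              object@k, length(object@targets),
              format(sum(nchar(object@targets)), big.mark = ",")))
})

setMethod("show", "TranscriptModels", function(object) {
  cat(sprintf("TranscriptModels: %d transcript(s), %d gene(s)%s\n",
              length(object@transcripts), length(geneIds(object)),
              if (length(object@cds)) ", with CDS blocks" else ""))
})

setMethod("show", "EvidenceSet", function(object) {
  cat(sprintf(
    "EvidenceSet for %s: gDNA %d, WGS %d, EST-WGS %d, EST-gDNA %d (EST %s)\n",
    object@reporterId, nrow(object@reporterGdna), nrow(object@reporterWgs),
    nrow(object@estWgs), nrow(object@estGdna),
    if (object@estVerified) "verified" else "absent/unverified"))
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf("FixtureSpec: %d x %s bp, %s reporters (+%d intron-spanning), seed %d\n",
              object@nChromosomes,
              format(object@chromLength, big.mark = ","),
              sum(object@nPerGroup), object@nIntronSpanning, object@seed))
})
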