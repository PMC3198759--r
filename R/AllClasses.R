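#' @include probeRemap-package.R
NULL

ANNOTATION_GROUPS <- c("sense_gene_model", "antisense_gene_model", "gdna",
                       "est", "ambiguous", "inconclusive")

#' Pipeline thresholds and conventions
#'
#' Holds every tunable cut-off of the annotation pipeline.  The defaults are
#' the published strategy for 60-mer array reporters: exact word seeds of 23
#' (a hybridization-stringency cut-off: matches of >= 23 contiguous bases
#' give signal under stringent conditions), retention of multiple hits only
#' at identity >= 55/60, EST hit retention at E <= 1e-10 (top) and
#' E <= 1e-20 (multiple), a spliced-alignment normalised score of at least
#' 3, and an expression call at signal-to-noise ratio strictly greater
#' than 3.  Identity thresholds are interpreted as fractions of the
#' expected reporter length so that non-60-mer queries scale (identity/len
#' >= 55/60).
#'
#' @slot wordSize integer, exact-seed word size for all searches.
#' @slot minContiguous integer, minimum longest run of contiguous matches
#'   for a reporter hit to be retained.
#' @slot multiHitMinIdentity integer, identity (out of `reporterLength`)
#'   required of second and further reporter hits.
#' @slot reporterLength integer, expected reporter length; the denominator
#'   of the identity fractions.
#' @slot estTopEvalue numeric, E-value cut-off for the top EST-transcript hit.
#' @slot estMultiEvalue numeric, E-value cut-off for further EST hits.
#' @slot exonerateNormScoreMin numeric, minimum normalised score
#'   (raw score / query length) for EST-to-genome spliced matches.
#' @slot snrThreshold numeric, signal-to-noise ratio above which (strictly)
#'   a reporter counts as expressed on an array.
#' @slot minIntron,maxIntron integer, allowed genomic gap between chained
#'   blocks of a spliced alignment.
#' @slot randomSeed integer, seed recorded with a run (the pipeline itself
#'   is deterministic; the seed feeds fixture generation only).
#' @export
setClass("PipelineConfig", representation(
  wordSize = "integer",
  minContiguous = "integer",
  multiHitMinIdentity = "integer",
  reporterLength = "integer",
  estTopEvalue = "numeric",
  estMultiEvalue = "numeric",
  exonerateNormScoreMin = "numeric",
  snrThreshold = "numeric",
  minIntron = "integer",
  maxIntron = "integer",
  randomSeed = "integer"
))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@minContiguous > object@reporterLength)
    msg <- c(msg, "minContiguous must not exceed reporterLength")
  if (object@multiHitMinIdentity > object@reporterLength)
    msg <- c(msg, "multiHitMinIdentity must not exceed reporterLength")
  if (object@estMultiEvalue > object@estTopEvalue)
    msg <- c(msg, "estMultiEvalue must be <= estTopEvalue")
  if (object@wordSize < 1L) msg <- c(msg, "wordSize must be >= 1")
  if (object@minIntron < 1L) msg <- c(msg, "minIntron must be >= 1")
  if (object@maxIntron < 0L) msg <- c(msg, "maxIntron must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param wordSize,minContiguous,multiHitMinIdentity,reporterLength
#'   integer thresholds, see slots.
#' @param estTopEvalue,estMultiEvalue,exonerateNormScoreMin,snrThreshold
#'   numeric thresholds, see slots.
#' @param minIntron,maxIntron integer intron-size bracket for spliced
#'   chaining (defaults bracket typical plant introns).
#' @param randomSeed integer seed recorded with a run.
#' @return A `PipelineConfig` object.
#' @examples
#' cfg <- pipelineConfig()
#' wordSize(cfg)
#' @rdname PipelineConfig-class
#' @export
pipelineConfig <- function(wordSize = 23L, minContiguous = 23L,
                           multiHitMinIdentity = 55L, reporterLength = 60L,
                           estTopEvalue = 1e-10, estMultiEvalue = 1e-20,
                           exonerateNormScoreMin = 3, snrThreshold = 3,
                           minIntron = 20L, maxIntron = 50000L,
                           randomSeed = 1L) {
  new("PipelineConfig",
      wordSize = as.integer(wordSize),
      minContiguous = as.integer(minContiguous),
      multiHitMinIdentity = as.integer(multiHitMinIdentity),
      reporterLength = as.integer(reporterLength),
      estTopEvalue = as.numeric(estTopEvalue),
      estMultiEvalue = as.numeric(estMultiEvalue),
      exonerateNormScoreMin = as.numeric(exonerateNormScoreMin),
      snrThreshold = as.numeric(snrThreshold),
      minIntron = as.integer(minIntron),
      maxIntron = as.integer(maxIntron),
      randomSeed = as.integer(randomSeed))
}

#' Alignment scoring scheme
#'
#' Match/mismatch scores plus the Karlin-Altschul parameters used to attach
#' E-values (`E = K * m * n * exp(-lambda * S)`).  [blastScheme()] gives the
#' ungapped nucleotide defaults of classic BLASTN (+1/-3, lambda = 1.374,
#' K = 0.711) used for reporter and EST searches; [exonerateScheme()] gives
#' the est2genome-style +5/-4 scoring used for spliced EST-to-genome
#' alignment, under which the normalised-score filter (raw score / query
#' length >= 3) is meaningful.
#'
#' @slot match positive match score.
#' @slot mismatch negative mismatch score.
#' @slot karlinLambda,karlinK positive Karlin-Altschul parameters.
#' @export
setClass("ScoringScheme", representation(
  match = "numeric", mismatch = "numeric",
  karlinLambda = "numeric", karlinK = "numeric"
))

setValidity("ScoringScheme", function(object) {
  msg <- character()
  if (!(object@match > 0)) msg <- c(msg, "match score must be positive")
  if (!(object@mismatch < 0)) msg <- c(msg, "mismatch score must be negative")
  if (!(object@karlinLambda > 0) || !(object@karlinK > 0))
    msg <- c(msg, "Karlin parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' @param match,mismatch,karlinLambda,karlinK see slots.
#' @return A `ScoringScheme` object.
#' @rdname ScoringScheme-class
#' @export
scoringScheme <- function(match = 1, mismatch = -3,
                          karlinLambda = 1.374, karlinK = 0.711) {
  new("ScoringScheme", match = as.numeric(match),
      mismatch = as.numeric(mismatch),
      karlinLambda = as.numeric(karlinLambda),
      karlinK = as.numeric(karlinK))
}

#' @rdname ScoringScheme-class
#' @export
blastScheme <- function() scoringScheme(1, -3, 1.374, 0.711)

#' @rdname ScoringScheme-class
#' @export
exonerateScheme <- function() scoringScheme(5, -4, 0.275, 0.711)

#' Exact k-mer seed index over a target sequence set
#'
#' Wraps the target sequences and the seed word size; every exact k-mer
#' occurrence on the forward strand of every target is a posting (windows
#' containing N are skipped).  Minus-strand hits are found by searching the
#' reverse-complemented query against this forward index.
#'
#' @slot k integer word size.
#' @slot targets named character vector of uppercase target sequences.
#' @export
setClass("SeedIndex", representation(k = "integer", targets = "character"))

setValidity("SeedIndex", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (is.null(names(object@targets)) || anyDuplicated(names(object@targets)))
    return("targets must be uniquely named")
  TRUE
})

#' Transcript gene models with genomic coordinates
#'
#' The genomic spans of predicted transcripts (1-based, inclusive,
#' strand-aware) plus optional exon and CDS block structure, as read from
#' GFF3 or a flat TSV.  Every transcript belongs to exactly one gene.
#'
#' @slot transcripts `GRanges`, one range per transcript, with metadata
#'   columns `transcript_id` and `gene_id`.
#' @slot exons `GRangesList` of exon blocks keyed by transcript_id (may be
#'   empty for transcripts supplied without block structure).
#' @slot cds `GRangesList` of CDS blocks keyed by transcript_id.
#' @export
setClass("TranscriptModels", representation(
  transcripts = "GRanges", exons = "GRangesList", cds = "GRangesList"
))

setValidity("TranscriptModels", function(object) {
  tx <- object@transcripts
  mc <- S4Vectors::mcols(tx)
  msg <- character()
  if (!all(c("transcript_id", "gene_id") %in% colnames(mc)))
    return("transcripts need transcript_id and gene_id metadata columns")
  if (anyDuplicated(mc$transcript_id))
    msg <- c(msg, "transcript_id values must be unique")
  if (!all(as.character(GenomicRanges::strand(tx)) %in% c("+", "-")))
    msg <- c(msg, "transcript strand must be + or -")
  for (nm in intersect(names(object@exons), mc$transcript_id)) {
    ex <- object@exons[[nm]]
    span <- tx[match(nm, mc$transcript_id)]
    if (length(ex) &&
        (min(GenomicRanges::start(ex)) < GenomicRanges::start(span) ||
         max(GenomicRanges::end(ex)) > GenomicRanges::end(span)))
      msg <- c(msg, sprintf("exon blocks of %s outside transcript span", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Filtered evidence for one reporter
#'
#' The four retained hit collections the classifier consumes: reporter vs
#' genome (`reporterGdna`, possibly a spliced multi-block hit), reporter vs
#' predicted transcripts (`reporterWgs`), the reporter's source EST vs
#' transcripts (`estWgs`) and the EST spliced against the genome
#' (`estGdna`), plus the flag that the reporter was confirmed against its
#' own EST (without which EST evidence is not used).  `reporterEst` keeps
#' the reporter-to-own-EST alignment so that EST-based genomic placement of
#' the reporter can be mapped through the EST's spliced blocks.
#'
#' @slot reporterId character scalar.
#' @slot reporterGdna,reporterWgs,estWgs,estGdna,reporterEst hit
#'   data.frames (see [emptyHits()] for the column contract).
#' @slot estVerified logical scalar.
#' @export
setClass("EvidenceSet", representation(
  reporterId = "character",
  reporterGdna = "data.frame", reporterWgs = "data.frame",
  estWgs = "data.frame", estGdna = "data.frame",
  reporterEst = "data.frame",
  estVerified = "logical"
))

setValidity("EvidenceSet", function(object) {
  msg <- character()
  if (length(object@reporterId) != 1L) msg <- c(msg, "one reporterId required")
  if (!isTRUE(object@estVerified) && !isFALSE(object@estVerified))
    msg <- c(msg, "estVerified must be TRUE or FALSE")
  if (!object@estVerified &&
      (nrow(object@estWgs) > 0L || nrow(object@estGdna) > 0L))
    msg <- c(msg, "EST evidence present although estVerified is FALSE")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic planted-truth fixture
#'
#' Describes the synthetic genome, gene models, reporters and ESTs that
#' [generateFixture()] emits, with one planted annotation group per
#' reporter.  Defaults describe the study conditions used throughout the
#' package's validation: two 500 kb chromosomes, 50 reporters per group and
#' ten extra intron-spanning sense reporters.
#'
#' @slot nChromosomes,chromLength integer genome dimensions (bp).
#' @slot exonsPerGene,exonLength,intronLength integer ranges (min, max).
#' @slot nPerGroup named integer vector, reporters planted per group.
#' @slot nIntronSpanning integer, extra sense reporters split 30 bp + 30 bp
#'   across an intron.
#' @slot estDivergence numeric in (0, 0.3], substitution rate applied to
#'   the genomic footprint of EST-group reporters.
#' @slot estLength integer, length of emitted EST sequences.
#' @slot misorientedEstFraction numeric, fraction of sense-group ESTs
#'   emitted reverse-complemented (exercises wrongly oriented source ESTs).
#' @slot seed integer RNG seed; generation is byte-deterministic under it.
#' @export
setClass("FixtureSpec", representation(
  nChromosomes = "integer", chromLength = "integer",
  exonsPerGene = "integer", exonLength = "integer", intronLength = "integer",
  nPerGroup = "integer", nIntronSpanning = "integer",
  estDivergence = "numeric", estLength = "integer",
  misorientedEstFraction = "numeric", seed = "integer"
))

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (!all(ANNOTATION_GROUPS %in% names(object@nPerGroup)))
    msg <- c(msg, "nPerGroup must name all six annotation groups")
  if (any(object@nPerGroup < 0L)) msg <- c(msg, "nPerGroup must be >= 0")
  if (!(object@estDivergence > 0 && object@estDivergence <= 0.3))
    msg <- c(msg, "estDivergence must lie in (0, 0.3]")
  if (object@exonLength[1] < 64L)
    msg <- c(msg, "exons must be at least 64 bp to host a 60-mer reporter")
  if (object@nChromosomes < 1L || object@chromLength < 1000L)
    msg <- c(msg, "need at least one chromosome of >= 1 kb")
  if (length(msg)) msg else TRUE
})

#' @param nChromosomes,chromLength,exonsPerGene,exonLength,intronLength,
#'   nPerGroup,nIntronSpanning,estDivergence,estLength,
#'   misorientedEstFraction,seed see slots.
#' @return A `FixtureSpec` object.
#' @rdname FixtureSpec-class
#' @export
fixtureSpec <- function(nChromosomes = 2L, chromLength = 500000L,
                        exonsPerGene = c(2L, 4L), exonLength = c(150L, 300L),
                        intronLength = c(80L, 800L),
                        nPerGroup = c(sense_gene_model = 50L,
                                      antisense_gene_model = 50L,
                                      gdna = 50L, est = 50L,
                                      ambiguous = 50L, inconclusive = 50L),
                        nIntronSpanning = 10L, estDivergence = 0.15,
                        estLength = 600L, misorientedEstFraction = 0,
                        seed = 42L) {
  full <- setNames(integer(length(ANNOTATION_GROUPS)), ANNOTATION_GROUPS)
  full[names(nPerGroup)] <- as.integer(nPerGroup)
  new("FixtureSpec",
      nChromosomes = as.integer(nChromosomes),
      chromLength = as.integer(chromLength),
      exonsPerGene = as.integer(exonsPerGene),
      exonLength = as.integer(exonLength),
      intronLength = as.integer(intronLength),
      nPerGroup = full,
      nIntronSpanning = as.integer(nIntronSpanning),
      estDivergence = as.numeric(estDivergence),
      estLength = as.integer(estLength),
      misorientedEstFraction = as.numeric(misorientedEstFraction),
      seed = as.integer(seed))
}
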