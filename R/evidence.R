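#' @include oligoalign.R
NULL

# scaled multi-hit identity threshold: identity >= 55/60 of the actual
# query length
multiIdentityFloor <- function(qLen, cfg) {
  cfg@multiHitMinIdentity / cfg@reporterLength * qLen
}

#' Apply the reporter hit-retention rule
#'
#' Hits are ranked by descending raw score (identity out of the reporter
#' length — not the E-value — is the similarity measure for reporter
#' searches; ties break deterministically by target, position, then `+`
#' strand).  The top hit is retained iff its longest contiguous run reaches
#' `minContiguous`; when the top hit fails, the search result is empty and
#' lower-ranked hits are not promoted.  Every further hit additionally
#' needs identity at or above 55/60 of the query length.
#'
#' @param hits hit data.frame for one query and one target kind.
#' @param cfg a [PipelineConfig-class].
#' @return the retained hits, best first.
#' @export
filterReporterHits <- function(hits, cfg = pipelineConfig()) {
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$query_id)) > 1L)
    stop("filterReporterHits expects hits of a single query")
  hits <- orderHits(hits)
  if (hits$longest_contiguous[1] < cfg@minContiguous)
    return(hits[0, , drop = FALSE])
  keep <- c(TRUE, hits$longest_contiguous[-1] >= cfg@minContiguous &
              hits$identities[-1] >=
              multiIdentityFloor(hits$q_len[-1], cfg))
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confirm that a reporter matches its own source EST
#'
#' EST-derived evidence is only used after the reporter has been confirmed
#' against the EST it was designed from (best ungapped alignment on either
#' strand with at least `minContiguous` contiguous matches).
#'
#' @param reporterSeq reporter sequence (character scalar).
#' @param estSeq EST sequence (character scalar).
#' @param cfg a [PipelineConfig-class].
#' @return list with `verified` (logical) and `hits` (the reporter-to-EST
#'   alignments, used later to map the reporter through the EST's genomic
#'   blocks).
#' @export
verifyReporterEst <- function(reporterSeq, estSeq, cfg = pipelineConfig()) {
  idx <- buildSeedIndex(c(est = unname(estSeq)), cfg@wordSize)
  hits <- setKind(findUngappedHits(c(reporter = unname(reporterSeq)), idx),
                  "EST")
  list(verified = nrow(hits) > 0L &&
         max(hits$longest_contiguous) >= cfg@minContiguous,
       hits = hits)
}

#' Apply the EST hit-retention rule (E-value based)
#'
#' Hits sorted by ascending E-value; the top hit is retained iff
#' `E <= estTopEvalue` (1e-10), further hits iff `E <= estMultiEvalue`
#' (1e-20).  A failing top hit empties the result.
#'
#' @param hits hit data.frame with E-values, one query.
#' @param cfg a [PipelineConfig-class].
#' @return retained hits, best first.
#' @export
filterEstHits <- function(hits, cfg = pipelineConfig()) {
  if (nrow(hits) == 0L) return(hits)
  if (anyNA(hits$evalue)) stop("EST hits must carry E-values")
  hits <- hits[order(hits$evalue, hits$target_id, hits$t_start,
                     hits$strand != "+"), , drop = FALSE]
  if (hits$evalue[1] > cfg@estTopEvalue) return(hits[0, , drop = FALSE])
  keep <- c(TRUE, hits$evalue[-1] <= cfg@estMultiEvalue)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain EST-to-genome spliced matches by normalised score
#'
#' A spliced match is recorded only when its raw score divided by the EST
#' length is at least `exonerateNormScoreMin` (default 3).
#'
#' @param hits spliced hit data.frame.
#' @param estLen EST length(s); defaults to the hits' `q_len`.
#' @param cfg a [PipelineConfig-class].
#' @return retained hits.
#' @export
filterEstGdna <- function(hits, estLen = NULL, cfg = pipelineConfig()) {
  if (nrow(hits) == 0L) return(hits)
  ns <- normalisedScore(hits, estLen)
  out <- hits[ns >= cfg@exonerateNormScoreMin, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# replace the ungapped reporter-gDNA result with the spliced one when a
# positive multi-block spliced match passes the contiguity rule
mergeSplicedGdna <- function(ungapped, spliced, cfg) {
  if (nrow(spliced) == 0L) return(ungapped)
  multi <- spliced[spliced$n_blocks > 1L &
                     spliced$longest_contiguous >= cfg@minContiguous, ,
                   drop = FALSE]
  if (nrow(multi) == 0L) return(ungapped)
  filterReporterHits(spliced, cfg)
}

#' Assemble the filtered evidence for one reporter
#'
#' Runs the four searches (reporter vs genome, reporter vs transcripts, and
#' — once the reporter is confirmed against its own EST — EST vs
#' transcripts and EST spliced vs genome), applies the retention rules, and
#' substitutes the spliced reporter-genome result when the reporter spans
#' an intron.  Reporters without an EST (or failing EST confirmation) carry
#' empty EST evidence.
#'
#' @param reporter one-row data.frame with `reporter_id`, `sequence`,
#'   `est_accession` (see [readReporterManifest()]).
#' @param genomeIndex,transcriptIndex [SeedIndex-class] objects over the
#'   genome and the predicted transcripts.
#' @param ests named character vector of EST sequences (may be empty).
#' @param cfg a [PipelineConfig-class].
#' @return an [EvidenceSet-class].
#' @export
buildEvidence <- function(reporter, genomeIndex, transcriptIndex,
                          ests = character(), cfg = pipelineConfig()) {
  stopifnot(nrow(reporter) == 1L)
  rid <- reporter$reporter_id
  qry <- setNames(reporter$sequence, rid)

  gHits <- filterReporterHits(findUngappedHits(qry, genomeIndex), cfg)
  spl <- splicedAlign(qry, genomeIndex, exonerateScheme(),
                      maxIntron = cfg@maxIntron, minIntron = cfg@minIntron)
  gHits <- mergeSplicedGdna(gHits, spl, cfg)

  wHits <- setKind(findUngappedHits(qry, transcriptIndex), "transcript")
  wHits <- filterReporterHits(wHits, cfg)

  estAcc <- reporter$est_accession
  verified <- FALSE
  repEst <- emptyHits("EST")
  estWgs <- emptyHits("transcript")
  estGdna <- emptyHits("gDNA")
  if (!is.na(estAcc) && estAcc %in% names(ests)) {
    vr <- verifyReporterEst(reporter$sequence, ests[[estAcc]], cfg)
    verified <- vr$verified
    repEst <- vr$hits
    repEst$query_id <- rep(rid, nrow(repEst))
    repEst$target_id <- rep(estAcc, nrow(repEst))
    if (verified) {
      estSeq <- setNames(ests[estAcc], estAcc)
      estWgs <- filterEstHits(
        alignEst(estSeq, transcriptIndex, blastScheme()), cfg)
      estGdna <- filterEstGdna(
        splicedAlign(estSeq, genomeIndex, exonerateScheme(),
                     maxIntron = cfg@maxIntron, minIntron = cfg@minIntron),
        cfg = cfg)
    }
  }
  new("EvidenceSet", reporterId = rid,
      reporterGdna = gHits, reporterWgs = wHits,
      estWgs = estWgs, estGdna = estGdna,
      reporterEst = repEst, estVerified = verified)
}
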