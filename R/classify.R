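#' @include agreement.R
NULL

emptyResults <- function() {
  data.frame(reporter_id = character(), group = character(),
             gene_ids = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             orientation = character(), intron_spanning = logical(),
             region = character(), rationale_code = character(),
             stringsAsFactors = FALSE)
}

resultRow <- function(reporterId, group, rationale, geneIds = character(),
                      chrom = NA_character_, start = NA_integer_,
                      end = NA_integer_, strand = NA_character_,
                      orientation = NA_character_,
                      intronSpanning = NA, region = NA_character_) {
  data.frame(reporter_id = reporterId, group = group,
             gene_ids = if (length(geneIds)) paste(sort(unique(geneIds)),
                                                   collapse = ",")
                        else NA_character_,
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, orientation = orientation,
             intron_spanning = intronSpanning, region = region,
             rationale_code = rationale, stringsAsFactors = FALSE)
}

bestAgreement <- function(agr) {
  agr[order(-agr$score, agr$gene_id, agr$transcript_id), ,
      drop = FALSE][1, , drop = FALSE]
}

#' Assign one reporter to one of the six annotation groups
#'
#' Decision order: (a) agreements to more than one distinct gene model
#' (reporter- and EST-level combined) are ambiguous; (b) exactly one
#' reporter-level agreement assigns the sense or antisense gene-model group
#' by its orientation; (c) with no reporter-level agreement, no retained
#' reporter-transcript hit and exactly one EST-level agreement, the
#' reporter is annotated by EST (when the reporter also has a genomic
#' placement, the EST-derived placement must corroborate it, otherwise the
#' conflict is inconclusive); (d) with no agreements at all, a unique
#' genomic hit and no transcript hit is the gDNA group (a location not
#' annotated as a gene model); (e) everything else — multiple transcripts
#' without genomic agreement, multiple genomic locations without
#' transcripts, or no valid hits — is inconclusive.  A rationale code
#' records which branch fired.
#'
#' @param ev an [EvidenceSet-class].
#' @param repAgr,estAgr agreement data.frames from [reporterAgreements()]
#'   and [estAgreements()].
#' @param cfg a [PipelineConfig-class].
#' @return one-row annotation result data.frame.
#' @export
classifyReporter <- function(ev, repAgr, estAgr, cfg = pipelineConfig()) {
  rid <- ev@reporterId
  genesAll <- union(repAgr$gene_id, estAgr$gene_id)

  if (length(genesAll) > 1L) {
    both <- rbind(repAgr, estAgr)
    b <- bestAgreement(both)
    return(resultRow(rid, "ambiguous", "multiple_gene_model_agreements",
                     geneIds = genesAll, chrom = b$chrom, start = b$g_start,
                     end = b$g_end, strand = b$g_strand,
                     intronSpanning = any(both$intron_spanning)))
  }
  if (nrow(repAgr) == 1L) {
    grp <- if (repAgr$orientation == "sense") "sense_gene_model"
           else "antisense_gene_model"
    code <- paste0("single_", repAgr$orientation, "_agreement")
    return(resultRow(rid, grp, code, geneIds = repAgr$gene_id,
                     chrom = repAgr$chrom, start = repAgr$g_start,
                     end = repAgr$g_end, strand = repAgr$g_strand,
                     orientation = repAgr$orientation,
                     intronSpanning = repAgr$intron_spanning,
                     region = repAgr$region))
  }
  nGdna <- nrow(ev@reporterGdna)
  nWgs <- nrow(ev@reporterWgs)
  if (nrow(estAgr) == 1L && nWgs == 0L) {
    corroborated <- nGdna == 0L ||
      any(ev@reporterGdna$target_id == estAgr$chrom &
            ev@reporterGdna$t_start <= estAgr$g_end &
            ev@reporterGdna$t_end >= estAgr$g_start)
    if (corroborated) {
      return(resultRow(rid, "est", "single_est_agreement",
                       geneIds = estAgr$gene_id, chrom = estAgr$chrom,
                       start = estAgr$g_start, end = estAgr$g_end,
                       strand = estAgr$g_strand,
                       orientation = estAgr$orientation,
                       intronSpanning = FALSE, region = estAgr$region))
    }
    return(resultRow(rid, "inconclusive", "conflicting_est_and_gdna"))
  }
  if (nrow(estAgr) == 0L && nGdna == 1L && nWgs == 0L) {
    h <- ev@reporterGdna
    return(resultRow(rid, "gdna", "unique_genomic_location",
                     chrom = h$target_id, start = h$t_start, end = h$t_end,
                     strand = h$strand,
                     intronSpanning = h$n_blocks > 1L))
  }
  code <- if (nGdna == 0L && nWgs == 0L && nrow(ev@estWgs) == 0L &&
                nrow(ev@estGdna) == 0L) "no_valid_hits"
          else if (nWgs > 0L) "transcript_without_genomic_agreement"
          else if (nGdna > 1L) "multiple_genomic_locations"
          else "unresolved_evidence"
  resultRow(rid, "inconclusive", code)
}

# ---- batched evidence -----------------------------------------------------

splitByQuery <- function(hits, ids) {
  out <- split(hits, factor(hits$query_id, levels = ids))
  lapply(out, function(df) { rownames(df) <- NULL; df })
}

# batched version of buildEvidence: a handful of index searches for the
# whole manifest instead of per-reporter calls
buildEvidenceAll <- function(manifest, genomeIndex, transcriptIndex,
                             ests = character(), cfg = pipelineConfig(),
                             verbose = FALSE) {
  ids <- manifest$reporter_id
  qall <- setNames(manifest$sequence, ids)
  say <- function(...) if (verbose) message(...)

  rg <- findUngappedHits(qall, genomeIndex)
  say("reporter-gDNA candidate hits: ", nrow(rg))
  spl <- splicedAlign(qall, genomeIndex, exonerateScheme(),
                      maxIntron = cfg@maxIntron, minIntron = cfg@minIntron)
  rw <- setKind(findUngappedHits(qall, transcriptIndex), "transcript")
  say("reporter-WGS candidate hits: ", nrow(rw))

  withEst <- !is.na(manifest$est_accession) &
    manifest$est_accession %in% names(ests)
  ve <- emptyHits("EST")
  if (any(withEst)) {
    estIdx <- buildSeedIndex(ests, cfg@wordSize)
    ve <- setKind(findUngappedHits(qall[ids[withEst]], estIdx), "EST")
  }
  veByRep <- splitByQuery(ve, ids)

  verified <- setNames(logical(length(ids)), ids)
  for (i in which(withEst)) {
    acc <- manifest$est_accession[i]
    own <- veByRep[[ids[i]]]
    own <- own[own$target_id == acc, , drop = FALSE]
    veByRep[[ids[i]]] <- own
    verified[ids[i]] <- nrow(own) > 0L &&
      max(own$longest_contiguous) >= cfg@minContiguous
  }
  say("reporters with verified ESTs: ", sum(verified))

  accUsed <- unique(manifest$est_accession[withEst & verified[ids]])
  ew <- emptyHits("transcript"); eg <- emptyHits("gDNA")
  if (length(accUsed)) {
    estSeqs <- ests[accUsed]
    ew <- alignEst(estSeqs, transcriptIndex, blastScheme())
    eg <- splicedAlign(estSeqs, genomeIndex, exonerateScheme(),
                       maxIntron = cfg@maxIntron, minIntron = cfg@minIntron)
  }
  ewByAcc <- splitByQuery(ew, accUsed)
  egByAcc <- splitByQuery(eg, accUsed)

  rgByRep <- splitByQuery(rg, ids)
  splByRep <- splitByQuery(spl, ids)
  rwByRep <- splitByQuery(rw, ids)

  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    rid <- ids[i]
    gHits <- filterReporterHits(rgByRep[[rid]], cfg)
    gHits <- mergeSplicedGdna(gHits, splByRep[[rid]], cfg)
    wHits <- filterReporterHits(rwByRep[[rid]], cfg)
    isVer <- unname(verified[rid])
    acc <- manifest$est_accession[i]
    estWgs <- emptyHits("transcript"); estGdna <- emptyHits("gDNA")
    if (isVer) {
      estWgs <- filterEstHits(ewByAcc[[acc]], cfg)
      estGdna <- filterEstGdna(egByAcc[[acc]], cfg = cfg)
    }
    repEst <- if (withEst[i]) veByRep[[rid]] else emptyHits("EST")
    out[[i]] <- new("EvidenceSet", reporterId = rid,
                    reporterGdna = gHits, reporterWgs = wHits,
                    estWgs = estWgs, estGdna = estGdna,
                    reporterEst = repEst, estVerified = isVer)
  }
  out
}

#' Classify every reporter of a manifest
#'
#' Runs the complete in-memory pipeline: builds seed indexes over genome
#' and transcripts, assembles the filtered evidence for every reporter
#' (batched searches), reconciles genome- and transcript-level hits into
#' agreement records, and assigns one of the six annotation groups per
#' reporter.  The pipeline is deterministic: identical inputs give
#' identical results.
#'
#' @param manifest reporter manifest data.frame
#'   (see [readReporterManifest()]).
#' @param genome named character vector / `DNAStringSet` of chromosomes.
#' @param transcripts named character vector / `DNAStringSet` of predicted
#'   transcript sequences (names = transcript IDs).
#' @param models a [TranscriptModels-class] giving transcript genomic
#'   spans.
#' @param ests named character vector / `DNAStringSet` of EST sequences.
#' @param cfg a [PipelineConfig-class].
#' @param verbose emit per-stage counts on stderr.
#' @return annotation result data.frame, one row per manifest reporter, in
#'   manifest order, with attribute `"evidence"` holding the per-reporter
#'   [EvidenceSet-class] list.
#' @export
classifyAll <- function(manifest, genome, transcripts, models,
                        ests = character(), cfg = pipelineConfig(),
                        verbose = FALSE) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  if (methods::is(transcripts, "DNAStringSet"))
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  if (methods::is(ests, "DNAStringSet"))
    ests <- setNames(as.character(ests), names(ests))
  gIdx <- buildSeedIndex(genome, cfg@wordSize)
  tIdx <- buildSeedIndex(transcripts, cfg@wordSize)
  evAll <- buildEvidenceAll(manifest, gIdx, tIdx, ests, cfg,
                            verbose = verbose)
  lk <- modelLookup(models)
  rows <- vector("list", length(evAll))
  for (i in seq_along(evAll)) {
    ev <- evAll[[i]]
    repAgr <- reporterAgreements(ev, models, lookup = lk)
    estAgr <- estAgreements(ev, models, lookup = lk)
    rows[[i]] <- classifyReporter(ev, repAgr, estAgr, cfg)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (verbose) {
    tab <- table(factor(res$group, levels = ANNOTATION_GROUPS))
    message("group counts: ",
            paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  attr(res, "evidence") <- evAll
  res
}

# ---- summaries ------------------------------------------------------------

#' Tabulate annotation-group counts and proportions
#'
#' @param results annotation result data.frame.
#' @return data.frame with one row per group plus a `total` row; counts sum
#'   to the input size and proportions (percent, one decimal) to 100 within
#'   rounding.
#' @export
summarizeGroups <- function(results) {
  counts <- table(factor(results$group, levels = ANNOTATION_GROUPS))
  n <- nrow(results)
  prop <- if (n > 0L) round(100 * as.integer(counts) / n, 1) else
    rep(0, length(counts))
  data.frame(group = c(ANNOTATION_GROUPS, "total"),
             count = c(as.integer(counts), n),
             proportion = c(prop, if (n > 0L) 100 else 0),
             stringsAsFactors = FALSE)
}

#' Mean number of reporters per linked gene model
#'
#' Counts reporter-to-gene links over the sense, antisense and ambiguous
#' groups (each gene counted once) and divides by the number of distinct
#' genes linked.
#'
#' @param results annotation result data.frame.
#' @return numeric ratio; `NA` (with a message) when no gene is linked.
#' @export
reportersPerGene <- function(results) {
  linked <- results[results$group %in%
                      c("sense_gene_model", "antisense_gene_model",
                        "ambiguous") & !is.na(results$gene_ids), ,
                    drop = FALSE]
  genes <- strsplit(linked$gene_ids, ",", fixed = TRUE)
  nLinks <- sum(lengths(genes))
  nGenes <- length(unique(unlist(genes)))
  if (nGenes == 0L) {
    message("no reporter-gene links; reporters-per-gene not applicable")
    return(NA_real_)
  }
  nLinks / nGenes
}

#' Flag reporters with measurable signal
#'
#' A reporter is expressed when its signal-to-noise ratio strictly exceeds
#' the threshold (default 3) on at least one array; an SNR of exactly 3
#' does not count.
#'
#' @param expr `SummarizedExperiment` with `signal` and `noise` assays.
#' @param cfg a [PipelineConfig-class].
#' @return named logical vector over reporters.
#' @export
flagExpressed <- function(expr, cfg = pipelineConfig()) {
  sig <- SummarizedExperiment::assay(expr, "signal")
  noi <- SummarizedExperiment::assay(expr, "noise")
  stopifnot(all(dim(sig) == dim(noi)))
  if (any(noi <= 0)) stop("noise values must be strictly positive")
  snr <- sig / noi
  setNames(apply(snr, 1, max) > cfg@snrThreshold, rownames(sig))
}

#' Expressed-reporter counts per annotation group
#'
#' @param flags named logical vector from [flagExpressed()]; must cover
#'   every reporter in `results`.
#' @param results annotation result data.frame.
#' @return data.frame of per-group expressed counts and percentages.
#' @export
expressionByGroup <- function(flags, results) {
  missing <- setdiff(results$reporter_id, names(flags))
  if (length(missing))
    stop("expression flags missing for ", length(missing), " reporter(s)")
  f <- flags[results$reporter_id]
  groups <- factor(results$group, levels = ANNOTATION_GROUPS)
  n <- as.integer(table(groups))
  nExpr <- as.integer(tapply(f, groups, sum, default = 0L))
  prop <- ifelse(n > 0L, round(100 * nExpr / n, 1), 0)
  data.frame(group = c(ANNOTATION_GROUPS, "total"),
             count = c(n, sum(n)),
             n_expressed = c(nExpr, sum(nExpr)),
             proportion_expressed = c(prop, if (sum(n) > 0L)
               round(100 * sum(nExpr) / sum(n), 1) else 0),
             stringsAsFactors = FALSE)
}
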