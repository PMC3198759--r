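#' @include evidence.R
NULL

#' Orientation of a genomic hit relative to a gene model
#'
#' A reporter placed on the genome reads sense when its strand equals the
#' transcribed strand of the gene model, antisense otherwise; the relation
#' is invariant under flipping both strands together.
#'
#' @param hitStrand `"+"` or `"-"`, strand of the query on the genome.
#' @param transcriptStrand `"+"` or `"-"`, transcribed strand of the model.
#' @return `"sense"` or `"antisense"` (vectorised).
#' @examples
#' orientationOf("+", "-")
#' @export
orientationOf <- function(hitStrand, transcriptStrand) {
  stopifnot(all(hitStrand %in% c("+", "-")),
            all(transcriptStrand %in% c("+", "-")))
  ifelse(hitStrand == transcriptStrand, "sense", "antisense")
}

emptyAgreements <- function() {
  data.frame(reporter_id = character(), gene_id = character(),
             transcript_id = character(), source = character(),
             orientation = character(), chrom = character(),
             g_start = integer(), g_end = integer(), g_strand = character(),
             region = character(), intron_spanning = logical(),
             score = numeric(), stringsAsFactors = FALSE)
}

# plain-coordinate view of a TranscriptModels object; computed once per
# pipeline run (the S4 containers are authoritative, this is the hot-path
# cache)
modelLookup <- function(models) {
  tx <- transcriptRanges(models)
  mc <- S4Vectors::mcols(tx)
  blocksOf <- function(grl) {
    if (length(grl) == 0L) return(list())
    df <- as.data.frame(grl)
    idx <- split(seq_len(nrow(df)), df$group_name)
    lapply(idx, function(i) cbind(df$start[i], df$end[i]))
  }
  list(ids = as.character(mc$transcript_id),
       gene = as.character(mc$gene_id),
       chrom = as.character(GenomicRanges::seqnames(tx)),
       start = GenomicRanges::start(tx), end = GenomicRanges::end(tx),
       strand = as.character(GenomicRanges::strand(tx)),
       exons = blocksOf(exonBlocks(models)),
       cds = blocksOf(cdsBlocks(models)))
}

# UTR/CDS/mixed/unknown call for one genomic interval on one transcript
regionOf <- function(lk, transcriptId, gStart, gEnd) {
  cdsM <- lk$cds[[transcriptId]]
  if (is.null(cdsM)) return("unknown")
  ov <- function(m) sum(pmax(0L, pmin(gEnd, m[, 2]) - pmax(gStart, m[, 1]) + 1L))
  wCds <- ov(cdsM)
  exM <- lk$exons[[transcriptId]]
  if (is.null(exM)) {
    ti <- match(transcriptId, lk$ids)
    exM <- matrix(c(lk$start[ti], lk$end[ti]), ncol = 2L)
  }
  wEx <- ov(exM)
  w <- gEnd - gStart + 1L
  if (wCds == w) "CDS"
  else if (wCds == 0L && wEx > 0L) "UTR"
  else if (wCds > 0L) "mixed"
  else "unknown"
}

# collapse agreements of one reporter+source to one record per gene,
# keeping the best-scoring transcript (deterministic tie-break)
collapsePerGene <- function(agr) {
  if (nrow(agr) <= 1L) return(agr)
  agr <- agr[order(agr$gene_id, -agr$score, agr$transcript_id), ,
             drop = FALSE]
  out <- agr[!duplicated(agr$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconcile reporter genome hits with reporter transcript hits
#'
#' For every (genome hit, transcript hit) pair of one reporter, an
#' agreement record is emitted when the genomic hit overlaps (by at least
#' one base) the genomic span of the matched transcript on the same
#' chromosome — the test that the transcript the reporter matched derives
#' from the same genomic position the reporter matched.  Orientation is
#' sense when the genomic hit strand equals the transcript strand.
#' Records for distinct transcripts of one gene collapse to the
#' best-scoring transcript, since groups are counted over gene models.
#'
#' @param ev an [EvidenceSet-class].
#' @param models a [TranscriptModels-class].
#' @param lookup optional precomputed coordinate cache (internal; built
#'   once per run by [classifyAll()]).
#' @return agreement data.frame (zero rows when no pair agrees).
#' @export
reporterAgreements <- function(ev, models, lookup = NULL) {
  g <- ev@reporterGdna; w <- ev@reporterWgs
  if (nrow(g) == 0L || nrow(w) == 0L) return(emptyAgreements())
  lk <- if (is.null(lookup)) modelLookup(models) else lookup
  unknown <- setdiff(w$target_id, lk$ids)
  if (length(unknown))
    stop("transcript hit to unknown transcript_id: ",
         paste(unknown, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(nrow(w))) {
      ti <- match(w$target_id[j], lk$ids)
      if (lk$chrom[ti] != g$target_id[i]) next
      if (g$t_end[i] < lk$start[ti] || g$t_start[i] > lk$end[ti]) next
      rows[[length(rows) + 1L]] <- data.frame(
        reporter_id = ev@reporterId,
        gene_id = lk$gene[ti], transcript_id = w$target_id[j],
        source = "reporter",
        orientation = orientationOf(g$strand[i], lk$strand[ti]),
        chrom = g$target_id[i], g_start = g$t_start[i], g_end = g$t_end[i],
        g_strand = g$strand[i],
        region = regionOf(lk, w$target_id[j], g$t_start[i], g$t_end[i]),
        intron_spanning = g$n_blocks[i] > 1L,
        score = w$raw_score[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(emptyAgreements())
  collapsePerGene(do.call(rbind, rows))
}

# map an interval on the EST through the EST's spliced genomic blocks;
# returns NULL when the interval is not contained in a single block
mapThroughBlocks <- function(blocks, strand, a, b) {
  for (j in seq_len(nrow(blocks))) {
    qs <- blocks[j, "q_start"]; qe <- blocks[j, "q_end"]
    if (a >= qs && b <= qe) {
      if (strand == "+") {
        return(unname(c(blocks[j, "t_start"] + (a - qs),
                        blocks[j, "t_start"] + (b - qs))))
      } else {
        return(unname(c(blocks[j, "t_end"] - (b - qs),
                        blocks[j, "t_end"] - (a - qs))))
      }
    }
  }
  NULL
}

#' Reconcile EST genome placements with EST transcript hits
#'
#' The EST-level analogue of [reporterAgreements()]: the EST's spliced
#' genomic placement must overlap the genomic span of the transcript the
#' EST matched.  The reporter's own genomic position is approximated by
#' mapping its position within the EST through the EST's spliced blocks;
#' when the reporter interval does not fall inside a single block the
#' record carries the EST's matched span with region `unknown`.
#'
#' @param ev an [EvidenceSet-class] with `estVerified = TRUE` (otherwise an
#'   empty record set is returned).
#' @param models a [TranscriptModels-class].
#' @param lookup optional precomputed coordinate cache (internal; built
#'   once per run by [classifyAll()]).
#' @return agreement data.frame with `source = "est"`.
#' @export
estAgreements <- function(ev, models, lookup = NULL) {
  if (!ev@estVerified) return(emptyAgreements())
  e <- ev@estGdna; w <- ev@estWgs
  if (nrow(e) == 0L || nrow(w) == 0L) return(emptyAgreements())
  lk <- if (is.null(lookup)) modelLookup(models) else lookup
  unknown <- setdiff(w$target_id, lk$ids)
  if (length(unknown))
    stop("transcript hit to unknown transcript_id: ",
         paste(unknown, collapse = ", "))

  # reporter's footprint on the EST, from the verification alignment
  repHit <- if (nrow(ev@reporterEst)) ev@reporterEst[1, ] else NULL

  rows <- list()
  for (i in seq_len(nrow(e))) {
    for (j in seq_len(nrow(w))) {
      ti <- match(w$target_id[j], lk$ids)
      if (lk$chrom[ti] != e$target_id[i]) next
      if (e$t_end[i] < lk$start[ti] || e$t_start[i] > lk$end[ti]) next
      txStrand <- lk$strand[ti]
      gs <- e$t_start[i]; ge <- e$t_end[i]
      region <- "unknown"
      repStrandOnGdna <- e$strand[i]
      if (!is.null(repHit)) {
        mapped <- mapThroughBlocks(e$blocks[[i]], e$strand[i],
                                   repHit$t_start, repHit$t_end)
        if (!is.null(mapped)) {
          gs <- mapped[1]; ge <- mapped[2]
          region <- regionOf(lk, w$target_id[j], gs, ge)
        }
        # reporter strand on the genome composes reporter-in-EST with
        # EST-on-genome
        repStrandOnGdna <- if (repHit$strand == e$strand[i]) "+" else "-"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        reporter_id = ev@reporterId,
        gene_id = lk$gene[ti], transcript_id = w$target_id[j],
        source = "est",
        orientation = orientationOf(repStrandOnGdna, txStrand),
        chrom = e$target_id[i], g_start = gs, g_end = ge,
        g_strand = repStrandOnGdna,
        region = region,
        intron_spanning = FALSE,
        score = w$raw_score[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(emptyAgreements())
  collapsePerGene(do.call(rbind, rows))
}
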