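#' @include hits.R
NULL

GFF_SOURCE <- "probeRemap"

# ---- FASTA ----------------------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' IDs are the first whitespace-delimited token of each header; sequences
#' are uppercased.  Duplicate IDs are an error; an empty file yields an
#' empty mapping with a warning.
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase sequences.
#' @export
readFastaMap <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(), character()))
  }
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA ID(s): ", paste(unique(dup), collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param x named character vector of DNA sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFastaMap <- function(x, path) {
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# ---- reporter manifest ----------------------------------------------------

#' Read a reporter manifest TSV
#'
#' Expects header columns `reporter_id`, `sequence`, `est_accession` (empty
#' cell = no source EST).  Reporter IDs must be unique and sequences must
#' use the A/C/G/T/N alphabet.  A sequence length other than the expected
#' reporter length is a warning, not an error: the identity thresholds are
#' fractions of the actual length, so non-60-mer designs remain usable.
#'
#' @param path TSV path.
#' @param expectedLength integer, expected reporter length (default 60).
#' @return data.frame with columns `reporter_id`, `sequence`,
#'   `est_accession` (NA when absent).
#' @export
readReporterManifest <- function(path, expectedLength = 60L) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("reporter_id", "sequence", "est_accession")
  if (!all(need %in% colnames(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$sequence <- toupper(df$sequence)
  df$est_accession[!nzchar(trimws(ifelse(is.na(df$est_accession), "",
                                         df$est_accession)))] <- NA_character_
  if (any(!nzchar(df$sequence)))
    stop("empty sequence at row ", which(!nzchar(df$sequence))[1])
  bad <- grepl("[^ACGTN]", df$sequence)
  if (any(bad))
    stop("non-ACGTN character in sequence at row ", which(bad)[1],
         " (", df$reporter_id[which(bad)[1]], ")")
  dup <- df$reporter_id[duplicated(df$reporter_id)]
  if (length(dup))
    stop("duplicate reporter_id(s): ", paste(unique(dup), collapse = ", "))
  off <- nchar(df$sequence) != expectedLength
  if (any(off))
    warning(sum(off), " reporter(s) differ from the expected length of ",
            expectedLength, " nt")
  rownames(df) <- NULL
  df
}

# ---- transcript spans -----------------------------------------------------

#' Read transcript gene models from GFF3 or a flat TSV
#'
#' GFF3 input expects `mRNA` (or `transcript`) features with `ID` and a
#' `Parent` gene, plus optional `exon`/`CDS` children.  The TSV dialect has
#' header columns `gene_id`, `transcript_id`, `chrom`, `start`, `end`,
#' `strand` and optional `exons`/`cds` columns holding comma-separated
#' `start-end` blocks.  Coordinates are 1-based inclusive throughout.
#'
#' @param path input path.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return A [TranscriptModels-class] object.
#' @export
readTranscriptSpans <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") return(readSpansTsv(path))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  tx <- gr[type %in% c("mRNA", "transcript")]
  if (length(tx) == 0L) stop("no mRNA/transcript features in ", path)
  if (!all(as.character(GenomicRanges::strand(tx)) %in% c("+", "-")))
    stop("transcript strand must be + or -")
  parent1 <- function(x, what) {
    p <- as.list(x$Parent)
    empty <- lengths(p) == 0L
    if (any(empty)) stop(what, " without Parent in ", path)
    vapply(p, `[[`, character(1), 1L)
  }
  txdf <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(tx),
    ranges = IRanges::ranges(tx),
    strand = GenomicRanges::strand(tx))
  S4Vectors::mcols(txdf)$transcript_id <- as.character(tx$ID)
  S4Vectors::mcols(txdf)$gene_id <- parent1(tx, "mRNA")
  splitChildren <- function(what) {
    ch <- gr[type == what]
    if (length(ch) == 0L) return(GenomicRanges::GRangesList())
    par <- parent1(ch, what)
    unknown <- setdiff(par, S4Vectors::mcols(txdf)$transcript_id)
    if (length(unknown))
      stop(what, " with unknown parent transcript: ",
           paste(unknown, collapse = ", "))
    ch <- GenomicRanges::granges(ch)
    GenomicRanges::GRangesList(lapply(
      split(ch, factor(par, levels = unique(par))), sort))
  }
  new("TranscriptModels", transcripts = txdf,
      exons = splitChildren("exon"), cds = splitChildren("CDS"))
}

readSpansTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  if (!all(need %in% colnames(df)))
    stop("spans TSV must have columns: ", paste(need, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be + or -")
  tx <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end), df$strand)
  S4Vectors::mcols(tx)$transcript_id <- as.character(df$transcript_id)
  S4Vectors::mcols(tx)$gene_id <- as.character(df$gene_id)
  parseBlocks <- function(col) {
    if (!col %in% colnames(df)) return(GenomicRanges::GRangesList())
    keep <- !is.na(df[[col]]) & nzchar(df[[col]])
    if (!any(keep)) return(GenomicRanges::GRangesList())
    lst <- lapply(which(keep), function(i) {
      parts <- strsplit(strsplit(df[[col]][i], ",")[[1]], "-")
      GenomicRanges::GRanges(df$chrom[i], IRanges::IRanges(
        as.integer(vapply(parts, `[`, character(1), 1L)),
        as.integer(vapply(parts, `[`, character(1), 2L))), df$strand[i])
    })
    names(lst) <- df$transcript_id[keep]
    GenomicRanges::GRangesList(lst)
  }
  new("TranscriptModels", transcripts = tx,
      exons = parseBlocks("exons"), cds = parseBlocks("cds"))
}

gffAttr <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(x) is.na(x) || !nzchar(x), logical(1))]
  paste(paste0(names(kv), "=", unlist(kv)), collapse = ";")
}

#' Write transcript gene models as GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` features with `ID`/`Parent`
#' attributes; the writer is deliberately plain so that identical inputs
#' produce byte-identical files.
#'
#' @param models a [TranscriptModels-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTranscriptSpans <- function(models, path) {
  tx <- transcriptRanges(models)
  mc <- S4Vectors::mcols(tx)
  lines <- c("##gff-version 3")
  geneSeen <- character()
  for (i in order(as.character(GenomicRanges::seqnames(tx)),
                  GenomicRanges::start(tx))) {
    gid <- mc$gene_id[i]; tid <- mc$transcript_id[i]
    chrom <- as.character(GenomicRanges::seqnames(tx))[i]
    std <- as.character(GenomicRanges::strand(tx))[i]
    if (!gid %in% geneSeen) {
      lines <- c(lines, paste(chrom, GFF_SOURCE, "gene",
                              GenomicRanges::start(tx)[i],
                              GenomicRanges::end(tx)[i], ".", std, ".",
                              gffAttr(ID = gid), sep = "\t"))
      geneSeen <- c(geneSeen, gid)
    }
    lines <- c(lines, paste(chrom, GFF_SOURCE, "mRNA",
                            GenomicRanges::start(tx)[i],
                            GenomicRanges::end(tx)[i], ".", std, ".",
                            gffAttr(ID = tid, Parent = gid), sep = "\t"))
    for (what in c("exon", "CDS")) {
      blocks <- if (what == "exon") exonBlocks(models) else cdsBlocks(models)
      if (!tid %in% names(blocks)) next
      b <- sort(blocks[[tid]])
      for (j in seq_along(b)) {
        lines <- c(lines, paste(chrom, GFF_SOURCE, what,
                                GenomicRanges::start(b)[j],
                                GenomicRanges::end(b)[j], ".", std,
                                if (what == "CDS") "0" else ".",
                                gffAttr(Parent = tid), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- BLAST tabular --------------------------------------------------------

#' Parse BLAST tabular (outfmt 6) alignments
#'
#' Reads the 12 standard columns, optionally extended with a 13th column
#' giving the longest contiguous match run.  Identities are computed as
#' `round(pident * length / 100)`; minus-strand rows (subject start >
#' subject end) are normalised to `t_start <= t_end` with `strand = "-"`.
#' When the 13th column is absent the run statistic is left `NA`, to be
#' recomputed from sequences with [rescoreHits()] (it must never be guessed
#' from percent identity).
#'
#' @param path tabular file path.
#' @param targetKind one of `"gDNA"`, `"transcript"`, `"EST"`.
#' @return hit data.frame; empty for an empty file.
#' @export
parseBlastTabular <- function(path, targetKind = "gDNA") {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(emptyHits(targetKind))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(emptyHits(targetKind))
  parts <- strsplit(lines, "\t")
  ncol <- lengths(parts)
  if (any(ncol < 12L | ncol > 13L))
    stop("malformed BLAST tabular row at line ",
         which(ncol < 12L | ncol > 13L)[1])
  m <- do.call(rbind, lapply(parts, function(p) p[1:12]))
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, nrow = nrow(m))
  if (anyNA(num))
    stop("malformed BLAST tabular row at line ",
         which(apply(is.na(num), 1, any))[1])
  ss <- as.integer(num[, 7]); se <- as.integer(num[, 8])
  minus <- ss > se
  lc <- rep(NA_integer_, length(lines))
  if (any(ncol == 13L)) {
    v <- vapply(parts, function(p) if (length(p) >= 13L) p[13] else
      NA_character_, character(1))
    lc <- suppressWarnings(as.integer(v))
  }
  alnLen <- as.integer(num[, 2])
  hits <- data.frame(
    query_id = m[, 1], target_id = m[, 2], target_kind = targetKind,
    strand = ifelse(minus, "-", "+"),
    q_start = as.integer(num[, 5]), q_end = as.integer(num[, 6]),
    t_start = ifelse(minus, se, ss), t_end = ifelse(minus, ss, se),
    q_len = NA_integer_,
    identities = as.integer(round(num[, 1] * alnLen / 100)),
    aln_length = alnLen,
    longest_contiguous = lc,
    n_blocks = 1L,
    raw_score = num[, 10],
    evalue = num[, 9],
    stringsAsFactors = FALSE)
  hits$blocks <- lapply(seq_len(nrow(hits)), function(i)
    cbind(q_start = hits$q_start[i], q_end = hits$q_end[i],
          t_start = hits$t_start[i], t_end = hits$t_end[i]))
  hits
}

#' Write hits in BLAST tabular (outfmt 6) layout
#'
#' The inverse of [parseBlastTabular()]: 12 standard columns plus a 13th
#' carrying the longest contiguous run.  Minus-strand hits are written with
#' subject start > subject end, per the tabular convention.
#'
#' @param hits hit data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeBlastTabular <- function(hits, path) {
  if (nrow(hits) == 0L) { writeLines(character(), path); return(invisible(path)) }
  pid <- sprintf("%.3f", 100 * hits$identities / hits$aln_length)
  ss <- ifelse(hits$strand == "-", hits$t_end, hits$t_start)
  se <- ifelse(hits$strand == "-", hits$t_start, hits$t_end)
  ev <- ifelse(is.na(hits$evalue), 0, hits$evalue)
  lines <- paste(hits$query_id, hits$target_id, pid, hits$aln_length,
                 hits$aln_length - hits$identities, 0L,
                 hits$q_start, hits$q_end, ss, se,
                 format(ev, scientific = TRUE, digits = 6, trim = TRUE),
                 hits$raw_score, hits$longest_contiguous, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# ---- exonerate-style spliced blocks ---------------------------------------

#' Read spliced alignments from a block-per-row TSV
#'
#' Import path for externally computed spliced (exonerate-style)
#' alignments.  Header columns: `hit_id`, `query_id`, `target_id`,
#' `strand`, `raw_score`, `q_start`, `q_end`, `t_start`, `t_end`; one row
#' per block, blocks of one hit sharing a `hit_id`.
#'
#' @param path TSV path.
#' @param targetKind target kind tag (default `"gDNA"`).
#' @return hit data.frame with multi-block hits assembled.
#' @export
parseExonerateBlocks <- function(path, targetKind = "gDNA") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("hit_id", "query_id", "target_id", "strand", "raw_score",
            "q_start", "q_end", "t_start", "t_end")
  if (!all(need %in% colnames(df)))
    stop("block TSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) return(emptyHits(targetKind))
  out <- lapply(split(df, df$hit_id), function(g) {
    g <- g[order(g$q_start), , drop = FALSE]
    h <- data.frame(
      query_id = g$query_id[1], target_id = g$target_id[1],
      target_kind = targetKind, strand = g$strand[1],
      q_start = min(g$q_start), q_end = max(g$q_end),
      t_start = min(g$t_start), t_end = max(g$t_end),
      q_len = NA_integer_, identities = NA_integer_,
      aln_length = sum(g$q_end - g$q_start + 1L),
      longest_contiguous = NA_integer_, n_blocks = nrow(g),
      raw_score = g$raw_score[1], evalue = NA_real_,
      stringsAsFactors = FALSE)
    h$blocks <- list(cbind(q_start = g$q_start, q_end = g$q_end,
                           t_start = g$t_start, t_end = g$t_end))
    h
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write spliced hits as a block-per-row TSV
#'
#' @param hits hit data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeExonerateBlocks <- function(hits, path) {
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    b <- hits$blocks[[i]]
    rows[[i]] <- data.frame(
      hit_id = sprintf("%s|%s|%d", hits$query_id[i], hits$target_id[i], i),
      query_id = hits$query_id[i], target_id = hits$target_id[i],
      strand = hits$strand[i], raw_score = hits$raw_score[i],
      q_start = b[, "q_start"], q_end = b[, "q_end"],
      t_start = b[, "t_start"], t_end = b[, "t_end"],
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hit_id = character(), query_id = character(),
               target_id = character(), strand = character(),
               raw_score = numeric(), q_start = integer(),
               q_end = integer(), t_start = integer(), t_end = integer())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- annotation outputs ---------------------------------------------------

#' Write the per-reporter annotation table
#'
#' @param results annotation result data.frame from [classifyAll()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeAnnotationTable <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read back an annotation table written by [writeAnnotationTable()]
#'
#' @param path TSV path.
#' @return annotation result data.frame.
#' @export
readAnnotationTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  df
}

#' Export reporter placements as a GFF3 genome-browser track
#'
#' One `oligo` feature per placed reporter, with the reporter ID, its
#' annotation group and (when present) the gene model in the attributes.
#' Reporters in the `inconclusive` and `est` groups are excluded from the
#' track; a reporter in any other group without genomic coordinates is an
#' internal inconsistency and raises an error.
#'
#' @param results annotation result data.frame from [classifyAll()].
#' @param path output GFF3 path.
#' @return invisibly, `path`.
#' @export
writeGffTrack <- function(results, path) {
  keep <- !(results$group %in% c("inconclusive", "est"))
  sub <- results[keep, , drop = FALSE]
  noCoord <- is.na(sub$chrom) | is.na(sub$start) | is.na(sub$end)
  if (any(noCoord))
    stop("reporter(s) in a track-writable group without genomic ",
         "coordinates: ", paste(sub$reporter_id[noCoord], collapse = ", "))
  lines <- "##gff-version 3"
  if (nrow(sub)) {
    sub <- sub[order(sub$chrom, sub$start, sub$reporter_id), , drop = FALSE]
    attrs <- vapply(seq_len(nrow(sub)), function(i) {
      gffAttr(ID = sub$reporter_id[i], annotation_group = sub$group[i],
              gene_id = if (is.na(sub$gene_ids[i])) "" else sub$gene_ids[i])
    }, character(1))
    lines <- c(lines, paste(sub$chrom, GFF_SOURCE, "oligo", sub$start,
                            sub$end, ".", sub$strand, ".", attrs,
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- expression matrix ----------------------------------------------------

#' Read a long-format expression TSV into a SummarizedExperiment
#'
#' Expects header columns `reporter_id`, `array_id`, `signal`, `noise`;
#' returns a `SummarizedExperiment` with `signal` and `noise` assays
#' (reporters x arrays).  Noise values must be strictly positive.
#'
#' @param path TSV path.
#' @return `SummarizedExperiment` with assays `signal` and `noise`.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("reporter_id", "array_id", "signal", "noise")
  if (!all(need %in% colnames(df)))
    stop("expression TSV must have columns: ", paste(need, collapse = ", "))
  if (any(df$noise <= 0)) stop("noise values must be strictly positive")
  reps <- unique(df$reporter_id); arrays <- unique(df$array_id)
  shape <- function(col) {
    m <- matrix(NA_real_, length(reps), length(arrays),
                dimnames = list(reps, arrays))
    m[cbind(match(df$reporter_id, reps), match(df$array_id, arrays))] <-
      df[[col]]
    m
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = shape("signal"), noise = shape("noise")))
}

#' Write a SummarizedExperiment expression matrix as long-format TSV
#'
#' @param se `SummarizedExperiment` with `signal` and `noise` assays.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeExpressionMatrix <- function(se, path) {
  sig <- SummarizedExperiment::assay(se, "signal")
  noi <- SummarizedExperiment::assay(se, "noise")
  df <- data.frame(
    reporter_id = rep(rownames(sig), times = ncol(sig)),
    array_id = rep(colnames(sig), each = nrow(sig)),
    signal = sprintf("%.3f", as.vector(sig)),
    noise = sprintf("%.3f", as.vector(noi)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
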