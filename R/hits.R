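#' @include AllClasses.R
NULL

HIT_COLUMNS <- c("query_id", "target_id", "target_kind", "strand",
                 "q_start", "q_end", "t_start", "t_end", "q_len",
                 "identities", "aln_length", "longest_contiguous",
                 "n_blocks", "raw_score", "evalue")

#' Empty alignment-hit table
#'
#' Alignment hits are plain data.frames with a fixed column contract shared
#' by every module: 1-based inclusive coordinates on query and target,
#' `t_start <= t_end` always with the strand stored separately (the strand
#' of the query relative to the target's forward strand), identity and
#' longest-contiguous-run counts, and a `blocks` list column holding one
#' four-column matrix (`q_start`, `q_end`, `t_start`, `t_end`) per hit for
#' spliced alignments (`n_blocks > 1`).
#'
#' @param targetKind one of `"gDNA"`, `"transcript"`, `"EST"`.
#' @return A zero-row hit data.frame with the canonical columns.
#' @examples
#' emptyHits("gDNA")
#' @export
emptyHits <- function(targetKind = "gDNA") {
  df <- data.frame(query_id = character(), target_id = character(),
                   target_kind = character(), strand = character(),
                   q_start = integer(), q_end = integer(),
                   t_start = integer(), t_end = integer(),
                   q_len = integer(), identities = integer(),
                   aln_length = integer(), longest_contiguous = integer(),
                   n_blocks = integer(), raw_score = numeric(),
                   evalue = numeric(), stringsAsFactors = FALSE)
  df$blocks <- list()
  df
}

# promote the raw C++ seed-extend table to the canonical hit frame
asHits <- function(df, targetKind) {
  if (is.null(df) || nrow(df) == 0L) return(emptyHits(targetKind))
  out <- data.frame(
    query_id = as.character(df$query_id),
    target_id = as.character(df$target_id),
    target_kind = targetKind,
    strand = as.character(df$strand),
    q_start = as.integer(df$q_start), q_end = as.integer(df$q_end),
    t_start = as.integer(df$t_start), t_end = as.integer(df$t_end),
    q_len = as.integer(df$q_len),
    identities = as.integer(df$identities),
    aln_length = as.integer(df$aln_length),
    longest_contiguous = as.integer(df$longest_contiguous),
    n_blocks = 1L,
    raw_score = as.numeric(df$raw_score),
    evalue = NA_real_,
    stringsAsFactors = FALSE)
  out$blocks <- lapply(seq_len(nrow(out)), function(i)
    cbind(q_start = out$q_start[i], q_end = out$q_end[i],
          t_start = out$t_start[i], t_end = out$t_end[i]))
  rownames(out) <- NULL
  out
}

# assign target_kind robustly (zero-row frames included)
setKind <- function(hits, kind) {
  hits$target_kind <- rep(kind, nrow(hits))
  hits
}

validateHits <- function(hits) {
  stopifnot(is.data.frame(hits), all(HIT_COLUMNS %in% colnames(hits)))
  if (nrow(hits)) {
    stopifnot(all(hits$t_start <= hits$t_end),
              all(hits$q_start <= hits$q_end),
              all(hits$identities >= 0L),
              all(hits$identities <= hits$aln_length),
              all(hits$strand %in% c("+", "-")))
    ok <- hits$identities == 0L |
      (hits$longest_contiguous >= 1L &
         hits$longest_contiguous <= hits$identities)
    stopifnot(all(ok))
  }
  invisible(hits)
}

# deterministic hit ordering: best score first, ties by lowest target_id,
# t_start, then '+' strand
orderHits <- function(hits) {
  hits[order(-hits$raw_score, hits$target_id, hits$t_start,
             hits$strand != "+"), , drop = FALSE]
}

hitsToGRanges <- function(hits) {
  GenomicRanges::GRanges(
    seqnames = hits$target_id,
    ranges = IRanges::IRanges(start = hits$t_start, end = hits$t_end),
    strand = hits$strand)
}

#' Reverse complement of plain character sequences
#'
#' Thin character-vector wrapper around Biostrings so that all modules use
#' one complementation rule (N maps to N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revComp("ACGTN")
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
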