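# Shared fixtures (memoised per test run) and small utilities.

.fixtureCache <- new.env(parent = emptyenv())

# small fixture for module tests: one 80 kb chromosome, 4 reporters/group
smallFixture <- function() {
  if (is.null(.fixtureCache$small)) {
    .fixtureCache$small <- generateFixture(fixtureSpec(
      nChromosomes = 1L, chromLength = 80000L,
      nPerGroup = c(sense_gene_model = 4L, antisense_gene_model = 4L,
                    gdna = 4L, est = 4L, ambiguous = 4L,
                    inconclusive = 4L),
      nIntronSpanning = 2L, seed = 11L))
  }
  .fixtureCache$small
}

# the default study-condition fixture (two 500 kb chromosomes, 50 per
# group, ten intron-spanning extras)
defaultFixture <- function() {
  if (is.null(.fixtureCache$default)) {
    .fixtureCache$default <- generateFixture(fixtureSpec())
  }
  .fixtureCache$default
}

defaultResults <- function() {
  if (is.null(.fixtureCache$defaultRes)) {
    fx <- defaultFixture()
    .fixtureCache$defaultRes <- classifyAll(fx$manifest, fx$genome,
                                            fx$transcripts, fx$models,
                                            fx$ests)
  }
  .fixtureCache$defaultRes
}

# the small fixture written to disk (plus an expression matrix), shared by
# the file-level tests
fixtureOnDisk <- function() {
  if (is.null(.fixtureCache$disk)) {
    d <- file.path(tempdir(), "probeRemap-fixture")
    fx <- generateFixture(fixtureSpec(
      nChromosomes = 1L, chromLength = 80000L,
      nPerGroup = c(sense_gene_model = 4L, antisense_gene_model = 4L,
                    gdna = 4L, est = 4L, ambiguous = 4L,
                    inconclusive = 4L),
      nIntronSpanning = 2L, seed = 11L), dir = d)
    ex <- generateExpression(fx$manifest, nArrays = 8L,
                             silentFraction = 0.25, seed = 2L, dir = d)
    fx$expression <- ex
    .fixtureCache$disk <- fx
  }
  .fixtureCache$disk
}

# mirror a fixture: reverse-complement every chromosome and flip the model
# coordinates/strands accordingly (transcripts, ESTs, reporters unchanged)
revCompFixture <- function(fx) {
  L <- nchar(fx$genome)
  genome <- setNames(revComp(fx$genome), names(fx$genome))
  flipGr <- function(gr) {
    chrom <- as.character(GenomicRanges::seqnames(gr))
    n <- L[chrom]
    GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(n - GenomicRanges::end(gr) + 1L,
                       n - GenomicRanges::start(gr) + 1L),
      ifelse(as.character(GenomicRanges::strand(gr)) == "+", "-", "+"))
  }
  tx <- transcriptRanges(fx$models)
  tx2 <- flipGr(tx)
  S4Vectors::mcols(tx2) <- S4Vectors::mcols(tx)
  flipGrl <- function(grl)
    GenomicRanges::GRangesList(lapply(grl, function(g) sort(flipGr(g))))
  models <- new("TranscriptModels", transcripts = tx2,
                exons = flipGrl(exonBlocks(fx$models)),
                cds = flipGrl(cdsBlocks(fx$models)))
  out <- fx
  out$genome <- genome
  out$models <- models
  out
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutateAt <- function(seq, pos) {
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  seq
}

# a synthetic single-block hit row for filter tests
makeHit <- function(query = "q1", target = "t1", score = 60,
                    identities = 60L, contig = 60L, alnLen = 60L,
                    qLen = 60L, tStart = 1L, strand = "+", evalue = NA_real_,
                    targetKind = "gDNA", nBlocks = 1L) {
  h <- data.frame(query_id = query, target_id = target,
                  target_kind = targetKind, strand = strand,
                  q_start = 1L, q_end = as.integer(alnLen),
                  t_start = as.integer(tStart),
                  t_end = as.integer(tStart + alnLen - 1L),
                  q_len = as.integer(qLen),
                  identities = as.integer(identities),
                  aln_length = as.integer(alnLen),
                  longest_contiguous = as.integer(contig),
                  n_blocks = as.integer(nBlocks),
                  raw_score = score, evalue = evalue,
                  stringsAsFactors = FALSE)
  h$blocks <- list(cbind(q_start = h$q_start, q_end = h$q_end,
                         t_start = h$t_start, t_end = h$t_end))
  h
}

bindHits <- function(...) do.call(rbind, list(...))
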