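test_that("FASTA reading takes the first header token and uppercases", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1 some description words", "acgt", ">r2", "GGCC"), f)
  m <- readFastaMap(f)
  expect_identical(m, c(r1 = "ACGT", r2 = "GGCC"))
})

test_that("FASTA reader errors on duplicate IDs and warns on empty files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), f)
  expect_error(readFastaMap(f), "duplicate.*a")
  e <- withr::local_tempfile(fileext = ".fa")
  file.create(e)
  expect_warning(m <- readFastaMap(e), "empty")
  expect_length(m, 0L)
})

test_that("FASTA writer round-trips sequences exactly", {
  x <- c(chr1 = randomDna(333), chr2 = randomDna(150))
  f <- withr::local_tempfile(fileext = ".fa")
  writeFastaMap(x, f)
  expect_identical(readFastaMap(f), x)
})

test_that("reporter manifest parses rows, blanks and odd lengths", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reporter_id\tsequence\test_accession",
               paste0("r1\t", strrep("ACGT", 15), "\tE1"),
               paste0("r2\t", strrep("GATC", 15), "\t"),
               paste0("r3\t", strrep("TTAA", 15), "\tE3")), f)
  m <- readReporterManifest(f)
  expect_equal(nrow(m), 3L)
  expect_true(is.na(m$est_accession[2]))
  expect_identical(m$est_accession[c(1, 3)], c("E1", "E3"))

  # a 59-mer is accepted with a warning: length is an expectation, not a rule
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reporter_id\tsequence\test_accession",
               paste0("r1\t", strrep("A", 59), "\t")), f2)
  expect_warning(m2 <- readReporterManifest(f2), "length")
  expect_equal(nchar(m2$sequence), 59L)
})

test_that("reporter manifest rejects duplicates and bad alphabets", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reporter_id\tsequence\test_accession",
               "r1\tACGT\t", "r1\tACGT\t"), f)
  expect_error(suppressWarnings(readReporterManifest(f)), "duplicate")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reporter_id\tsequence\test_accession", "r1\tACXT\t"), f2)
  expect_error(suppressWarnings(readReporterManifest(f2)), "non-ACGTN")
})

test_that("transcript spans round-trip through GFF3 write and re-read", {
  fx <- smallFixture()
  f <- withr::local_tempfile(fileext = ".gff3")
  writeTranscriptSpans(fx$models, f)
  back <- readTranscriptSpans(f, "gff3")
  a <- transcriptRanges(fx$models); b <- transcriptRanges(back)
  oa <- order(S4Vectors::mcols(a)$transcript_id)
  ob <- order(S4Vectors::mcols(b)$transcript_id)
  expect_equal(GenomicRanges::start(a)[oa], GenomicRanges::start(b)[ob])
  expect_equal(GenomicRanges::end(a)[oa], GenomicRanges::end(b)[ob])
  expect_identical(as.character(GenomicRanges::strand(a))[oa],
                   as.character(GenomicRanges::strand(b))[ob])
  expect_identical(S4Vectors::mcols(a)$gene_id[oa],
                   S4Vectors::mcols(b)$gene_id[ob])
  # exon blocks survive too
  tid <- S4Vectors::mcols(a)$transcript_id[oa][1]
  expect_equal(GenomicRanges::start(exonBlocks(fx$models)[[tid]]),
               GenomicRanges::start(exonBlocks(back)[[tid]]))
})

test_that("TSV span dialect works with and without exon columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttranscript_id\tchrom\tstart\tend\tstrand\texons",
               "G1\tT1\tchr1\t100\t500\t+\t100-200,300-500",
               "G2\tT2\tchr2\t900\t1200\t-\t"), f)
  m <- readTranscriptSpans(f, "tsv")
  expect_equal(length(transcriptRanges(m)), 2L)
  expect_equal(GenomicRanges::start(exonBlocks(m)[["T1"]]), c(100, 300))
  expect_false("T2" %in% names(exonBlocks(m)))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttranscript_id\tchrom\tstart\tend\tstrand",
               "G1\tT1\tchr1\t100\t500\t."), f2)
  expect_error(readTranscriptSpans(f2, "tsv"), "strand")
})

test_that("BLAST tabular parsing normalises strand and computes identities", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "r1\tchr1\t100.0\t60\t0\t0\t1\t60\t500\t559\t1e-30\t120",
    "r2\tchr1\t95.0\t60\t3\t0\t1\t60\t700\t641\t1e-20\t90\t31"), f)
  h <- parseBlastTabular(f)
  expect_equal(nrow(h), 2L)
  expect_equal(h$identities[1], 60L)
  expect_equal(h$t_start[1], 500L)
  expect_identical(h$strand[1], "+")
  # minus-strand row: subject coordinates normalised, strand flagged
  expect_identical(h$strand[2], "-")
  expect_equal(c(h$t_start[2], h$t_end[2]), c(641L, 700L))
  expect_equal(h$identities[2], 57L)
  expect_equal(h$longest_contiguous[2], 31L)
  expect_true(is.na(h$longest_contiguous[1]))
})

test_that("BLAST tabular parser is total on well-formed files", {
  f <- withr::local_tempfile(fileext = ".tsv")
  n <- 25L
  writeLines(sprintf("q%d\tt1\t98.3\t60\t1\t0\t1\t60\t%d\t%d\t1e-9\t50",
                     seq_len(n), 100 + seq_len(n), 159 + seq_len(n)), f)
  expect_equal(nrow(parseBlastTabular(f)), n)
  e <- withr::local_tempfile(fileext = ".tsv")
  file.create(e)
  expect_equal(nrow(parseBlastTabular(e)), 0L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\tt1\tnot_a_number", bad)
  expect_error(parseBlastTabular(bad), "line 1")
})

test_that("BLAST tabular writing round-trips through the parser", {
  idx <- buildSeedIndex(c(chr1 = randomDna(4000)), 23)
  q <- setNames(substr(idx@targets[["chr1"]], 1001, 1060), "r1")
  h <- findUngappedHits(q, idx)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeBlastTabular(h, f)
  back <- parseBlastTabular(f)
  expect_equal(back$t_start, h$t_start)
  expect_equal(back$t_end, h$t_end)
  expect_identical(back$strand, h$strand)
  expect_equal(back$identities, h$identities)
  expect_equal(back$longest_contiguous, h$longest_contiguous)
})

test_that("exonerate-style block TSV round-trips spliced hits", {
  fx <- smallFixture()
  intronRep <- fx$truth$reporter_id[fx$truth$notes == "intron_spanning"][1]
  q <- setNames(fx$manifest$sequence[fx$manifest$reporter_id == intronRep],
                intronRep)
  sp <- splicedAlign(q, buildSeedIndex(fx$genome, 23))
  sp <- sp[sp$n_blocks > 1L, , drop = FALSE]
  expect_gte(nrow(sp), 1L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExonerateBlocks(sp, f)
  back <- parseExonerateBlocks(f)
  expect_equal(back$n_blocks[1], sp$n_blocks[1])
  expect_equal(unname(back$blocks[[1]]), unname(sp$blocks[[1]]))
  back <- rescoreHits(back, q, fx$genome)
  expect_equal(back$identities[1], sp$identities[1])
  expect_equal(back$longest_contiguous[1], sp$longest_contiguous[1])
})

test_that("GFF track excludes est/inconclusive and round-trips coordinates", {
  res <- data.frame(
    reporter_id = c("r1", "r2", "r3", "r4"),
    group = c("sense_gene_model", "gdna", "inconclusive", "est"),
    gene_ids = c("G1", NA, NA, "G9"),
    chrom = c("chr1", "chr2", NA, "chr1"),
    start = c(500L, 900L, NA, 10L), end = c(559L, 959L, NA, 69L),
    strand = c("+", "-", NA, "+"),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".gff3")
  writeGffTrack(res, f)
  gr <- rtracklayer::import(f, format = "gff3")
  expect_equal(length(gr), 2L)
  expect_setequal(gr$ID, c("r1", "r2"))
  expect_identical(as.character(gr$type), rep("oligo", 2))
  r1 <- gr[gr$ID == "r1"]
  expect_equal(GenomicRanges::start(r1), 500L)
  expect_equal(GenomicRanges::end(r1), 559L)
  expect_identical(as.character(GenomicRanges::strand(r1)), "+")

  # only excluded groups present -> header-only file
  f2 <- withr::local_tempfile(fileext = ".gff3")
  writeGffTrack(res[res$group %in% c("inconclusive", "est"), ], f2)
  expect_identical(readLines(f2), "##gff-version 3")

  # writable group without coordinates is an internal inconsistency
  broken <- res
  broken$chrom[1] <- NA
  expect_error(writeGffTrack(broken, f2), "without genomic")
})

test_that("expression matrix TSV round-trips through SummarizedExperiment", {
  fx <- smallFixture()
  ex <- generateExpression(fx$manifest, nArrays = 5L, seed = 3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(ex$se, f)
  back <- readExpressionMatrix(f)
  expect_equal(dim(back), dim(ex$se))
  expect_equal(SummarizedExperiment::assay(back, "signal"),
               SummarizedExperiment::assay(ex$se, "signal"))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reporter_id\tarray_id\tsignal\tnoise", "r1\ta1\t10\t0"), bad)
  expect_error(readExpressionMatrix(bad), "positive")
})
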