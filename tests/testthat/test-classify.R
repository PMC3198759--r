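cfg <- pipelineConfig()

agrRow <- function(rid = "r1", gene = "G1", orientation = "sense",
                   source = "reporter", chrom = "chr1", gs = 100L,
                   ge = 159L, strand = "+", score = 60) {
  data.frame(reporter_id = rid, gene_id = gene, transcript_id = paste0(gene, "_T"),
             source = source, orientation = orientation, chrom = chrom,
             g_start = gs, g_end = ge, g_strand = strand,
             region = "unknown", intron_spanning = FALSE, score = score,
             stringsAsFactors = FALSE)
}

evMake <- function(nGdna = 0L, nWgs = 0L, estVerified = FALSE,
                   nEstWgs = 0L, nEstGdna = 0L, rid = "r1",
                   gdnaStart = 100L) {
  hitsN <- function(n, kind, start = 100L, ev = NA_real_) {
    if (n == 0L) return(emptyHits(kind))
    do.call(rbind, lapply(seq_len(n), function(i)
      makeHit(query = rid, target = if (kind == "gDNA") "chr1" else
        paste0("T", i), targetKind = kind,
        tStart = start + (i - 1L) * 1000L, evalue = ev)))
  }
  new("EvidenceSet", reporterId = rid,
      reporterGdna = hitsN(nGdna, "gDNA", gdnaStart),
      reporterWgs = hitsN(nWgs, "transcript"),
      estWgs = if (estVerified) hitsN(nEstWgs, "transcript", ev = 1e-30)
               else emptyHits("transcript"),
      estGdna = if (estVerified) hitsN(nEstGdna, "gDNA") else
        emptyHits("gDNA"),
      reporterEst = emptyHits("EST"), estVerified = estVerified)
}

test_that("decision branches assign the documented groups", {
  empty <- agrRow()[0, ]
  # (b) single sense agreement
  r <- classifyReporter(evMake(1L, 1L), agrRow(), empty, cfg)
  expect_identical(r$group, "sense_gene_model")
  expect_identical(r$gene_ids, "G1")
  expect_equal(c(r$start, r$end), c(100L, 159L))
  # (b) antisense orientation
  r2 <- classifyReporter(evMake(1L, 1L),
                         agrRow(orientation = "antisense"), empty, cfg)
  expect_identical(r2$group, "antisense_gene_model")
  # (vi) no hits at all
  r3 <- classifyReporter(evMake(), empty, empty, cfg)
  expect_identical(r3$group, "inconclusive")
  expect_identical(r3$rationale_code, "no_valid_hits")
  # (v) two sense agreements on different chromosomes
  r4 <- classifyReporter(evMake(2L, 2L),
                         rbind(agrRow(), agrRow(gene = "G2", chrom = "chr2")),
                         empty, cfg)
  expect_identical(r4$group, "ambiguous")
  expect_identical(r4$gene_ids, "G1,G2")
  # (iii) unique genomic location, no transcript
  r5 <- classifyReporter(evMake(1L, 0L), empty, empty, cfg)
  expect_identical(r5$group, "gdna")
  expect_true(is.na(r5$gene_ids))
  # (iv) EST-only agreement
  r6 <- classifyReporter(evMake(0L, 0L, estVerified = TRUE, nEstWgs = 1L,
                                nEstGdna = 1L),
                         empty, agrRow(source = "est"), cfg)
  expect_identical(r6$group, "est")
  # conflicting EST placement vs reporter genomic hit -> inconclusive
  r7 <- classifyReporter(evMake(1L, 0L, estVerified = TRUE, nEstWgs = 1L,
                                nEstGdna = 1L, gdnaStart = 99000L),
                         empty, agrRow(source = "est"), cfg)
  expect_identical(r7$group, "inconclusive")
  expect_identical(r7$rationale_code, "conflicting_est_and_gdna")
  # corroborating overlap keeps the EST call
  r8 <- classifyReporter(evMake(1L, 0L, estVerified = TRUE, nEstWgs = 1L,
                                nEstGdna = 1L, gdnaStart = 120L),
                         empty, agrRow(source = "est"), cfg)
  expect_identical(r8$group, "est")
  # transcripts without genomic agreement stay inconclusive
  r9 <- classifyReporter(evMake(0L, 2L), empty, empty, cfg)
  expect_identical(r9$group, "inconclusive")
  expect_identical(r9$rationale_code, "transcript_without_genomic_agreement")
  # multiple genomic locations without transcripts
  r10 <- classifyReporter(evMake(3L, 0L), empty, empty, cfg)
  expect_identical(r10$group, "inconclusive")
  expect_identical(r10$rationale_code, "multiple_genomic_locations")
})

test_that("randomized evidence matches the decision-table oracle", {
  set.seed(47)
  empty <- agrRow()[0, ]
  for (rep in 1:200) {
    nGdna <- sample(0:3, 1); nWgs <- sample(0:3, 1)
    nRepAgr <- if (nGdna > 0L && nWgs > 0L) sample(0:min(2L, nWgs), 1) else 0L
    estVer <- sample(c(TRUE, FALSE), 1)
    nEstAgr <- if (estVer) sample(0:2, 1) else 0L
    repAgr <- if (nRepAgr > 0L)
      do.call(rbind, lapply(seq_len(nRepAgr), function(i)
        agrRow(gene = paste0("G", i),
               orientation = sample(c("sense", "antisense"), 1),
               chrom = "chr1", gs = 100L + 1000L * (i - 1L),
               ge = 159L + 1000L * (i - 1L)))) else empty
    estAgr <- if (nEstAgr > 0L)
      do.call(rbind, lapply(seq_len(nEstAgr), function(i)
        agrRow(gene = paste0("G", 10L + i), source = "est",
               gs = 100L, ge = 159L))) else empty
    ev <- evMake(nGdna, nWgs, estVerified = estVer,
                 nEstWgs = max(nEstAgr, estVer * sample(0:1, 1)),
                 nEstGdna = nEstAgr)
    got <- classifyReporter(ev, repAgr, estAgr, cfg)$group
    # est placement at 100..159 always overlaps the first gdna hit at 100
    want <- oracleGroup(nRepAgr,
                        if (nRepAgr == 1L) repAgr$orientation[1] else "",
                        nEstAgr, nGdna, nWgs, estCorroborated = TRUE,
                        nGenesAll = length(union(repAgr$gene_id,
                                                 estAgr$gene_id)))
    expect_identical(got, want,
                     info = sprintf("gdna=%d wgs=%d rep=%d est=%d",
                                    nGdna, nWgs, nRepAgr, nEstAgr))
  }
})

test_that("group summaries partition the reporters", {
  res <- data.frame(reporter_id = sprintf("r%d", 1:10),
                    group = "sense_gene_model",
                    gene_ids = "G1", stringsAsFactors = FALSE)
  s <- summarizeGroups(res)
  expect_equal(s$count[s$group == "sense_gene_model"], 10L)
  expect_equal(s$proportion[s$group == "sense_gene_model"], 100)
  expect_equal(s$count[s$group == "total"], 10L)
  expect_true(all(s$count[s$group %in% c("antisense_gene_model", "gdna",
                                         "est", "ambiguous",
                                         "inconclusive")] == 0L))
  sEmpty <- summarizeGroups(res[0, ])
  expect_true(all(sEmpty$count == 0L))
  # proportions recompute from counts
  fx <- smallFixture()
  res2 <- classifyAll(fx$manifest, fx$genome, fx$transcripts, fx$models,
                      fx$ests, cfg)
  s2 <- summarizeGroups(res2)
  body <- s2[s2$group != "total", ]
  expect_equal(sum(body$count), nrow(res2))
  expect_equal(body$proportion,
               round(100 * body$count / nrow(res2), 1), tolerance = 1e-3)
})

test_that("reporters-per-gene counts links over distinct genes", {
  mk <- function(groups, genes)
    data.frame(reporter_id = sprintf("r%d", seq_along(groups)),
               group = groups, gene_ids = genes, stringsAsFactors = FALSE)
  expect_equal(reportersPerGene(mk(rep("sense_gene_model", 3), rep("G1", 3))),
               3)
  expect_equal(reportersPerGene(mk(rep("sense_gene_model", 2),
                                   c("G1", "G2"))), 1)
  # ambiguous links count each gene once
  expect_equal(reportersPerGene(mk(c("sense_gene_model", "ambiguous"),
                                   c("G1", "G1,G2"))), 3 / 2)
  expect_message(v <- reportersPerGene(mk("gdna", NA_character_)),
                 "not applicable")
  expect_true(is.na(v))
})

test_that("expression flags are strict and tabulate by group", {
  sig <- matrix(c(300, 90, 90, 90, 50, 60), nrow = 3, byrow = TRUE,
                dimnames = list(c("r1", "r2", "r3"), c("a1", "a2")))
  noi <- matrix(c(50, 45, 30, 30, 100, 100), nrow = 3, byrow = TRUE,
                dimnames = dimnames(sig))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = sig, noise = noi))
  f <- flagExpressed(se, cfg)
  expect_identical(unname(f), c(TRUE, FALSE, FALSE))  # SNR exactly 3 -> FALSE
  res <- data.frame(reporter_id = c("r1", "r2", "r3"),
                    group = c("sense_gene_model", "sense_gene_model",
                              "gdna"), stringsAsFactors = FALSE)
  tab <- expressionByGroup(f, res)
  expect_equal(tab$n_expressed[tab$group == "sense_gene_model"], 1L)
  expect_equal(tab$proportion_expressed[tab$group == "sense_gene_model"], 50)
  expect_equal(tab$n_expressed[tab$group == "total"], 1L)
  expect_error(expressionByGroup(f[1:2], res), "missing")
})

test_that("duplicating a planted gene moves its reporter to ambiguous", {
  fx <- smallFixture()
  rid <- fx$truth$reporter_id[fx$truth$planted_group ==
                                "sense_gene_model"][1]
  gene <- fx$truth$gene_id[fx$truth$reporter_id == rid]
  tx <- transcriptRanges(fx$models)
  ti <- match(gene, S4Vectors::mcols(tx)$gene_id)
  tid <- S4Vectors::mcols(tx)$transcript_id[ti]
  span <- c(GenomicRanges::start(tx)[ti], GenomicRanges::end(tx)[ti])

  # append a perfect copy of the locus as a new chromosome + gene model
  genome2 <- c(fx$genome,
               chrDup = substr(fx$genome[[as.character(
                 GenomicRanges::seqnames(tx))[ti]]], span[1], span[2]))
  tx2 <- suppressWarnings(c(tx, GenomicRanges::GRanges(
    "chrDup", IRanges::IRanges(1L, span[2] - span[1] + 1L),
    as.character(GenomicRanges::strand(tx))[ti],
    transcript_id = "DUP_T01", gene_id = "GDUP")))
  models2 <- new("TranscriptModels", transcripts = tx2,
                 exons = exonBlocks(fx$models), cds = cdsBlocks(fx$models))
  transcripts2 <- c(fx$transcripts, DUP_T01 = unname(fx$transcripts[tid]))

  man <- fx$manifest[fx$manifest$reporter_id == rid, , drop = FALSE]
  before <- classifyAll(man, fx$genome, fx$transcripts, fx$models,
                        fx$ests, cfg)
  after <- classifyAll(man, genome2, transcripts2, models2, fx$ests, cfg)
  expect_identical(before$group, "sense_gene_model")
  expect_identical(after$group, "ambiguous")
  expect_identical(after$gene_ids, paste(sort(c(gene, "GDUP")),
                                         collapse = ","))
})
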