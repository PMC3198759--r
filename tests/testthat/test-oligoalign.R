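test_that("seed index posting counts match brute-force window enumeration", {
  idx <- buildSeedIndex(c(t1 = "ACGTACGT"), k = 4)
  expect_equal(nPostings(idx), 5)          # L - k + 1

  idxN <- buildSeedIndex(c(t1 = "ACGTNACGTACG"), k = 4)
  # windows touching the N never seed
  bruteCount <- function(targets, k) {
    sum(vapply(targets, function(t) {
      w <- substring(t, seq_len(nchar(t) - k + 1),
                     seq_len(nchar(t) - k + 1) + k - 1)
      sum(!grepl("N", w, fixed = TRUE))
    }, numeric(1)))
  }
  expect_equal(nPostings(idxN), bruteCount(idxN@targets, 4))

  set.seed(5)
  for (rep in 1:5) {
    targets <- setNames(vapply(1:3, function(i)
      mutateAt(randomDna(200), integer()), character(1)),
      paste0("t", 1:3))
    k <- sample(3:8, 1)
    expect_equal(nPostings(buildSeedIndex(targets, k)),
                 bruteCount(targets, k))
  }
  expect_warning(buildSeedIndex(c(t1 = "ACG"), k = 23), "empty")
})

test_that("exact substrings and their reverse complements are found", {
  set.seed(21)
  genome <- c(chrA = randomDna(5000))
  idx <- buildSeedIndex(genome, 23)
  q <- substr(genome[["chrA"]], 2001, 2060)
  h <- findUngappedHits(c(r = q), idx)
  h <- h[h$raw_score == max(h$raw_score), ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$identities, 60L)
  expect_equal(h$longest_contiguous, 60L)
  expect_identical(h$strand, "+")
  expect_equal(c(h$t_start, h$t_end), c(2001L, 2060L))

  hrc <- findUngappedHits(c(r = revComp(q)), idx)
  hrc <- hrc[hrc$raw_score == max(hrc$raw_score), ]
  expect_identical(hrc$strand, "-")
  expect_equal(c(hrc$t_start, hrc$t_end), c(2001L, 2060L))
  expect_equal(c(hrc$q_start, hrc$q_end), c(1L, 60L))
})

test_that("planted substitutions reproduce the exhaustive-offset oracle", {
  set.seed(77)
  genome <- c(g = randomDna(3000))
  idx <- buildSeedIndex(genome, 23)
  for (rep in 1:10) {
    off <- sample(1:2900, 1)
    q <- substr(genome[["g"]], off, off + 59)
    q <- mutateAt(q, sample(c(10L, 40L), sample(0:2, 1)))
    if (sample(c(TRUE, FALSE), 1)) q <- revComp(q)
    got <- findUngappedHits(c(r = q), idx)[1, ]
    want <- oracleBestHit(q, as.list(idx@targets))
    expect_equal(got$raw_score, want$score)
    expect_equal(c(got$t_start, got$t_end), c(want$t_start, want$t_end))
    expect_equal(c(got$q_start, got$q_end), c(want$q_start, want$q_end))
    expect_identical(got$strand, want$strand)
  }
})

test_that("strand symmetry: hits of the reverse complement mirror exactly", {
  set.seed(31)
  genome <- c(g1 = randomDna(2000), g2 = randomDna(2000))
  idx <- buildSeedIndex(genome, 23)
  for (rep in 1:5) {
    tgt <- sample(names(genome), 1)
    off <- sample(1:1900, 1)
    q <- mutateAt(substr(genome[[tgt]], off, off + 59), sample(60, 1))
    a <- findUngappedHits(c(r = q), idx)
    b <- findUngappedHits(c(r = revComp(q)), idx)
    expect_equal(nrow(a), nrow(b))
    key <- function(h) {
      L <- h$q_len
      paste(h$target_id, h$t_start, h$t_end,
            ifelse(h$strand == "+", "-", "+"),
            L - h$q_end + 1L, L - h$q_start + 1L, h$raw_score)
    }
    expect_setequal(key(a),
                    paste(b$target_id, b$t_start, b$t_end, b$strand,
                          b$q_start, b$q_end, b$raw_score))
  }
})

test_that("longest contiguous run matches a naive scan", {
  a <- strrep("A", 60)
  expect_equal(longestContiguousRun(a, a), 60L)
  b <- paste0(strrep("A", 30), "C", strrep("A", 29))
  expect_equal(longestContiguousRun(a, b), 30L)   # mismatch at position 31
  expect_equal(longestContiguousRun("AAAA", "CCCC"), 0L)
  expect_error(longestContiguousRun("AA", "AAA"), "equal length")
  set.seed(9)
  for (rep in 1:50) {
    n <- sample(10:80, 1)
    x <- randomDna(n); y <- mutateAt(x, sample(n, sample(0:6, 1)))
    expect_equal(longestContiguousRun(x, y), oracleLongestRun(x, y))
  }
})

test_that("E-values follow the Karlin-Altschul closed form", {
  s <- blastScheme()
  expect_equal(computeEvalue(120, 600, 1e6, s),
               0.711 * 600 * 1e6 * exp(-1.374 * 120))
  # linear in database size, monotone decreasing in score
  expect_equal(computeEvalue(50, 60, 2e5, s),
               2 * computeEvalue(50, 60, 1e5, s))
  expect_gt(computeEvalue(40, 60, 1e5, s), computeEvalue(45, 60, 1e5, s))
  expect_error(computeEvalue(10, 0, 100, s), "positive")
})

test_that("EST alignment ranks by E-value and finds diverged sources", {
  set.seed(13)
  txs <- setNames(vapply(1:6, function(i) randomDna(600), character(1)),
                  paste0("T", 1:6))
  # perfect self-match dominates
  h <- alignEst(c(e1 = txs[["T3"]]), txs)
  expect_identical(h$target_id[1], "T3")
  expect_lt(h$evalue[1], 1e-20)
  expect_equal(h$identities[1], 600L)

  # 5% substitutions still find the source transcript as top hit
  div <- mutateAt(txs[["T5"]], sample(600, 30))
  h2 <- alignEst(c(e2 = div), txs)
  expect_identical(h2$target_id[1], "T5")
  best <- oracleBestHit(div, as.list(txs))
  expect_identical(best$target, "T5")
  expect_equal(h2$raw_score[1], best$score)

  # no shared word, no hits
  expect_equal(nrow(alignEst(c(e3 = randomDna(100)), txs)), 0L)
})

test_that("normalised score divides raw score by query length", {
  expect_equal(normalisedScore(180, 60), 3)
  expect_equal(normalisedScore(0, 600), 0)
  cfg <- pipelineConfig()
  h <- bindHits(makeHit(score = 3 * 600 - 0.5, qLen = 600),
                makeHit(score = 3 * 600, qLen = 600, tStart = 50L))
  kept <- filterEstGdna(h, cfg = cfg)
  expect_equal(nrow(kept), 1L)       # 2.999... fails, 3.0 passes (>= rule)
  expect_equal(kept$raw_score, 1800)
})

test_that("spliced alignment chains planted split reporters", {
  set.seed(41)
  exon1 <- randomDna(200); intron <- randomDna(200); exon2 <- randomDna(200)
  genome <- c(chr = paste0(randomDna(300), exon1, intron, exon2,
                           randomDna(300)))
  q <- paste0(substr(exon1, 171, 200), substr(exon2, 1, 30))
  idx <- buildSeedIndex(genome, 23)
  sp <- splicedAlign(c(r = q), idx)
  top <- sp[1, ]
  expect_equal(top$n_blocks, 2L)
  b <- top$blocks[[1]]
  expect_equal(sum(b[, "q_end"] - b[, "q_start"] + 1L), 60L)  # full coverage
  expect_equal(unname(b[1, "t_start"]), 300L + 171L)
  expect_equal(unname(b[2, "t_start"] - b[1, "t_end"]) - 1L, 200L)  # intron
  expect_equal(top$identities, 60L)

  # a query inside one exon stays single-block and equals the ungapped hit
  q1 <- substr(exon1, 51, 110)
  one <- splicedAlign(c(r = q1), idx, scheme = blastScheme())
  ung <- findUngappedHits(c(r = q1), idx, blastScheme())
  expect_equal(one[, setdiff(colnames(one), "blocks")],
               ung[, setdiff(colnames(ung), "blocks")])
})

test_that("spliced alignment with maxIntron = 0 reduces to ungapped hits", {
  fx <- smallFixture()
  idx <- buildSeedIndex(fx$genome, 23)
  q <- setNames(fx$manifest$sequence[1:8], fx$manifest$reporter_id[1:8])
  a <- splicedAlign(q, idx, scheme = blastScheme(), maxIntron = 0L)
  b <- findUngappedHits(q, idx, blastScheme())
  expect_equal(a[, setdiff(colnames(a), "blocks")],
               b[, setdiff(colnames(b), "blocks")])
})

test_that("blocks on different chromosomes never chain", {
  set.seed(3)
  half1 <- randomDna(30); half2 <- randomDna(30)
  genome <- c(c1 = paste0(randomDna(100), half1, randomDna(100)),
              c2 = paste0(randomDna(100), half2, randomDna(100)))
  sp <- splicedAlign(c(r = paste0(half1, half2)),
                     buildSeedIndex(genome, 23))
  expect_true(all(sp$n_blocks == 1L))
})

test_that("hits agree with reference BLASTN (word size 23, ungapped)", {
  set.seed(59)
  d <- withr::local_tempdir()
  genome <- c(chr1 = randomDna(20000))
  qs <- setNames(vapply(1:6, function(i)
    substr(genome[[1]], i * 3000, i * 3000 + 59), character(1)),
    paste0("r", 1:6))
  qs[2] <- mutateAt(qs[2], c(10L, 40L))
  qs[4] <- revComp(qs[4])
  writeFastaMap(genome, file.path(d, "g.fa"))
  writeFastaMap(qs, file.path(d, "q.fa"))
  status <- system2("blastn",
                    c("-task", "blastn", "-word_size", "23", "-ungapped",
                      "-dust", "no", "-subject", file.path(d, "g.fa"),
                      "-query", file.path(d, "q.fa"), "-outfmt", "6"),
                    stdout = file.path(d, "hits.tsv"),
                    stderr = file.path(d, "err.txt"))
  expect_equal(status, 0L)
  ref <- parseBlastTabular(file.path(d, "hits.tsv"))
  mine <- findUngappedHits(qs, buildSeedIndex(genome, 23))
  for (r in names(qs)) {
    b <- ref[ref$query_id == r, ][1, ]
    m <- mine[mine$query_id == r, ][1, ]
    expect_equal(c(m$t_start, m$t_end), c(b$t_start, b$t_end), info = r)
    expect_identical(m$strand, b$strand, info = r)
    expect_equal(m$identities, b$identities, info = r)
  }
})
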