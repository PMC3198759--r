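#' @include classify.R
NULL

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# gene structure in transcript space: segment k of the transcript maps to
# genomic exon k (plus strand) or exon n-k+1 read backwards (minus strand)
makeGeneDef <- function(spec) {
  nEx <- sample(seq(spec@exonsPerGene[1], spec@exonsPerGene[2]), 1L)
  exLen <- sample(seq(spec@exonLength[1], spec@exonLength[2]), nEx,
                  replace = TRUE)
  inLen <- if (nEx > 1L)
    sample(seq(spec@intronLength[1], spec@intronLength[2]), nEx - 1L,
           replace = TRUE) else integer()
  list(nEx = nEx, exLen = exLen, inLen = inLen,
       span = sum(exLen) + sum(inLen))
}

finishGene <- function(def, geneId, txId, chrom, start, strand) {
  offs <- cumsum(c(0L, head(def$exLen, -1L) + def$inLen))
  exS <- start + offs
  exE <- exS + def$exLen - 1L
  widths <- if (strand == "+") def$exLen else rev(def$exLen)
  segE <- cumsum(widths)
  segS <- segE - widths + 1L
  list(gene_id = geneId, tx_id = txId, chrom = chrom, strand = strand,
       start = start, end = max(exE), exS = exS, exE = exE,
       segS = segS, segE = segE, txLen = sum(widths), nEx = def$nEx)
}

txToGenome <- function(gene, pos) {
  k <- which(pos >= gene$segS & pos <= gene$segE)[1]
  if (is.na(k)) stop("transcript position outside transcript")
  if (gene$strand == "+") gene$exS[k] + (pos - gene$segS[k])
  else gene$exE[gene$nEx - k + 1L] - (pos - gene$segS[k])
}

extractTranscript <- function(genome, gene) {
  parts <- vapply(seq_len(gene$nEx), function(k)
    substr(genome[[gene$chrom]], gene$exS[k], gene$exE[k]), character(1))
  tx <- paste(parts, collapse = "")
  if (gene$strand == "-") revComp(tx) else tx
}

# transcript-space interval -> genomic blocks (ascending starts)
txIntervalToBlocks <- function(gene, a, b) {
  blocks <- NULL
  for (k in seq_len(gene$nEx)) {
    lo <- max(a, gene$segS[k]); hi <- min(b, gene$segE[k])
    if (lo > hi) next
    g1 <- txToGenome(gene, lo); g2 <- txToGenome(gene, hi)
    blocks <- rbind(blocks, c(min(g1, g2), max(g1, g2)))
  }
  blocks[order(blocks[, 1]), , drop = FALSE]
}

modelsFromGenes <- function(genes, cdsTrim = 60L) {
  tx <- GenomicRanges::GRanges(
    vapply(genes, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(genes, `[[`, integer(1), "start"),
                     vapply(genes, `[[`, integer(1), "end")),
    vapply(genes, `[[`, character(1), "strand"))
  S4Vectors::mcols(tx)$transcript_id <-
    vapply(genes, `[[`, character(1), "tx_id")
  S4Vectors::mcols(tx)$gene_id <- vapply(genes, `[[`, character(1), "gene_id")
  exons <- GenomicRanges::GRangesList(lapply(genes, function(g)
    GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$exS, g$exE),
                           g$strand)))
  names(exons) <- S4Vectors::mcols(tx)$transcript_id
  cdsL <- lapply(genes, function(g) {
    if (g$txLen <= 2L * cdsTrim + 10L) return(NULL)
    b <- txIntervalToBlocks(g, cdsTrim + 1L, g$txLen - cdsTrim)
    GenomicRanges::GRanges(g$chrom, IRanges::IRanges(b[, 1], b[, 2]),
                           g$strand)
  })
  keep <- !vapply(cdsL, is.null, logical(1))
  cds <- GenomicRanges::GRangesList(cdsL[keep])
  names(cds) <- S4Vectors::mcols(tx)$transcript_id[keep]
  new("TranscriptModels", transcripts = tx, exons = exons, cds = cds)
}

# a reporter-sized window inside one transcript segment, with margins
pickSegmentWindow <- function(gene, repLen = 60L, margin = 2L) {
  segLen <- gene$segE - gene$segS + 1L
  ok <- which(segLen >= repLen + 2L * margin)
  if (!length(ok)) return(NULL)
  k <- ok[sample.int(length(ok), 1L)]
  a <- gene$segS[k] + margin +
    sample.int(segLen[k] - repLen - 2L * margin + 1L, 1L) - 1L
  c(a, a + repLen - 1L)
}

#' Generate a deterministic synthetic fixture with planted truth
#'
#' Builds a random genome, non-overlapping multi-exon gene models, their
#' transcripts, reporters planted so that each belongs to a known
#' annotation group, source ESTs, and the truth table:
#' sense reporters are excised from an exon of a transcript; antisense
#' reporters are the reverse complement of such an excision; gDNA
#' reporters come from intergenic sequence; EST-group reporters have their
#' genomic footprint mutated beyond both retention rules (contiguity and
#' identity) while their EST keeps the pre-mutation sequence; ambiguous
#' reporters sit in a gene duplicated at a second annotated locus (at most
#' two substitutions, outside the reporter footprint); inconclusive
#' reporters are random sequence sharing no seed word with the genome;
#' intron-spanning sense reporters cover an exon junction 30 bp + 30 bp.
#' Generation is byte-deterministic under the spec seed, and the EST
#' plantings are verified post hoc to defeat the retention envelope.
#'
#' @param spec a [FixtureSpec-class].
#' @param dir optional output directory; when given, writes `genome.fa`,
#'   `transcripts.fa`, `ests.fa`, `spans.gff3`, `manifest.tsv`,
#'   `truth.tsv` and returns their paths in `$paths`.
#' @param cfg a [PipelineConfig-class] (used for the post-generation
#'   self-checks).
#' @return list with `genome`, `transcripts`, `ests` (named character
#'   vectors), `models` ([TranscriptModels-class]), `manifest`, `truth`
#'   (data.frames), and optionally `paths`.
#' @export
generateFixture <- function(spec = fixtureSpec(), dir = NULL,
                            cfg = pipelineConfig()) {
  methods::validObject(spec)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec@seed)

  nG <- spec@nPerGroup
  roles <- c(rep("sense", nG[["sense_gene_model"]]),
             rep("antisense", nG[["antisense_gene_model"]]),
             rep("est", nG[["est"]]),
             rep("intron", spec@nIntronSpanning),
             rep("amb", nG[["ambiguous"]]))

  # gene definitions; ambiguous plantings need a duplicate locus with the
  # same structure
  defs <- list(); geneRole <- character(); pairOf <- integer()
  for (r in roles) {
    d <- makeGeneDef(spec)
    defs[[length(defs) + 1L]] <- d
    geneRole <- c(geneRole, r)
    pairOf <- c(pairOf, NA_integer_)
    if (r == "amb") {
      defs[[length(defs) + 1L]] <- d
      geneRole <- c(geneRole, "amb_copy")
      pairOf <- c(pairOf, length(defs) - 1L)
    }
  }
  # a few unprobed genes so not every model carries a reporter
  for (i in seq_len(3L)) {
    defs[[length(defs) + 1L]] <- makeGeneDef(spec)
    geneRole <- c(geneRole, "spare")
    pairOf <- c(pairOf, NA_integer_)
  }

  # sequential layout, round-robin over chromosomes
  chroms <- sprintf("chr%d", seq_len(spec@nChromosomes))
  cursor <- setNames(rep(501L, spec@nChromosomes), chroms)
  genes <- vector("list", length(defs))
  gaps <- list()
  ord <- sample.int(length(defs))
  ci <- 0L
  for (i in ord) {
    placed <- FALSE
    for (try in seq_along(chroms)) {
      ci <- ci %% length(chroms) + 1L
      ch <- chroms[ci]
      gap <- sample(300:1500, 1L)
      start <- cursor[[ch]] + gap
      if (start + defs[[i]]$span + 500L <= spec@chromLength) {
        gaps[[length(gaps) + 1L]] <-
          list(chrom = ch, lo = cursor[[ch]] + 1L, hi = start - 1L)
        genes[[i]] <- finishGene(
          defs[[i]], sprintf("G%04d", i), sprintf("G%04d_T01", i),
          ch, start, sample(c("+", "-"), 1L))
        cursor[[ch]] <- genes[[i]]$end
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("fixture spec infeasible: chromosomes too short for the ",
           "requested gene load")
  }
  for (ch in chroms)  # chromosome tails are intergenic too
    gaps[[length(gaps) + 1L]] <-
      list(chrom = ch, lo = cursor[[ch]] + 1L, hi = spec@chromLength - 200L)

  genome <- setNames(lapply(seq_along(chroms), function(i)
    randSeq(spec@chromLength)), chroms)

  # duplicate loci for ambiguous plantings (copy before any reporter is
  # excised; <=2 substitutions are applied outside the reporter footprint
  # once the footprint is chosen)
  for (i in which(geneRole == "amb_copy")) {
    src <- genes[[pairOf[i]]]; dst <- genes[[i]]
    seqA <- substr(genome[[src$chrom]], src$start, src$end)
    substr(genome[[dst$chrom]], dst$start, dst$end) <- seqA
  }

  manifest <- data.frame(reporter_id = character(), sequence = character(),
                         est_accession = character(),
                         stringsAsFactors = FALSE)
  truth <- data.frame(reporter_id = character(), planted_group = character(),
                      gene_id = character(), intron_spanning = logical(),
                      notes = character(), stringsAsFactors = FALSE)
  ests <- character()
  ridN <- 0L
  nextRid <- function() { ridN <<- ridN + 1L; sprintf("R_%04d", ridN) }
  addReporter <- function(rid, seq, acc, group, gene, intron, note) {
    manifest[nrow(manifest) + 1L, ] <<- list(rid, seq, acc)
    truth[nrow(truth) + 1L, ] <<- list(rid, group, gene, intron, note)
  }

  estWindow <- function(txSeq, a, b) {
    # EST of the configured length around the reporter window
    half <- (spec@estLength - (b - a + 1L)) %/% 2L
    lo <- max(1L, a - half)
    hi <- min(nchar(txSeq), lo + spec@estLength - 1L)
    lo <- max(1L, hi - spec@estLength + 1L)
    substr(txSeq, lo, hi)
  }

  byRole <- split(seq_along(genes), geneRole)

  # sense (with source ESTs) -----------------------------------------------
  senseIdx <- byRole$sense
  nMis <- round(spec@misorientedEstFraction * length(senseIdx))
  misoriented <- if (length(senseIdx))
    seq_along(senseIdx) <= nMis else integer()
  for (m in seq_along(senseIdx)) {
    g <- genes[[senseIdx[m]]]
    tx <- extractTranscript(genome, g)
    w <- pickSegmentWindow(g)
    if (is.null(w)) stop("fixture spec infeasible: exon too short for a ",
                         "reporter window")
    rid <- nextRid()
    acc <- paste0("EST_", rid)
    est <- estWindow(tx, w[1], w[2])
    if (isTRUE(misoriented[m])) est <- revComp(est)
    ests[[acc]] <- est
    addReporter(rid, substr(tx, w[1], w[2]), acc, "sense_gene_model",
                g$gene_id, FALSE,
                if (isTRUE(misoriented[m])) "misoriented_est" else "")
  }

  # antisense ---------------------------------------------------------------
  for (i in byRole$antisense) {
    g <- genes[[i]]
    tx <- extractTranscript(genome, g)
    w <- pickSegmentWindow(g)
    rid <- nextRid()
    addReporter(rid, revComp(substr(tx, w[1], w[2])), NA_character_,
                "antisense_gene_model", g$gene_id, FALSE, "")
  }

  # intron-spanning sense ----------------------------------------------------
  for (i in byRole$intron) {
    g <- genes[[i]]
    tx <- extractTranscript(genome, g)
    j <- sample.int(g$nEx - 1L, 1L)      # junction after segment j
    a <- g$segE[j] - 29L
    rid <- nextRid()
    addReporter(rid, substr(tx, a, a + 59L), NA_character_,
                "sense_gene_model", g$gene_id, TRUE, "intron_spanning")
  }

  # EST group: mutate the genomic footprint beyond the retention envelope ---
  for (i in byRole$est) {
    g <- genes[[i]]
    txPre <- extractTranscript(genome, g)
    w <- pickSegmentWindow(g)
    rid <- nextRid()
    acc <- paste0("EST_", rid)
    ests[[acc]] <- estWindow(txPre, w[1], w[2])
    reporter <- substr(txPre, w[1], w[2])
    gpos <- sort(c(txToGenome(g, w[1]), txToGenome(g, w[2])))
    nSub <- max(6L, ceiling(60L * spec@estDivergence))
    offs <- unique(round(seq(5, 56, length.out = nSub)))
    for (o in offs) {
      p <- gpos[1] + o - 1L
      cur <- substr(genome[[g$chrom]], p, p)
      substr(genome[[g$chrom]], p, p) <-
        sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
    addReporter(rid, reporter, acc, "est", g$gene_id, FALSE,
                sprintf("footprint_mutated_%dx", length(offs)))
  }

  # ambiguous: reporter from gene A, duplicate locus B annotated too --------
  for (i in byRole$amb) {
    g <- genes[[i]]
    copyIdx <- which(pairOf == i)
    gB <- genes[[copyIdx]]
    tx <- extractTranscript(genome, g)
    w <- pickSegmentWindow(g)
    rid <- nextRid()
    reporter <- substr(tx, w[1], w[2])
    # up to 2 substitutions in the copy, outside the reporter footprint
    fpLo <- min(txToGenome(g, w[1]), txToGenome(g, w[2])) - g$start
    fpHi <- max(txToGenome(g, w[1]), txToGenome(g, w[2])) - g$start
    cand <- setdiff(seq(0L, g$end - g$start), seq(fpLo, fpHi))
    for (o in sample(cand, 2L)) {
      p <- gB$start + o
      cur <- substr(genome[[gB$chrom]], p, p)
      substr(genome[[gB$chrom]], p, p) <-
        sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
    addReporter(rid, reporter, NA_character_, "ambiguous",
                paste(sort(c(g$gene_id, gB$gene_id)), collapse = ","),
                FALSE, "duplicated_locus")
  }

  # gDNA: unique intergenic windows ------------------------------------------
  wide <- Filter(function(x) x$hi - x$lo + 1L >= 300L, gaps)
  if (length(wide) < nG[["gdna"]])
    stop("fixture spec infeasible: not enough intergenic room for gDNA ",
         "reporters")
  for (gap in wide[sample.int(length(wide), nG[["gdna"]])]) {
    lo <- gap$lo + 120L
    a <- lo + sample.int(max(1L, gap$hi - 120L - 60L - lo + 1L), 1L) - 1L
    rid <- nextRid()
    addReporter(rid, substr(genome[[gap$chrom]], a, a + 59L), NA_character_,
                "gdna", NA_character_, FALSE, "intergenic")
  }

  # inconclusive: random 60-mers sharing no seed word with the genome -------
  nInc <- nG[["inconclusive"]]
  incSeqs <- vapply(seq_len(nInc), function(i) randSeq(60L), character(1))
  gIdx <- buildSeedIndex(setNames(unlist(genome), chroms), cfg@wordSize)
  for (round in seq_len(10L)) {
    if (!length(incSeqs)) break
    h <- findUngappedHits(setNames(incSeqs,
                                   sprintf("tmp%d", seq_along(incSeqs))),
                          gIdx)
    bad <- unique(as.integer(sub("tmp", "", h$query_id)))
    if (!length(bad)) break
    incSeqs[bad] <- vapply(bad, function(i) randSeq(60L), character(1))
    if (round == 10L) stop("could not generate hit-free reporters")
  }
  for (s in incSeqs)
    addReporter(nextRid(), s, NA_character_, "inconclusive", NA_character_,
                FALSE, "random_sequence")

  genome <- setNames(vapply(genome, identity, character(1)), chroms)
  transcripts <- setNames(
    vapply(genes, function(g) extractTranscript(as.list(genome), g),
           character(1)),
    vapply(genes, `[[`, character(1), "tx_id"))
  models <- modelsFromGenes(genes)

  # self-check: EST plantings must defeat both retention rules --------------
  estRows <- which(truth$planted_group == "est")
  for (r in estRows) {
    g <- genes[[byRole$est[match(r, estRows)]]]
    txMut <- transcripts[[g$tx_id]]
    rep <- manifest$sequence[r]
    best <- 0L; bestId <- 0L
    for (off in seq_len(nchar(txMut) - 59L)) {
      win <- substr(txMut, off, off + 59L)
      idn <- sum(utf8ToInt(win) == utf8ToInt(rep))
      if (idn > bestId) {
        bestId <- idn
        best <- longestContiguousRun(win, rep)
      }
    }
    if (best >= cfg@minContiguous ||
        bestId >= cfg@multiHitMinIdentity)
      stop("EST planting failed to defeat the retention envelope (",
           manifest$reporter_id[r], ")")
  }

  out <- list(genome = genome, transcripts = transcripts,
              ests = unlist(ests) %||% setNames(character(), character()),
              models = models, manifest = manifest, truth = truth,
              spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      transcripts = file.path(dir, "transcripts.fa"),
      ests = file.path(dir, "ests.fa"),
      spans = file.path(dir, "spans.gff3"),
      manifest = file.path(dir, "manifest.tsv"),
      truth = file.path(dir, "truth.tsv"))
    writeFastaMap(out$genome, paths$genome)
    writeFastaMap(out$transcripts, paths$transcripts)
    writeFastaMap(out$ests, paths$ests)
    writeTranscriptSpans(models, paths$spans)
    write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    out$paths <- paths
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Generate a synthetic expression matrix with planted silent reporters
#'
#' Signal is noise times a per-(reporter, array) ratio; a configurable
#' fraction of reporters is forced below the SNR threshold on every array
#' (their planted flag is FALSE), while every other reporter gets at least
#' one array with SNR comfortably above it.
#'
#' @param manifest reporter manifest data.frame.
#' @param nArrays number of arrays (default 50, the usual leaf-panel size).
#' @param silentFraction fraction of reporters planted silent.
#' @param seed RNG seed.
#' @param dir optional output directory for `expression.tsv` and
#'   `expression_truth.tsv`.
#' @return list with `se` (`SummarizedExperiment`), `truth` (data.frame
#'   `reporter_id`, `expressed`), and optionally `paths`.
#' @export
generateExpression <- function(manifest, nArrays = 50L,
                               silentFraction = 0.25, seed = 1L,
                               dir = NULL) {
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  ids <- manifest$reporter_id
  n <- length(ids)
  nSilent <- as.integer(round(silentFraction * n))
  silent <- sample(ids, nSilent)
  noise <- matrix(runif(n * nArrays, 20, 80), n, nArrays,
                  dimnames = list(ids, sprintf("array%02d", seq_len(nArrays))))
  ratio <- matrix(runif(n * nArrays, 0.2, 2.9), n, nArrays)
  expressed <- !(ids %in% silent)
  for (i in which(expressed)) {
    ratio[i, ] <- runif(nArrays, 0.5, 8)
    ratio[i, sample.int(nArrays, 1L)] <- runif(1, 3.5, 9)
  }
  signal <- round(noise * ratio, 3)
  noise <- round(noise, 3)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = signal, noise = noise))
  truth <- data.frame(reporter_id = ids, expressed = expressed,
                      stringsAsFactors = FALSE)
  out <- list(se = se, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(expression = file.path(dir, "expression.tsv"),
                  truth = file.path(dir, "expression_truth.tsv"))
    writeExpressionMatrix(se, paths$expression)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}
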