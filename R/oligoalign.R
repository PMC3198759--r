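#' @include hits.R
NULL

# ---- index ----------------------------------------------------------------

#' Build an exact k-mer seed index over target sequences
#'
#' @param targets named character vector or `DNAStringSet` of target
#'   sequences (forward strand); sequences are uppercased.
#' @param k integer word size (default 23, the hybridization-stringency
#'   word size used for all reporter searches).
#' @return A [SeedIndex-class] object.
#' @examples
#' idx <- buildSeedIndex(c(t1 = "ACGTACGT"), k = 4)
#' nPostings(idx)
#' @export
buildSeedIndex <- function(targets, k = 23L) {
  if (methods::is(targets, "DNAStringSet"))
    targets <- setNames(as.character(targets), names(targets))
  stopifnot(is.character(targets), length(targets) > 0L)
  if (is.null(names(targets)))
    stop("targets must be named")
  targets <- toupper(targets)
  if (all(nchar(targets) < k))
    warning("k exceeds every target length; index is empty")
  new("SeedIndex", k = as.integer(k), targets = targets)
}

# shared C++ entry: queries may be one or many; returns canonical hit frame
seedExtendRaw <- function(query, targets, k, scheme, targetKind) {
  if (methods::is(query, "DNAStringSet"))
    query <- setNames(as.character(query), names(query))
  if (is.null(names(query))) {
    if (length(query) > 1L) stop("multiple queries must be named")
    names(query) <- "query"
  }
  query <- toupper(query)
  raw <- cpp_seed_extend(unname(query), names(query),
                         unname(targets), names(targets),
                         as.integer(k), scheme@match, scheme@mismatch, TRUE)
  hits <- asHits(raw, targetKind)
  hits <- hits[order(hits$query_id, -hits$raw_score, hits$target_id,
                     hits$t_start, hits$strand != "+"), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Ungapped seed-and-extend search of short queries against an index
#'
#' Searches both query strands (the reverse-complemented query is matched
#' against the forward index for minus-strand hits).  Every seed is
#' extended without gaps to the maximal-scoring local alignment on its
#' diagonal; at most one hit is reported per (target, diagonal, strand).
#' Each hit carries identities, alignment length, the longest run of
#' contiguous matches, and `raw_score = match * identities +
#' mismatch * (aln_length - identities)`.
#'
#' @param query named character vector (or `DNAStringSet`) of queries.
#' @param index a [SeedIndex-class].
#' @param scheme a [ScoringScheme-class]; default [blastScheme()].
#' @return A hit data.frame (see [emptyHits()]); empty when nothing seeds.
#' @examples
#' idx <- buildSeedIndex(c(chr = strrep("ACGT", 50)), k = 11)
#' findUngappedHits(c(r1 = strrep("ACGT", 8)), idx)[1, 1:8]
#' @export
findUngappedHits <- function(query, index, scheme = blastScheme()) {
  stopifnot(methods::is(index, "SeedIndex"),
            methods::is(scheme, "ScoringScheme"))
  seedExtendRaw(query, index@targets, index@k, scheme, "gDNA")
}

# ---- run lengths ----------------------------------------------------------

#' Longest run of contiguous identical positions in an ungapped alignment
#'
#' @param queryAln,targetAln equal-length aligned strings (no gap
#'   characters; reporter alignments are ungapped by construction).
#' @return integer, the longest run of positions where the two strings
#'   agree (0 when they never agree).
#' @examples
#' longestContiguousRun("ACGTACGT", "ACGAACGT")
#' @export
longestContiguousRun <- function(queryAln, targetAln) {
  if (nchar(queryAln) != nchar(targetAln))
    stop("aligned strings must have equal length")
  if (nchar(queryAln) == 0L) return(0L)
  eq <- utf8ToInt(toupper(queryAln)) == utf8ToInt(toupper(targetAln))
  if (!any(eq)) return(0L)
  r <- rle(eq)
  as.integer(max(r$lengths[r$values]))
}

# ---- E-values -------------------------------------------------------------

#' Karlin-Altschul E-value for an ungapped local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: strictly decreasing in the score and
#' linear in the search-space product, emulating the E-values that BLASTN
#' reports for EST searches.
#'
#' @param rawScore numeric alignment score(s).
#' @param queryLen,dbLen positive integer query length and total database
#'   length.
#' @param scheme a [ScoringScheme-class] carrying `karlinLambda`, `karlinK`.
#' @return numeric E-value(s).
#' @examples
#' computeEvalue(120, 600, 1e6)
#' @export
computeEvalue <- function(rawScore, queryLen, dbLen, scheme = blastScheme()) {
  if (any(queryLen <= 0) || any(dbLen <= 0))
    stop("queryLen and dbLen must be positive")
  stopifnot(all(is.finite(rawScore)))
  scheme@karlinK * as.numeric(queryLen) * as.numeric(dbLen) *
    exp(-scheme@karlinLambda * rawScore)
}

#' Align EST-length queries against a transcript set, with E-values
#'
#' Same seed-and-extend core as [findUngappedHits()], but hits carry
#' Karlin-Altschul E-values (database size = total target length) and are
#' sorted by ascending E-value within each query, the ordering the EST
#' retention rules consume.
#'
#' @param query named character vector / `DNAStringSet` of EST sequences.
#' @param targets named character vector / `DNAStringSet`, or a
#'   [SeedIndex-class], of transcript sequences.
#' @param scheme a [ScoringScheme-class]; default [blastScheme()].
#' @param k integer word size when `targets` is not already an index.
#' @return hit data.frame with the `evalue` column populated,
#'   `target_kind = "transcript"`.
#' @export
alignEst <- function(query, targets, scheme = blastScheme(), k = 23L) {
  if (!methods::is(targets, "SeedIndex"))
    targets <- buildSeedIndex(targets, k)
  hits <- seedExtendRaw(query, targets@targets, targets@k, scheme,
                        "transcript")
  if (nrow(hits)) {
    dbLen <- sum(nchar(targets@targets))
    hits$evalue <- computeEvalue(hits$raw_score, hits$q_len, dbLen, scheme)
    hits <- hits[order(hits$query_id, hits$evalue, hits$target_id,
                       hits$t_start, hits$strand != "+"), , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Normalised spliced-alignment score
#'
#' The spliced-alignment retention statistic: raw alignment score divided
#' by the query length.  EST-to-genome matches are retained when this is at
#' least the configured minimum (default 3).
#'
#' @param hit a hit data.frame (or numeric raw scores).
#' @param queryLen query length(s); defaults to the hits' `q_len` column.
#' @return numeric vector of normalised scores.
#' @examples
#' normalisedScore(180, 60)
#' @export
normalisedScore <- function(hit, queryLen = NULL) {
  score <- if (is.data.frame(hit)) hit$raw_score else as.numeric(hit)
  if (is.null(queryLen)) {
    stopifnot(is.data.frame(hit))
    queryLen <- hit$q_len
  }
  if (any(queryLen <= 0)) stop("queryLen must be positive")
  score / as.numeric(queryLen)
}

# ---- spliced alignment ----------------------------------------------------

# per-block identity/run/score recompute in the alignment frame
# (strand-adjusted query qsv vs target tsv, both integer vectors; D such
# that target position = query position + D, 1-based)
blockFrameStats <- function(qsv, tsv, a, b, D, scheme) {
  eq <- qsv[a:b] == tsv[(a:b) + D]
  idn <- sum(eq)
  run <- if (idn == 0L) 0L else {
    r <- rle(eq); as.integer(max(r$lengths[r$values]))
  }
  list(identities = as.integer(idn), aln = as.integer(b - a + 1L),
       run = run,
       score = scheme@match * idn + scheme@mismatch * (b - a + 1L - idn))
}

# chain candidate blocks of one (query, target, strand) in the alignment
# frame; returns list(chain = indices-with-trims or NULL, ...)
chainBlocks <- function(blk, qsv, tsv, scheme, minIntron, maxIntron,
                        maxQGap = 10L, maxTrim = 120L) {
  n <- nrow(blk)
  items <- lapply(seq_len(n), function(i) {
    as.list(blk[i, c("qs_f", "qe_f", "ts", "te", "score")])
  })
  ord <- order(blk$qs_f, blk$ts)
  dp <- vector("list", n)       # each: list(score, blocks = list(items))
  for (oi in seq_along(ord)) {
    i <- ord[oi]
    bi <- items[[i]]
    dp[[i]] <- list(score = bi$score, blocks = list(bi))
    if (oi == 1L) next
    for (oj in seq_len(oi - 1L)) {
      j <- ord[oj]
      last <- dp[[j]]$blocks[[length(dp[[j]]$blocks)]]
      v <- last$qe_f - bi$qs_f + 1L          # query overlap (if > 0)
      cands <- list()
      if (v <= 0L) {
        qgap <- -v                            # unaligned query bases
        if (qgap <= maxQGap) cands <- list(list(last = last, cur = bi))
      } else if (v <= maxTrim) {
        # trim the overlap from either side; trimming the upstream block's
        # tail is tried first so that score ties resolve toward clean
        # downstream block starts (tail extensions into the intron are the
        # usual cause of the overlap)
        if ((last$qe_f - v) - last$qs_f + 1L >= 1L) {
          b2 <- last$qe_f - v
          D2 <- last$ts - last$qs_f
          st2 <- blockFrameStats(qsv, tsv, last$qs_f, b2, D2, scheme)
          cands <- c(cands, list(list(
            last = list(qs_f = last$qs_f, qe_f = b2, ts = last$ts,
                        te = b2 + D2, score = st2$score),
            cur = bi)))
        }
        if (bi$qe_f - (bi$qs_f + v) + 1L >= 1L) {
          a <- bi$qs_f + v
          D <- bi$ts - bi$qs_f
          st <- blockFrameStats(qsv, tsv, a, bi$qe_f, D, scheme)
          cands <- c(cands, list(list(
            last = last,
            cur = list(qs_f = a, qe_f = bi$qe_f, ts = a + D, te = bi$te,
                       score = st$score))))
        }
      }
      for (cand in cands) {
        tgap <- cand$cur$ts - cand$last$te - 1L
        if (tgap < minIntron || tgap > maxIntron) next
        if (cand$cur$score <= 0 || cand$last$score <= 0) next
        newScore <- dp[[j]]$score - last$score + cand$last$score +
          cand$cur$score
        if (newScore > dp[[i]]$score) {
          blocks <- dp[[j]]$blocks
          blocks[[length(blocks)]] <- cand$last
          blocks[[length(blocks) + 1L]] <- cand$cur
          dp[[i]] <- list(score = newScore, blocks = blocks)
        }
      }
    }
  }
  best <- which.max(vapply(dp, `[[`, numeric(1), "score"))
  dp[[best]]
}

#' Spliced (intron-aware) alignment of queries against genomic targets
#'
#' Ungapped diagonal blocks from the seed-and-extend core are chained into
#' spliced alignments: consecutive blocks must be (near-)adjacent and
#' disjoint on the query, separated on the target by a gap inside the
#' intron bracket, and chaining must increase the total score.  The best
#' chain per (target, strand) is reported alongside the unchained blocks;
#' with `maxIntron = 0` no chain is possible and the output reduces to the
#' ungapped hits.  Default scoring is [exonerateScheme()] (+5/-4), under
#' which the normalised-score retention filter operates.
#'
#' @param query named character vector / `DNAStringSet` of queries.
#' @param index a [SeedIndex-class] over the genomic targets (or a named
#'   character vector, indexed at `k`).
#' @param scheme a [ScoringScheme-class]; default [exonerateScheme()].
#' @param maxIntron,minIntron integer target-gap bracket for chaining.
#' @param k integer word size when `index` is not already an index.
#' @return hit data.frame; spliced hits have `n_blocks > 1` and a `blocks`
#'   matrix ordered by query position.
#' @export
splicedAlign <- function(query, index, scheme = exonerateScheme(),
                         maxIntron = 50000L, minIntron = 20L, k = 23L) {
  if (!methods::is(index, "SeedIndex")) index <- buildSeedIndex(index, k)
  stopifnot(maxIntron >= 0L)
  hits <- seedExtendRaw(query, index@targets, index@k, scheme, "gDNA")
  if (nrow(hits) == 0L) return(hits)
  if (methods::is(query, "DNAStringSet"))
    query <- setNames(as.character(query), names(query))
  if (is.null(names(query))) names(query) <- "query"
  query <- toupper(query)

  tsvCache <- new.env(parent = emptyenv())
  targetInts <- function(id) {
    if (is.null(tsvCache[[id]]))
      tsvCache[[id]] <- utf8ToInt(index@targets[[id]])
    tsvCache[[id]]
  }

  out <- list()
  key <- paste(hits$query_id, hits$target_id, hits$strand, sep = "\r")
  for (grp in split(seq_len(nrow(hits)), key)) {
    sub <- hits[grp, , drop = FALSE]
    qid <- sub$query_id[1]; tid <- sub$target_id[1]; std <- sub$strand[1]
    L <- sub$q_len[1]
    if (nrow(sub) == 1L || maxIntron < minIntron) {
      out[[length(out) + 1L]] <- sub
      next
    }
    # alignment-frame query coordinates (monotone with target position)
    if (std == "+") {
      qs_f <- sub$q_start; qe_f <- sub$q_end
      qsv <- utf8ToInt(query[[qid]])
    } else {
      qs_f <- L - sub$q_end + 1L; qe_f <- L - sub$q_start + 1L
      qsv <- utf8ToInt(revComp(query[[qid]]))
    }
    blk <- data.frame(qs_f = qs_f, qe_f = qe_f, ts = sub$t_start,
                      te = sub$t_end, score = sub$raw_score)
    chain <- chainBlocks(blk, qsv, targetInts(tid), scheme,
                         minIntron, maxIntron)
    if (length(chain$blocks) < 2L ||
        chain$score <= max(sub$raw_score)) {
      out[[length(out) + 1L]] <- sub
      next
    }
    # which original blocks joined the chain (by target start proximity)
    used <- vapply(chain$blocks, function(b) {
      which.min(abs(blk$ts - b$ts))
    }, integer(1))
    stats <- lapply(chain$blocks, function(b) {
      blockFrameStats(qsv, targetInts(tid), b$qs_f, b$qe_f,
                      b$ts - b$qs_f, scheme)
    })
    bm <- do.call(rbind, lapply(chain$blocks, function(b) {
      if (std == "+")
        cbind(q_start = b$qs_f, q_end = b$qe_f,
              t_start = b$ts, t_end = b$te)
      else
        cbind(q_start = L - b$qe_f + 1L, q_end = L - b$qs_f + 1L,
              t_start = b$ts, t_end = b$te)
    }))
    bm <- bm[order(bm[, "q_start"]), , drop = FALSE]
    chained <- sub[1, , drop = FALSE]
    chained$q_start <- min(bm[, "q_start"]); chained$q_end <- max(bm[, "q_end"])
    chained$t_start <- min(bm[, "t_start"]); chained$t_end <- max(bm[, "t_end"])
    chained$identities <- sum(vapply(stats, `[[`, integer(1), "identities"))
    chained$aln_length <- sum(vapply(stats, `[[`, integer(1), "aln"))
    chained$longest_contiguous <-
      max(vapply(stats, `[[`, integer(1), "run"))
    chained$n_blocks <- length(chain$blocks)
    chained$raw_score <- chain$score
    chained$blocks <- list(bm)
    out[[length(out) + 1L]] <-
      rbind(chained, sub[-used, , drop = FALSE])
  }
  res <- do.call(rbind, out)
  res <- res[order(res$query_id, -res$raw_score, res$target_id,
                   res$t_start, res$strand != "+"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# ---- rescoring imported hits ----------------------------------------------

#' Recompute identity statistics of imported hits from sequences
#'
#' BLAST tabular files do not carry the longest-contiguous-run statistic;
#' imported hits therefore get it (and missing identity counts and query
#' lengths) recomputed from the actual sequences over the stated ungapped
#' interval rather than guessed from percent identity.
#'
#' @param hits hit data.frame (e.g. from [parseBlastTabular()]).
#' @param queries,targets named character vectors of the query and target
#'   sequences the hits refer to.
#' @return the hit data.frame with `q_len`, `identities` and
#'   `longest_contiguous` filled in.
#' @export
rescoreHits <- function(hits, queries, targets) {
  if (nrow(hits) == 0L) return(hits)
  queries <- toupper(queries); targets <- toupper(targets)
  for (i in seq_len(nrow(hits))) {
    q <- queries[[hits$query_id[i]]]
    t <- targets[[hits$target_id[i]]]
    if (is.null(q) || is.null(t))
      stop("sequence missing for hit ", hits$query_id[i], " -> ",
           hits$target_id[i])
    hits$q_len[i] <- nchar(q)
    b <- hits$blocks[[i]]
    idn <- 0L; aln <- 0L; run <- 0L
    for (j in seq_len(nrow(b))) {
      if (b[j, "q_end"] - b[j, "q_start"] != b[j, "t_end"] - b[j, "t_start"])
        stop("gapped alignment block cannot be rescored ungapped (hit ",
             hits$query_id[i], " -> ", hits$target_id[i], ")")
      qsub <- substr(q, b[j, "q_start"], b[j, "q_end"])
      if (hits$strand[i] == "-") qsub <- revComp(qsub)
      tsub <- substr(t, b[j, "t_start"], b[j, "t_end"])
      idn <- idn + as.integer(sum(utf8ToInt(qsub) == utf8ToInt(tsub)))
      aln <- aln + nchar(qsub)
      run <- max(run, longestContiguousRun(qsub, tsub))
    }
    hits$identities[i] <- idn
    hits$aln_length[i] <- aln
    hits$longest_contiguous[i] <- run
  }
  hits
}
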