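# Independent reference implementations ("oracles") used to validate the
# package's fast paths.  They share no code with the implementation: the
# aligner oracle scores the query at every offset of the target, the run
# oracle is an explicit scan, the filter oracles are row predicates, and
# the classification oracle is a directly transcribed decision table.

oracleRevComp <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# maximal-scoring local interval on one diagonal; deterministic choice:
# the first interval (smallest end) attaining the maximal score, with the
# start at the first prefix minimum — the convention the whole package
# uses for ungapped extension
oracleDiagonalBest <- function(s) {
  cs <- cumsum(s)
  base <- cummin(c(0, cs[-length(cs)]))
  cur <- cs - base
  best <- max(cur)
  if (best <= 0) return(NULL)
  e <- which.max(cur)
  m <- base[e]
  b <- if (m == 0) 1L else which(cs[seq_len(e - 1L)] == m)[1] + 1L
  list(start = b, end = e, score = best)
}

# exhaustive both-strand, every-offset scoring of query against target;
# returns the best hit under the package-wide tie-break (score, then
# target order as supplied, then t_start, then + strand)
oracleBestHit <- function(query, targets, match = 1, mismatch = -3) {
  best <- NULL
  consider <- function(cand) {
    if (is.null(cand)) return()
    if (is.null(best) || cand$score > best$score) best <<- cand
  }
  for (std in c("+", "-")) {
    qs <- if (std == "+") query else oracleRevComp(query)
    qv <- utf8ToInt(qs)
    L <- length(qv)
    for (tn in names(targets)) {
      tv <- utf8ToInt(targets[[tn]])
      Tn <- length(tv)
      for (d in (-(L - 1L)):(Tn - 1L)) {
        lo <- max(1L, 1L - d)
        hi <- min(L, Tn - d)
        if (lo > hi) next
        i <- lo:hi
        s <- ifelse(qv[i] == tv[i + d], match, mismatch)
        r <- oracleDiagonalBest(s)
        if (is.null(r)) next
        b <- lo + r$start - 1L; e <- lo + r$end - 1L
        qsp <- if (std == "+") c(b, e) else c(L - e + 1L, L - b + 1L)
        consider(list(score = r$score, target = tn, strand = std,
                      t_start = b + d, t_end = e + d,
                      q_start = qsp[1], q_end = qsp[2]))
      }
    }
  }
  best
}

# explicit left-to-right scan for the longest run of equal characters
oracleLongestRun <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0L; run <- 0L
  for (i in seq_along(av)) {
    if (av[i] == bv[i]) {
      run <- run + 1L
      if (run > best) best <- run
    } else run <- 0L
  }
  best
}

# row-predicate re-statement of the reporter retention rule
oracleFilterReporter <- function(hits, cfg) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(-hits$raw_score, hits$target_id, hits$t_start,
             hits$strand != "+")
  hits <- hits[o, , drop = FALSE]
  minC <- minContiguous(cfg)
  scaled <- function(qlen) 55 / 60 * qlen
  keep <- logical(nrow(hits))
  if (hits$longest_contiguous[1] >= minC) {
    keep[1] <- TRUE
    for (i in seq_len(nrow(hits))[-1])
      keep[i] <- hits$longest_contiguous[i] >= minC &&
        hits$identities[i] >= scaled(hits$q_len[i])
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracleFilterEst <- function(hits, topE = 1e-10, multiE = 1e-20) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$evalue, hits$target_id, hits$t_start,
                     hits$strand != "+"), , drop = FALSE]
  keep <- logical(nrow(hits))
  if (hits$evalue[1] <= topE) {
    keep[1] <- TRUE
    keep[-1] <- hits$evalue[-1] <= multiE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracleFilterEstGdna <- function(hits, minNorm = 3) {
  out <- hits[hits$raw_score / hits$q_len >= minNorm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# directly transcribed five-branch decision table over evidence summaries
oracleGroup <- function(nRepAgr, repOrientation, nEstAgr, nGdna, nWgs,
                        estCorroborated = TRUE,
                        nGenesAll = max(nRepAgr, 0) + max(nEstAgr, 0)) {
  if (nGenesAll > 1L) return("ambiguous")
  if (nRepAgr == 1L)
    return(if (repOrientation == "sense") "sense_gene_model"
           else "antisense_gene_model")
  if (nEstAgr == 1L && nWgs == 0L)
    return(if (nGdna == 0L || estCorroborated) "est" else "inconclusive")
  if (nEstAgr == 0L && nGdna == 1L && nWgs == 0L) return("gdna")
  "inconclusive"
}
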