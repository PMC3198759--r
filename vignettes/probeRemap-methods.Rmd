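---
title: "Re-annotating oligo array reporters against a genome: methods and design"
author: "probeRemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-annotating oligo array reporters against a genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probeRemap)
```

## The problem

Long-oligo expression arrays are often designed from EST collections years
before a usable genome assembly exists.  Once a reference genome and a
predicted gene set become available, each reporter (probe) on the array can
be re-annotated: does it measure a known gene model, in which orientation,
does it sit in unannotated genomic sequence, or is its hybridization signal
hard to interpret at all?  probeRemap implements that reconciliation as a
self-contained pipeline.  The moving parts are:

1. an ungapped seed-and-extend **aligner** for the short (typically 60-mer)
   reporters, plus a spliced mode for reporters and ESTs that cross introns;
2. **retention rules** deciding which raw alignments count as evidence;
3. an **agreement** step asking whether the transcript a query matched is
   annotated at the same genomic position the query matched;
4. a **classifier** placing every reporter into one of six annotation
   groups: `sense_gene_model`, `antisense_gene_model`, `gdna`, `est`,
   `ambiguous`, `inconclusive`.

All coordinates in the package are 1-based and inclusive, with
`start <= end` always and strand stored separately; minus-strand hits are
normalised to this convention at the alignment boundary.  This removes a
class of silent off-by-one and strand bugs at the cost of one explicit
conversion when exporting to other conventions.

## Alignment model

### Ungapped seed-and-extend

Reporter searches use exact seed words of length `wordSize` (default 23)
over the forward strand of the targets; the reverse-complemented query is
searched against the same index for minus-strand hits.  Every seeded
(target, diagonal, strand) triple is extended to the maximal-scoring
ungapped local alignment on that diagonal (a Kadane scan over +match /
-mismatch position scores), so each triple yields at most one hit.
Gapped alignment is deliberately absent: hybridization of a 60-mer
tolerates mismatches but an indel breaks the duplex geometry, and the
retention rules below only ever keep hits with a long exact stretch.

The seed length equals the retention threshold of 23 contiguous matches on
purpose: any alignment containing a run of 23 identical bases necessarily
contains an exact 23-mer seed, so the search is *complete* for precisely
the class of hits that can ever be retained.  Hits whose longest run is
below 23 can be missed, and are knowingly irrelevant.  The default word
size comes from hybridization data: oligos sharing at least 23 contiguous
bases with a target give signal under stringent conditions, which is why
23 is both the seed and the retention cut-off.

Ties are resolved deterministically everywhere: among equal-scoring hits
the lowest (target, start, `+`-strand-first) wins, and within a diagonal
the first maximal interval (smallest end, then the earliest prefix
minimum as start) is reported.  The test suite checks the whole search
against an exhaustive every-offset scorer and against a reference BLASTN
run at word size 23 in ungapped mode.

### Two scoring schemes

Two schemes are exposed rather than one because the pipeline emulates two
different external tools:

* `blastScheme()` — match +1, mismatch -3, the classic ungapped BLASTN
  nucleotide scoring, with Karlin–Altschul parameters lambda = 1.374,
  K = 0.711 used to attach E-values (`E = K m n e^{-lambda S}`) for EST
  searches.  Exact parity with any particular BLAST release is not
  promised; the E-values serve the retention thresholds (1e-10 / 1e-20),
  which sit many orders of magnitude away from the scores that clean
  alignments produce, so reasonable parameter choices do not move any
  decision.
* `exonerateScheme()` — match +5, mismatch -4, est2genome-style scoring
  used for spliced alignment.  The EST-to-genome retention statistic is
  the *normalised score*, raw score divided by query length, kept when at
  least 3.  Under +1 scoring that filter would be unsatisfiable (the
  maximum normalised score would be 1); under +5 scoring the maximum is 5
  and the threshold of 3 demands roughly two thirds of the query aligned
  in high identity, which is the filter's intent.  This is why the spliced
  default is the +5/-4 scheme.

### Spliced (intron-aware) mode

`splicedAlign()` chains the ungapped diagonal blocks of one
(query, target, strand): consecutive blocks must be near-adjacent and
disjoint on the query, separated on the target by a gap inside the intron
bracket, and the chain must score higher than any of its blocks alone.
Numerical choices, fixed once:

* intron bracket 20 bp to 50 kb (`minIntron`, `maxIntron`): values that
  bracket plant introns generously; a target gap below 20 bp is treated as
  noise, not an intron.
* query-side tolerance: blocks may leave up to 10 unaligned query bases
  between them (a mismatch exactly at an exon junction stops extension
  early), and may overlap by up to 120 bases.  Overlaps arise when a
  block's extension runs past its exon boundary into the intron by chance
  matches; the overlap is trimmed from one side, with per-base rescoring,
  preferring to trim the upstream block's tail on ties so that clean
  junction coordinates are recovered.
* chain score is the sum of (trimmed) block scores; no explicit intron
  penalty.  This reproduces the role of the normalised-score filter, not
  any external tool's exact numbers.

With `maxIntron = 0` chaining is impossible and the output provably equals
the ungapped search — a property the tests assert.

## Retention rules (the evidence filters)

For reporter searches, similarity is measured as identity out of the
reporter length, not E-value — a 60-mer's E-values are too coarse to
separate cross-hybridizing from specific probes.  The rules:

* **Reporter vs genome / transcripts**: rank by raw score.  Keep the top
  hit iff its longest contiguous run is >= 23; if the top hit fails, the
  search result is empty (lower-ranked hits are *not* promoted — the rule
  is conditioned on the top hit).  Keep further hits iff they also reach
  identity >= 55/60, scaled to the actual query length for non-60-mer
  designs (identity/length >= 55/60).
* **EST vs transcripts**: rank by E-value; top hit kept iff E <= 1e-10,
  further hits iff E <= 1e-20.
* **EST vs genome (spliced)**: kept iff normalised score >= 3.
* EST evidence is only consulted after the reporter has been confirmed
  against its own source EST (>= 23 contiguous matches on either strand);
  reporters without an EST record simply carry no EST evidence.
* When a reporter has a positive spliced (multi-block) genome match with a
  run >= 23, that spliced result *replaces* the ungapped reporter-genome
  result, so intron-spanning reporters are placed with their true exon
  structure.

All three filters are idempotent and monotone under threshold tightening;
the tests check them against independent row-by-row predicates.

## Agreement and orientation

An agreement record states that a query's transcript-level hit and its
genome-level hit point at the same locus.  "Same locus" is operationalised
as an overlap of at least one base between the genomic hit interval and
the transcript's annotated genomic span on the same chromosome.  Strict
containment was rejected deliberately: reporters designed into UTRs can
protrude slightly beyond annotated transcript bounds and would otherwise
be lost.  Anyone comparing against a pipeline that used containment or a
distance cut-off should expect small count differences at gene edges.

Orientation is the strand algebra `sense iff hit strand == transcript
strand`, invariant under flipping both strands (mirroring the whole
genome flips nothing — asserted in the tests).  Antisense calls inherit
the usual caveat: a mis-oriented source EST or a mis-stranded gene model
turns a sense transcript into an apparent antisense hit; the package
reports what the evidence says and the fixture generator can plant
mis-oriented ESTs to exercise exactly that case.

Agreements are collapsed to one record per *gene* (best-scoring
transcript kept, deterministic tie-break), because the annotation groups
count gene models, not transcripts.  For EST-level agreements the
reporter's genomic position is obtained by mapping its footprint inside
the EST through the EST's spliced blocks; when the footprint does not fall
inside a single block, the record falls back to the EST's whole matched
span with region `unknown`.

When CDS blocks are available the record also carries a region call:
`CDS` when the interval lies entirely in coding blocks, `UTR` when it
overlaps exons but no CDS, `mixed` otherwise, `unknown` without CDS
annotation.  The call is reported, never used in classification.

## The six-group decision table

Branches are evaluated in order; the first match wins, and a
`rationale_code` records which branch fired for every reporter:

(a) agreements to **more than one distinct gene model** (reporter-level
    and EST-level combined) -> `ambiguous`;
(b) **exactly one reporter-level agreement** -> `sense_gene_model` or
    `antisense_gene_model` by its orientation;
(c) no reporter-level agreement, no retained reporter-transcript hit,
    **exactly one EST-level agreement** -> `est`; if the reporter also has
    its own genomic placement, the EST-derived placement must overlap it,
    otherwise the conflict drops to `inconclusive` (`conflicting_est_and_
    gdna`).  This collision is not covered by the published group
    definitions; routing disagreeing evidence to the lowest-confidence
    bucket is this package's explicit choice;
(d) no agreements at all, **exactly one retained genomic hit and no
    transcript hit** -> `gdna` (a unique genomic location not annotated as
    a gene model);
(e) everything else -> `inconclusive`, with sub-codes for
    transcripts-without-genomic-agreement, multiple genomic locations, and
    no valid hits.

Every reporter lands in exactly one group, so the group counts always sum
to the manifest size.  An independently transcribed copy of this table
serves as the oracle for randomized classification tests.

In the annotation table and the browser track each reporter carries one
primary genomic placement (for `ambiguous`, the best-scoring agreement's
placement under the deterministic tie-break); all supporting agreements
remain available in the per-reporter evidence.  The exported GFF3 track
omits the `est` and `inconclusive` groups, whose genomic position is
respectively indirect or absent.

## Expression flags

Given a reporter x array matrix of signal and noise (a
`SummarizedExperiment` with `signal` and `noise` assays), a reporter has
measurable signal when signal/noise **strictly exceeds** 3 on at least one
array; an SNR of exactly 3.0 is not expression.  The flag joins the
annotation table and the per-group summary, mirroring the usual
"proportion of reporters with signal" columns of array annotation tables.

## The synthetic fixture generator

`generateFixture()` builds the data the validation runs on: random
chromosomes (uniform base composition, GC 0.5), non-overlapping multi-exon
gene models with their transcripts, and reporters planted so each has a
known group:

* *sense*: a 60-mer excised from one exon of a transcript (a source EST
  covering the region is emitted too);
* *antisense*: the reverse complement of such an excision;
* *gdna*: excised from intergenic sequence, at least 120 bp from any gene;
* *est*: the reporter's genomic footprint is mutated with substitutions
  spaced so that both retention rules fail (longest run < 23 *and*
  identity < 55/60) while the EST keeps the pre-mutation sequence — the
  divergent-line scenario.  A post-generation check re-aligns the emitted
  sequences and refuses to write a fixture where the envelope is not
  defeated;
* *ambiguous*: the host gene is duplicated at a second annotated locus
  with at most two substitutions placed outside the reporter footprint, so
  both copies pass retention;
* *inconclusive*: random 60-mers verified to share no seed word with the
  genome;
* *intron-spanning sense*: reporters split 30 bp + 30 bp across an exon
  junction.

Defaults are the package's study conditions: two 500 kb chromosomes,
50 reporters per group plus ten intron-spanning extras (310 reporters,
~265 gene models), exons 150–300 bp, introns 80–800 bp, EST length
600 nt, EST-footprint divergence 0.15.  Generation is byte-deterministic
under the spec seed.  The expression generator plants an exactly-sized
silent fraction (default 25%) whose SNR stays below 3 on every array,
while every other reporter gets at least one array comfortably above it.

What the fixtures do **not** emulate: repeat families and transposon
landscapes (ambiguity in real crop-scale genomes is far more pervasive),
indels and sequencing error (the aligner is ungapped by design),
alternative transcripts per gene, biased base composition, and genome-scale
data volumes.  Passing the planted-truth tests therefore demonstrates that
the decision logic and coordinate arithmetic are correct under clean,
separable conditions — not that group proportions on a real array would be
reproduced.  Published genome-scale counts additionally depend on
proprietary reporter sets and a specific genome release, which is why
validation here is property-based rather than count-based.

## Degenerate inputs and edge policies

* Reporters shorter or longer than 60 nt: warning on import; all /60
  thresholds scale by actual length.
* `N` bases never seed and always score as mismatches.
* An empty FASTA is a warning plus an empty mapping; duplicate sequence
  IDs and non-ACGTN reporter sequences are errors that name the offender.
* BLAST tabular import never guesses the contiguous-run statistic from
  percent identity: absent the optional 13th column it is recomputed from
  the sequences (`rescoreHits()`), and gapped rows are rejected there.
* A reporter in a track-writable group without coordinates is an internal
  inconsistency and an error, not a silent omission.
* Zero classified genes makes reporters-per-gene `NA` with a message.

## Known limitations

* The aligner is ungapped; a reporter overlapping a true indel
  polymorphism will lose its run of contiguous matches and drop toward
  `est` or `inconclusive`, which matches the hybridization rationale but
  not sequence-level truth.
* Spliced chaining considers one best chain per (target, strand) and sums
  block scores without an intron penalty; exonerate's exact scores are not
  reproduced, only the role of its normalised-score filter.
* E-values use fixed ungapped Karlin–Altschul constants for the +1/-3
  scheme; changing match/mismatch scores without updating lambda and K
  shifts E-values accordingly.
* Functional annotation (protein-database searches, GO assignment) is out
  of scope; the annotation table is designed so such columns can be joined
  on `reporter_id` from external sources.

## Problem sizes used in validation

The shipped checks run the full pipeline on the default 310-reporter /
1 Mb fixture, a dedicated 20-reporter intron fixture (introns 80 bp–5 kb),
an 80 kb module-test fixture, 200 aligner-versus-oracle pairs on 2 kb
targets, and 1,000-case predicate and run-length comparisons.  These sizes
were chosen so the whole suite exercises every code path in about a
minute on a single core while keeping every comparison exact.
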