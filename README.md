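# probeRemap

Genomic re-annotation of microarray oligonucleotide reporters (probes).

Long-oligo expression arrays are usually designed from EST collections,
often before a reference genome exists.  Once a genome assembly and a
predicted transcript set become available, every reporter on the array can
be re-annotated: probeRemap maps each reporter — and, where known, the EST
it was designed from — to the genome and to the predicted transcripts,
reconciles the two levels of evidence through the transcripts' genomic
coordinates, and assigns each reporter to one of six annotation groups.
The result is an annotation table, a per-group summary, and a GFF3 track
for a genome browser.  It is aimed at anyone reinterpreting legacy array
data (expression atlases, eQTL panels) against a modern annotation.

## Method at a glance

* **Alignment.** Reporters are aligned with an ungapped seed-and-extend
  search: exact word seeds of length *w* = 23, both query strands, each
  seeded diagonal extended to its maximal-scoring local alignment
  (match +1 / mismatch −3).  Any alignment containing ≥ 23 contiguous
  matches contains an exact 23-mer, so the search is complete for exactly
  the class of hits retained below.  A spliced mode chains ungapped blocks
  across plausible introns (est2genome-style +5/−4 scoring) for
  intron-spanning reporters and for EST-to-genome placement.
* **Retention.** Reporter hits: top hit kept iff its longest contiguous
  run ≥ 23; further hits additionally need identity ≥ 55/60 (scaled by
  query length).  EST–transcript hits: top kept iff E ≤ 1e−10, further
  hits iff E ≤ 1e−20 (Karlin–Altschul E = K·m·n·e^(−λS)).  EST–genome
  spliced matches: normalised score (raw score / EST length) ≥ 3.  EST
  evidence is used only after the reporter is confirmed against its own
  EST (≥ 23 contiguous matches).
* **Agreement.** A reporter's (or EST's) transcript hit *agrees* with its
  genomic hit when the genomic interval overlaps the transcript's
  annotated genomic span (≥ 1 bp, same chromosome).  Orientation is sense
  iff the genomic hit strand equals the transcript strand.
* **Groups.** (i) sense gene model, (ii) antisense gene model,
  (iii) gDNA (unique genomic location, no gene model), (iv) EST (only the
  source EST, not the reporter, reaches a gene model), (v) ambiguous
  (more than one gene model supported), (vi) inconclusive.  Optional
  signal/noise data flags reporters with measurable signal
  (SNR > 3 on ≥ 1 array, strict).

Design notes, tunable thresholds and limitations are documented in the
methods vignette (`vignettes/probeRemap-methods.Rmd`).

## Worked example

Everything below runs on a synthetic fixture with planted ground truth —
no downloads.  `generateFixture()` builds a genome, gene models,
transcripts, ESTs and a reporter manifest in which every reporter's true
group is known:

```r
library(probeRemap)

spec <- fixtureSpec(nChromosomes = 1L, chromLength = 80000L,
                    nPerGroup = c(sense_gene_model = 4L,
                                  antisense_gene_model = 4L, gdna = 4L,
                                  est = 4L, ambiguous = 4L,
                                  inconclusive = 4L),
                    nIntronSpanning = 2L, seed = 11L)
fx  <- generateFixture(spec)
res <- classifyAll(fx$manifest, fx$genome, fx$transcripts, fx$models,
                   fx$ests)
summarizeGroups(res)
#>                 group count proportion
#>      sense_gene_model     6       23.1
#>  antisense_gene_model     4       15.4
#>                  gdna     4       15.4
#>                   est     4       15.4
#>             ambiguous     4       15.4
#>          inconclusive     4       15.4
#>                 total    26      100.0
```

The two extra sense reporters are the intron-spanning plantings.  Each row
of the annotation table carries the group, the supporting gene model(s),
the genomic placement and a rationale code naming the decision branch:

```r
res[res$reporter_id %in% c("R_0001", "R_0011", "R_0019"),
    c("reporter_id", "group", "gene_ids", "chrom", "start", "end",
      "strand", "orientation", "rationale_code")]
#>  reporter_id            group gene_ids chrom start   end strand orientation
#>       R_0001 sense_gene_model    G0001  chr1 21657 21716      +       sense
#>       R_0011              est    G0009  chr1 31207 31266      -       sense
#>       R_0019             gdna     <NA>  chr1 57340 57399      +        <NA>
#>           rationale_code
#>   single_sense_agreement
#>     single_est_agreement
#>  unique_genomic_location
```

`R_0001` matches a transcript and the same genomic locus in sense
orientation.  `R_0011`'s own sequence no longer matches anything (its
genomic footprint diverged), but its source EST still reaches gene
`G0009` and the same locus, so the reporter is annotated by EST, with its
position mapped through the EST's spliced alignment.  `R_0019` sits at a
unique genomic location with no gene model.  Against the planted truth,
`mean(res$group == fx$truth$planted_group)` is `1` — every reporter
recovers its planted group — and `reportersPerGene(res)` is `1` (each
planted gene carries one reporter; ambiguous reporters count once per
supported gene).

The same pipeline runs file-to-file, writing `annotation.tsv`,
`track.gff3` (the browser track, which omits the `est` and `inconclusive`
groups), `summary.tsv` and a `run_manifest.json` with input digests and
the configuration snapshot:

```r
fx <- generateFixture(spec, dir = "fixtures")
runAnnotate("fixtures/genome.fa", "fixtures/transcripts.fa",
            "fixtures/spans.gff3", "fixtures/manifest.tsv",
            outDir = "out", estsFa = "fixtures/ests.fa")
```

A thin command-line wrapper is installed as `exec/probe-remap`
(`probe-remap annotate --genome ... --out ...`, plus `make-fixtures`,
`summarize`, `export-gff`).  Externally computed BLAST tabular results can
replace the internal aligner via `--use-external-hits`.

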