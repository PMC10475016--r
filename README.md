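# TRAscan

TRAscan is an R/Bioconductor-style package for asking a focused question
about paired tumor genomes: when a cancer relapses or transforms under
therapy, do the somatic mutations it acquires cluster in **transcription
regulatory areas (TRAs)** — and if so, which transcription regulators'
binding territory is being hit?

It was built for the analysis pattern seen in myeloid malignancies
treated with DNA hypomethylating agents, where a diagnosis sample and a
relapse sample from the same patient are whole-genome sequenced together
with a germline control, and the acquired ("additional") mutations are
interrogated against ENCODE transcription factor binding site (TFBS)
cluster data and against expression changes measured in a model system.
Nothing in the package is disease-specific: any paired-timepoint variant
call sets plus a TFBS cluster track will do.

## What it computes

* **TRAs** — maximal genomic intervals where at least *k* (default 5)
  *distinct* transcription regulators have overlapping binding-site
  clusters. Per chromosome, each regulator's clusters are merged first
  (so duplicates never double-count), the distinct-regulator depth
  `d(x)` is accumulated, and TRAs are the maximal runs with
  `d(x) >= k`.
* **Filtered somatic calls** — the variant identification condition
  VAF `> 0.20` with `>= 5` supporting reads (both halves configurable,
  including the total-depth reading), after subtraction of germline
  calls by exact `(chrom, pos, ref, alt)` key.
* **Timepoint classes** — *common* (both timepoints), *additional*
  (relapse only), *lost* (diagnosis only); the three classes partition
  the key union.
* **Coding consequence** — codon-level annotation of SNVs against
  one-transcript-per-gene models (synonymous / missense / nonsense /
  stop_lost / start_lost), mod-3 classification of CDS indels
  (frameshift / in-frame), with HGVS-flavoured labels such as
  `c.3340G>T (p.E1114*)` and `c.504delG (p.L168fs)`.
* **TRA alterations and proximal genes** — classified variants whose
  anchor base falls in a TRA, the regulators bound at the mutated base,
  and all genes whose span lies within 20 kb (inclusive) of an
  alteration.
* **Involvement skew** — per regulator *r*, the involvement rate
  `rate_s(r) = 100 · |{alterations of class s overlapping r}| / N_s`
  for the common and additional classes, and the ratio
  `rate_additional / rate_common`, with regulators engaged exclusively
  in additional alterations flagged rather than forced to a number.
* **Expression integration** — differential-expression gene sets at
  `|FC| >= 2` (ratio scale) and `p < 0.01`, transcript-variant ("shift")
  gene sets from assembler structure classes, and exact Venn partitions
  of 2–4 gene sets against the WGS-derived proximal-gene sets.

A synthetic-data module (`simulateReference`, `simulateTfbs`,
`simulateVariantSets`, `simulateExpression`, `paperLikeFixture`)
generates every input format with planted, machine-readable truth, so
the entire pipeline is testable without controlled-access data.

## Worked example

```r
library(TRAscan)
library(GenomicRanges)

clusters <- GRanges("chr1",
    IRanges(c(101, 111, 121, 101, 141), c(200, 190, 180, 150, 200)),
    regulator = c("POLR2A", "EP300", "CTCF", "MYC", "RCOR1"))
tras <- buildTraRegions(clusters, minRegulators = 5)
tras
#> TRARegions with 1 region(s),  10 bp total coverage
#> TRARegions object with 1 range and 2 metadata columns:
#>       seqnames    ranges strand |         regulators  maxDepth
#>          <Rle> <IRanges>  <Rle> |    <CharacterList> <integer>
#>   [1]     chr1   141-150      * | CTCF,EP300,MYC,...         5
```

All five clusters overlap only on 141–150, so that interval — and
nothing wider — is the TRA. Variants are then filtered and dropped into
it:

```r
calls <- VariantCalls("chr1", c(145, 139, 60), "G", "T",
                      refReads = c(14L, 20L, 6L), altReads = c(6L, 5L, 4L))
kept <- filterCalls(calls)
attr(kept, "filterLog")
#> retained zero_depth    low_vaf  low_reads
#>        1          0          1          1

mcols(kept)$status <- "additional"
alts <- intersectVariantsTras(kept, tras, clusters)
involvedRegulators(alts)
#> CharacterList of length 1
#> [[1]] CTCF EP300 MYC POLR2A RCOR1
```

The 6/20 call (VAF 0.30) survives; the call with VAF exactly 0.20 and
the call with only 4 supporting reads are rejected — the bounds are
strict on VAF and inclusive on read support. The surviving variant sits
at base 145, inside the TRA, with all five regulators bound at the
mutated base.

The full composition — filter, subtract, classify, annotate, build
TRAs, intersect, collect proximal genes, tabulate involvement,
integrate expression — is `runPipeline(pipelineConfig(...))`, which
writes TSV/BED reports and a JSON manifest of per-stage counts.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the synthetic end-to-end fixture from the given seed, runs
the installed package's full pipeline on it, prints the per-stage
manifest counts, and writes the acceptance report JSON.
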