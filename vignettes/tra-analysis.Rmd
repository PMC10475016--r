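---
title: "Transcription regulatory area mutation analysis: methods and design"
author: "TRAscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcription regulatory area mutation analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(TRAscan)
  library(GenomicRanges)
})
```

## The problem

When a myeloid neoplasm relapses or transforms under therapy, the
mutations acquired between the two timepoints carry the signal of the
selective pressure. Most acquired mutations are non-coding, and a useful
lens on them is the binding territory of transcription regulators:
genomic areas where many regulators — transcription factors, cofactors,
chromatin modifiers — can be recruited are both functionally dense and,
in several haematological malignancies, preferentially hypermutated.
TRAscan operationalises this lens. It takes a TFBS cluster track (the
ENCODE TFBS cluster v3 dialect), paired diagnosis/relapse variant calls
with a germline control, gene models with a genome sequence, and
(optionally) expression result tables from a model system, and produces
the acquired-mutation view of the regulatory genome: which regulatory
areas were hit, which regulators' territory is over-represented among
acquired relative to shared mutations, and which nearby genes connect
the DNA-level events to expression-level changes.

## The TRA model

A **transcription regulatory area** is defined by a single parameter,
`minRegulators` (default 5): a maximal interval on which at least that
many *distinct* regulators have overlapping binding-site clusters.
The construction is a sweep over cluster endpoints, implemented with
IRanges primitives:

1. per regulator, merge that regulator's clusters (`reduce`), so
   duplicate rows and within-regulator overlaps contribute depth 1;
2. sum the merged per-regulator coverages to get the distinct-regulator
   depth `d(x)` at every base;
3. take maximal runs with `d(x) >= minRegulators` (`slice`).

Step 3 yields inherently merged, disjoint, sorted intervals; each
carries the union of overlapping regulators and the maximum depth it
attains. The definition makes two properties hold by construction,
and the test suite audits both: equality with a per-base brute-force
count, and monotonicity — raising the threshold never enlarges total
TRA coverage.

The track is consumed in its published dialect: only the first five BED
columns are interpreted (chrom, start, end, regulator name, score); the
experiment-list columns are tolerated and ignored. Coordinates are
converted from BED's 0-based half-open convention to the 1-based closed
convention of `GRanges` exactly once, at parse time. We chose the
GRanges convention as the single internal one (rather than the BED
convention) because every container and operation in the Bioconductor
stack this package is built on speaks it natively; all boundary
semantics below are stated — and tested — in printed coordinates, so
the choice is not observable in results.

## Variant identification and timepoint classes

The filter implements the identification condition "more than 20% of at
least five reads" as two explicit thresholds:

* VAF strictly greater than `minVaf = 0.20`, where
  VAF `= alt_reads / (ref_reads + alt_reads)` — AD-style two-allele
  accounting; depth carried by other alleles at the locus is excluded;
* supporting reads of at least `minAltReads = 5`, inclusive.

The phrase is ambiguous about whether "five reads" means alt-supporting
or total reads; the default counts alt-supporting reads (the reading
under which the phrase adds information at typical depths), and
`depthRule = "total"` gives the other reading. Zero-depth records are
rejected with an explicit reason, never a division error, and the
filter log counts rejects by reason.

Germline subtraction and timepoint matching use the exact identity key
`(chrom, pos, ref, alt)`. No left-normalisation is applied implicitly —
silently re-normalising indels can merge records a caller emitted as
distinct — but `leftAlignCalls()` offers the standard left-shift against
the reference as an explicit, off-by-default pass. Keys present in both
filtered timepoints are *common*, relapse-only keys are *additional*,
diagnosis-only keys are *lost*; the three classes partition the key
union, which the pipeline asserts on every run. Duplicate keys within
one sample collapse deterministically to the record with the most
supporting reads, with a warning.

## Coding consequence

Gene models keep one protein-coding transcript per gene (longest CDS,
ties broken lexicographically by transcript id), because the analysis
reports gene-level consequences only. Models whose CDS length is not a
multiple of 3 are flagged non-codable and excluded from consequence
calls with a warning.

An SNV inside a CDS segment is classified by translating its codon on
the coding strand: synonymous, missense, nonsense (gain of stop),
stop_lost, or start_lost (any change to the initiator ATG codon). An
indel overlapping CDS is frameshift or in-frame by the mod-3 rule,
applied to the CDS-overlapping portion only, so a deletion spanning a
CDS boundary is classed by the bases it removes from the CDS. All
non-CDS positions form a single class; splice-site and UTR sub-classes
are deliberately out of scope. Labels are HGVS-flavoured
(`c.3340G>T (p.E1114*)`, `c.504delG (p.L168fs)`) but not full HGVS.
The implementation is codon-local; the test suite checks it against an
independent oracle that translates the entire wildtype and mutant CDS
and diffs the proteins, across random multi-exon models on both
strands, and refuses to run when the stated reference allele
contradicts the genome sequence.

## TRA alterations, involvement, and the 20-kb rule

A classified variant joins a TRA iff its anchor base — the SNV base, or
the leftmost reference base of an indel (the VCF convention) — lies in
the TRA interval. Since TRAs are disjoint, no tie-breaking is ever
needed.

Regulator involvement is attributed **per variant position** by
default: the regulators whose clusters overlap the mutated base. This
is the stricter of two readings of "alterations involved in each
regulator" (the other being membership of the whole TRA's regulator
union), and the base-resolution reading is what makes the involvement
ratio sensitive to where inside a broad area the mutation landed;
`attribution = "region"` provides the coarser alternative.

For each regulator the **involvement rate** is the percentage of a
class's TRA alterations overlapping that regulator, and the
**involvement ratio** is additional rate over common rate. Ratios are
computed on unrounded rates; rounding to one decimal happens only at
serialization. (With rates of 14/50 and 47/100 the unrounded ratio is
1.6786; computing on pre-rounded percentages would give a slightly
different number, which is exactly why the order matters.) A regulator
with zero common involvement but nonzero additional involvement has an
undefined ratio: it is reported as an `additional_exclusive` flag and
sorted before all finite ratios, never encoded as a numeric sentinel.
The skew report flags ratio ≥ 2 ("more than two-fold") or exclusivity,
with a low-frequency caveat for exclusive regulators under 5%
involvement. No significance machinery is attached to the ratio — it is
a descriptive statistic; the simulator quantifies its sampling noise
instead.

Genes are collected for an alteration when the gap between the anchor
base and the **gene span** is at most 20,000 bp, inclusive (gap 0 inside
the span). Distance to the transcript extent, not the TSS, is the
default because "within 20 kb of an alteration" reads most naturally as
proximity to the gene body; `useTss = TRUE` gives the TSS-based
alternative. The exact boundary — 20,000 in, 20,001 out — is pinned
against a quadratic brute-force oracle.

## Expression integration

The differential-expression engine is deliberately **not**
re-implemented: p-values are first-class input, and a Welch t-test on
`log2(FPKM + pseudocount)` is offered only as a convenience when both
groups have replicates. The implementable content is the thresholds:
`|FC| >= 2` realised on the ratio scale (FC ≥ 2 or ≤ 0.5, i.e.
`|log2FC| >= 1`, the standard volcano convention) inclusively, and
`p < 0.01` strictly. Transcript-variant ("shift") genes require one
transcript that passes the thresholds *and* carries an accepted
structure class; classes are consumed as labels from the assembler
(gffcompare-style `c` = containment of reference, `j` = at least one
junction match, by default) and never recomputed. Gene-set overlaps are
exact Venn partitions of up to four sets, with the all-set intersection
reported explicitly.

## The synthetic world

The simulator's job is to make every claim above testable without the
controlled-access data the analysis pattern was developed on. Its
defaults state a world at the scale of the motivating study, and the
planted parameters are fixed, not tuned:

* **Reference**: 2 chromosomes × 300 kb, 24 genes on both strands,
  2 CDS exons each; every CDS starts ATG, ends with a stop, has length
  divisible by 3 and no internal stop (audited by translating the
  generator's own output).
* **TFBS clusters**: planted TRAs receive `k` distinct regulators
  covering the interval exactly (k from 4 to 8; the k = 4 regions exist
  to prove the threshold is real). Background clusters avoid the
  planted intervals and the builder is run inside the generator to
  verify no accidental TRA arises; on a collision the background is
  re-jittered.
* **Variants**: 20 germline (present in all three samples, exercising
  subtraction), 40 common / 70 additional / 15 lost after filtering, of
  which exactly 32 common and 54 additional lie inside planted TRAs —
  the headline counts of the motivating study, used as an homage, not a
  reproduction. Passing calls draw depth 30–100 and VAF ≈ 0.35; decoy
  calls are planted at exactly VAF = 0.20 or exactly 4 supporting
  reads, the two filter boundaries.
* **Involvement**: a MYC-like regulator is planted with involvement
  probabilities 0.28 (common) and 0.47 (additional). Each in-TRA
  variant draws a Bernoulli; on success a width-1 cluster of that
  regulator is emitted over the variant base. Because these clusters
  sit inside already-qualifying TRAs, TRA intervals are unchanged, and
  position-level attribution recovers exactly the drawn involvement —
  this geometric realisation supports any number of regulators with
  independent probabilities, which coverage-stripe designs do not.
* **Expression**: 2000 genes, 3 + 3 replicates, log2 noise sd 0.2;
  74 up- and 320 down-regulated genes planted at |log2FC| = 2,
  1321 shift genes with one accepted-class passing transcript each.
  Planted p-values sit below 0.005 and null p-values above 0.02, so
  threshold recovery is exact by construction; fold changes are
  honestly recomputed from the noisy FPKM columns.

Every generator is a pure function of its seed; reruns are
byte-identical. What a green planted-truth test establishes is that the
pipeline's set algebra, filters and joins are exact; what it does not
establish is performance on real data — the simulator has no mutational
signatures, no clonal structure in VAFs beyond a single mode, no LD or
haplotypes, uniformly random background clusters rather than the strong
clustering of real ChIP-seq tracks, and planted p-values rather than a
real DE engine.

## Numerical and design choices

* Coordinates: one internal convention (GRanges, 1-based closed);
  conversion exactly once at each I/O boundary; chromosome names match
  exactly unless an alias table is explicitly supplied.
* The variant identity key is never normalised implicitly; left
  alignment is opt-in.
* Manifest determinism: the run manifest records tool version, the full
  configuration and per-stage counts, but no timestamps — reruns of the
  pipeline on identical inputs must be byte-identical, and we chose
  that reproducibility guarantee over wall-clock provenance.
* Ordering rules are total everywhere a report is emitted (involvement:
  exclusive first, then ratio desc, additional rate desc, name asc;
  variant tables: chrom, pos, ref, alt), so outputs are stable across
  platforms.
* Degenerate inputs are defined, not accidental: empty call sets flow
  through with zero counts; an empty cluster set yields no TRAs; an
  empty class pair yields an empty involvement table with a warning.

## Limitations

TRAscan does not call variants, align reads, assemble transcripts, or
test DE; it consumes the outputs of those tools. Copy-number and
structural variants, splice-site consequence classes, promoter/enhancer
functional classification and cross-patient aggregation are out of
scope. The involvement ratio is descriptive; with small alteration
counts (tens, as in single-patient studies) its sampling noise is
substantial — the simulator's Bernoulli machinery exists precisely to
make that noise visible before interpreting a skew.
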