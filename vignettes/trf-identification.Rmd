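---
title: "Identifying tRNA-derived fragments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying tRNA-derived fragments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptrfkit)
```

## The problem

Transfer RNAs are processed extensively: the precursor transcript
(pre-tRNA) carries a 5′ leader and a 3′ trailer that are removed, introns
(where present) are spliced, and tRNA nucleotidyltransferase appends a
non-templated `CCA` to the mature 3′ end. Endonucleolytic cleavage of both
mature and precursor tRNAs produces a distinct class of 15–28 nt small
RNAs, tRNA-derived fragments (tRFs), with regulatory roles in plants and
animals. Their positional classes are defined by which processing landmark
they abut: tRF-5 at the mature 5′ end, tRF-3 at the mature 3′ end (CCA
included), and tRF-1 beginning at the first base of the 3′ trailer.

`ptrfkit` identifies and classifies tRFs from small RNA sequencing
libraries given only a genome and tRNA gene annotations. This vignette
explains the model behind each stage, the parameters that matter, the
numerical and design choices that were genuinely open, and what the
synthetic test bed does and does not demonstrate.

## Reference model

For each annotated tRNA gene the package builds two reference sequences,
both stored on the transcribed strand as DNA (U in input is mapped to T):

* **mature**: the genomic slice of the gene, reverse-complemented for
  minus-strand genes, introns spliced out, `CCA` appended. Because the CCA
  is added enzymatically it is absent from the genome; appending it is what
  lets CCA-containing tRF-3 reads map at all.
* **pre**: the unspliced gene plus 40 nt of upstream leader and 40 nt of
  downstream trailer in transcript orientation. The trailer window of
  40 nt comfortably contains tRF-1 fragments (at most 28 nt). The position
  of the first trailer base within the precursor, `trailer_start =
  actual_upstream + gene_length + 1`, is carried in the reference manifest
  and is the tRF-1 anchor.

Flanks are clipped at chromosome boundaries rather than erroring —
telomere-proximal tRNA genes exist — and the actual flank sizes are
recorded so `trailer_start` stays correct. Intron handling was an open
choice: mature tRNAs are spliced in vivo, so mature entries are spliced by
default and pre entries never are; `splice = FALSE` reproduces the
unspliced reading for pipelines that treated the gene as a contiguous
block. Coordinates are 1-based inclusive throughout the package; BED input
is converted on read.

## Ingestion and filters

Two input forms are supported, with strict-inequality filters applied as
configurable integers whose defaults encode the standard rules:

| parameter | default | meaning |
|---|---|---|
| `min_len`/`max_len` (table) | 15 / 28 nt | tRF length window |
| `min_freq` (table) | 10 | clonal frequency > 9 |
| `min_q` (FASTQ) | 28 | discard a read if **any** base < Q28 (Phred+33) |
| `min_len`/`max_len` (FASTQ) | 15 / 100 nt | collapsed-read length window |
| `min_freq` (FASTQ) | 101 | frequency > 100 |
| `upstream`/`downstream` | 40 / 40 nt | pre-tRNA flanks |

FASTQ reads are optionally adapter-trimmed first (exact leftmost match of
the full 3′ adapter, or an adapter prefix of at least 8 nt at the read
end; deliberately minimal plumbing, not an error-tolerant aligner), then
quality-filtered, collapsed to unique sequences with clonal frequencies,
and only then length/frequency-filtered. The frequency rule is applied
after collapsing trimmed, quality-passing reads — the natural reading when
collapsing defines the clonal frequency. The 15–28 nt tRF window is
enforced at classification for FASTQ-derived fragments, since reads of
15–100 nt are mapped first. Reads containing `N` are discarded: they could
never survive the 100%-identity mapping contract anyway. Qualities are
fixed to Phred+33; Phred+64 data must be converted upstream. Collapsing
conserves read mass and the filters commute, which the test suite checks
property-style.

## Exact mapping instead of alignment

The alignment acceptance rule — full query length, 100% identity, zero
gaps, plus strand of the reference only — defines exactly the set of exact
substring occurrences, so the mapper is a deterministic all-occurrence
substring search (overlap-aware, via `Biostrings::vmatchPattern`) rather
than a heuristic aligner. No reverse-complement search is performed
because the reference is already strand-resolved. The index technology is
an implementation detail behind `build_index()`; the contract, "all exact
occurrences in deterministic order", is pinned by a brute-force
sliding-window oracle over randomized instances in the tests and the
acceptance script.

Because a precursor contains its mature sequence (minus CCA), a
mature-body fragment always double-hits its source gene. Resolution is
gene-local: a fragment's pre-tRNA hits on gene X are dropped only when the
same fragment also hit gene X's mature entry. A mature hit never
suppresses pre hits on unrelated genes, since the containment argument
that justifies the rule is local to a gene. Multi-locus hits are all
retained — the catalog stores genomic location per record, and uniqueness
is an accounting concept, not a mapping one.

One sRNA-frequency heuristic sometimes applied at this stage — keeping
only the highest-frequency query per tRNA to suppress random hits — is
ambiguous between a per-gene and a global reading; the package implements
no such hidden filter and instead carries per-fragment frequencies through
the hits table so either reading can be applied downstream.

## Classification

With reference coordinates in hand, classification is pure arithmetic on
the hit interval, restricted to 15–28 nt fragments:

* `kind = mature`, `sstart = 1` → **tRF-5**;
* `kind = mature`, `send = mature_length` → **tRF-3**;
* `kind = pre`, `sstart = trailer_start` → **tRF-1**;
* anything else → no record (tallied as unanchored in the run report).
  In particular a 5′-anchored *pre*-tRNA hit (a leader-containing
  fragment) is not a tRF class and yields no record.

Open design points, resolved as follows:

* **Tie rule.** A fragment spanning the entire mature tRNA satisfies both
  terminal anchors; this requires `mature_length ≤ 28`, which is
  biologically marginal. Such records are classified tRF-5 and flagged
  (`full_length_ambiguous`) rather than silently dropped.
* **CCA and the genome.** Matched CCA bases have no genomic coordinates.
  `genomic_location` covers templated bases only and `cca_overlap` counts
  the matched CCA bases, keeping genome lift-over well-defined; for a
  spliced gene the location spans the intron gap.
* **tRF-1 3′ boundary.** Only the start is anchored; the end may fall
  anywhere inside the trailer window (no poly-U requirement is imposed,
  as plant pol III terminators are variable and the trailer window bounds
  the fragment anyway).
* Anticodon and isotype flow from the reference header and are never
  re-predicted.

Catalog accounting separates *entries* (one per classified hit, i.e.
sample-level) from *unique* tRFs (distinct sequence within a species and
type). Summary tables report both, plus fixed 15–28 nt length histograms
per species and per type.

## Synthetic test bed

`spike_plan()` → `make_genome()` → `make_library()` generate a toy genome
(default one 20 kb contig) with 10 planted intron-less tRNA genes of
70–90 nt on both strands, and a library spiking true tRF-5/tRF-3/tRF-1
fragments (correct anchors, frequencies 101–400, above both input-path
thresholds) among seven decoy classes: internal mature-body fragments,
±1-shifted anchors, frequency-boundary fragments at exactly 9 and 100,
single-substitution copies, reverse complements, non-tRNA sequences, and
(FASTQ only) reads with one base at Q27. Every fragment carries an
intended fate per input path in a ground-truth ledger; the flagship test
is exact agreement between the pipeline's catalog and the ledger's kept
set, with every decoy rejected at the stage its fate names. A single seed
drives two derived RNG streams (genome layout, library), so changing
library knobs does not shift the genome.

Decoy draws are guarded against coincidences — each anchored fragment must
anchor exactly once, at its intended terminus only, and absent-by-design
sequences are verified absent — so ledger fates hold by construction on
every seed rather than with high probability.

What passing these tests shows: the coordinate arithmetic, strand
handling, threshold semantics, resolution rule and classification logic
are exact. What they do not show: behaviour on real tRNA sequence
families (the fixtures use random gene bodies, so cross-gene multi-mapping
of isoacceptor families is rare here but common in real genomes — the
pipeline reports all loci, which is the correct behaviour in both
regimes), sequencing error models, or adapter chemistry beyond exact-match
trimming.

Problem sizes were chosen to keep the full validation sweep comfortable on
a laptop: 20 fixture seeds with ~100 planted fragments each for
end-to-end recovery, 1000 random instances for the mapper oracle, and 500
random genes for the reference invariants.

## Degenerate inputs and numerical conventions

Empty gene lists build an empty reference with a warning; empty or fully
filtered libraries run to completion with a zero-record warning; malformed
FASTQ records and out-of-bounds gene coordinates are hard errors naming
the record or gene. All character sorting uses radix order so outputs are
byte-identical across locales; catalogs sort by (species, type, sequence)
and reruns on identical inputs are byte-identical.

## Limitations

* tRNA halves (30–36 nt), internal tRFs and target prediction are out of
  scope.
* The adapter trimmer is exact-match only.
* Mapping is strictly exact: a single sequencing error drops a fragment,
  which is the intended reading of the 100%-identity contract, not an
  approximation to error-tolerant mapping.
* The per-gene mature/pre resolution assumes gene-local containment; it
  does not attempt to resolve identical mature sequences shared by
  distinct loci (all loci are reported).
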