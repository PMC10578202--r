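---
title: "Methods: merging, classifying and evaluating RNA-seq transcript annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: merging, classifying and evaluating RNA-seq transcript annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotweave)
```

# The problem

A genome annotation project holds a reference annotation and per-sample
transcript assemblies (e.g. StringTie GTFs with per-transcript TPMs) from
many tissues, stages and replicates. The goal is one merged annotation that
keeps every reference model, adds reproducible novel transcripts, and
characterises the result: positional novelty, coding status, lncRNA context,
structural quality, tissue specificity, and cross-species orthology.
`annotweave` implements that computational core; it deliberately does not
trim, map, assemble or compute TPMs — those are inputs produced by standard
tools.

# Data model and coordinate conventions

Annotations are tibbles with one row per transcript and exon coordinates in
integer list-columns. All internal coordinates are **1-based inclusive** on
the forward strand, the GTF convention; BED peaks (0-based half-open) and
PSL alignments (0-based half-open blocks) are converted at ingestion, so no
other code path ever reasons about mixed conventions. Exons of one
transcript must be sorted, non-overlapping and separated by at least one
intronic base; introns are the inclusive gaps, so exons `(100,200),(300,400)`
have the single intron `(201,299)` and the identity
*exonic length + intronic length = genomic span* holds for every transcript.

Unstranded transcripts are dropped at GTF ingestion with a counted warning
(a flag turns this into an error): every downstream rule — chain identity,
overlap, splice-site read-out, TSS/TTS — is strand-aware, and a strandless
model cannot participate meaningfully in any of them. Transcripts whose exon
rows span chromosomes or strands are rejected outright: trans-splicing is
out of scope.

# Merging

The merge is intentionally conservative. Two spliced transcripts may be
collapsed **only** when they share an exact intron chain on the same
chromosome and strand; collapsing then takes the minimum first-exon start
and maximum last-exon end, leaving internal exons untouched. This is the
only structural modification merging can ever make, which rules out chimeric
models assembled from incompatible isoforms. Per-sample TPMs are merged by
per-sample maximum, and the detection count becomes the number of distinct
source transcriptomes contributing members.

The chain rule says nothing about monoexonic transcripts. We collapse
same-strand monoexonic transcripts whose intervals overlap (transitively)
into their union extent — the natural zero-intron limit of the chain rule —
and the behaviour can be disabled (`merge_config(monoexonic_collapse =
FALSE)`) for users who prefer to keep fragmented single-exon models apart.

Containment removal discards transcripts that add no information, but only
under **chain compatibility**: a spliced transcript is removed only when a
same-strand transcript extends it (its chain is a contiguous sub-chain of
the container's, extra introns strictly outside its extent) and covers its
extent; a monoexonic transcript only when it lies inside a single exon of
another model. A short model whose extent happens to sit inside an
incompatible structure (e.g. a monoexonic transcript spanning an intron) is
genuine alternative structure and is kept. Removed ids are recorded in the
survivor's `contains` attribute.

Reference integration preserves the reference: every reference transcript
appears in the output exactly once. The single exception adopts, for a
reference transcript whose chain equals a novel transcript's chain with a
longer terminal exon, the longer extremity — keeping the reference
transcript id and biotype on the extended model, since identity should
follow the reference even when coordinates improve. A novel transcript that
adds an intron to a reference chain is a new isoform and coexists with the
reference model.

Gene loci are connected components of the graph joining transcripts with at
least 1 bp of same-strand exonic overlap. Components containing reference
transcripts keep the lexicographically first reference gene id and list all
same-strand overlapping reference genes in `ref_gene_id`; novel components
are numbered `TAGG000001, ...` in (chromosome, start) order so ids are
stable across runs. Novel transcripts are numbered `TAGT000001, ...` the
same way.

# Filters

Two filters remove assembly noise, and only noise that fails to replicate:
a novel transcript must be detected in at least 2 input transcriptomes
(`min_transcriptomes`) and reach 0.1 TPM (`min_tpm`) in at least one of
them. Both comparisons are inclusive — detection in exactly
`min_transcriptomes` assemblies survives, and a maximal TPM exactly at the
threshold survives ("does not reach" fails only strictly below). A novel
transcript with no TPM values has maximum 0 and is removed under any
positive threshold. Reference transcripts are exempt from both filters under
every configuration, and the two filters commute.

# Classification

Spliced transcripts receive the first matching class in the fixed priority
order **Exact > Extension > Inclusion > Overlapping >
Intergenic_or_Antisense**; monoexonic transcripts form their own
`Monoexonic` stratum. Extension and Inclusion both require extent overlap in
addition to sub-chain compatibility. For the Overlapping predicate the
package uses same-strand *extent* overlap by default, with an exonic-overlap
mode behind a flag (`overlap_mode = "exonic"`) — the choice only affects
transcripts overlapping a reference gene exclusively within its introns.

Novelty is the strictest structural reading: a spliced transcript is `known`
only on exact chain identity; a monoexonic transcript only on exact
(chromosome, strand, start, end) identity, with a stranded-overlap
alternative behind `monoexonic_match = "overlap"`. Gene novelty is `known`
if all member transcripts are known, `unknown` if none are, `enriched`
otherwise.

Unified biotypes resolve the reference label and the coding-potential label
with coding priority: `protein_coding`/`mRNA` from either source wins, then
`lncRNA`, then `TUCp`, then `noORF`; anything else is `uncharacterized`. A
gene with one mRNA transcript is coding; otherwise one lncRNA transcript
makes it long non-coding. LncRNA candidate eligibility requires exonic
length strictly above 200 bp, no same-strand exonic overlap with a reference
mRNA, and either more than two exons or exactly two both longer than 25 bp —
so monoexonic transcripts are never candidates.

LncRNA positional context is computed against the annotation's own mRNA
transcripts. Genic (extent overlap, the mRNA chosen by largest overlap then
smallest id) splits into exonic/intronic by 1 bp of exon-level overlap;
intergenic lncRNAs search the nearest mRNA within a 100 kb window (the
class vocabulary fixes no window; 100 kb comfortably covers regulatory
neighbourhoods at mammalian/avian gene density, and ties break by distance
then id), with upstream/downstream defined relative to the mRNA's
orientation and antisense upstream/downstream labelled divergent/convergent.
No mRNA in the window leaves the transcript `unclassified` rather than
forcing a label.

Catalog matching declares a spliced transcript found in an external catalog
when it shares at least one identical intron, and a monoexonic transcript
when it strandedly overlaps a catalog monoexonic transcript; a gene matches
when any member transcript does.

# QC metrics

Intron canonicity extracts donor and acceptor dinucleotides strand-aware
(reverse complement on the minus strand) over introns deduplicated on
(chromosome, strand, start, end), and accepts GT–AG, GC–AG, AT–AC. Introns
shorter than 4 bp are rejected at read-out — donor and acceptor would
overlap, which indicates a corrupt model rather than a metric value.

3' completion has two published readings and both are implemented, neither
presumed canonical: the distance mode (default) counts distinct TTS with a
same-strand AATAAA/ATTAAA hexamer whose nearest motif base is strictly
closer than 50 bp; the windowed-containment mode (`tts_polya_span`) counts
TTS whose last 30 bp contain a complete hexamer. 5' completion counts
distinct TSS falling inside (strandless) open-chromatin peaks, matching the
strand-agnostic nature of ATAC-seq. All metrics report their backing
integer counts so every fraction is recomputable.

# Expression statistics

Expressed-feature calls use TPM >= 0.1 in >= 2 samples (both inclusive).
Expression breadth counts tissues with TPM strictly **above** 0.1 in at
least 4 of the tissue's samples. The inclusive/strict asymmetry between the
two calls is deliberate and follows the conventions the two statistics are
reported with; it is visible in the function documentation.

The tau index is computed on per-tissue mean TPMs, requires at least two
tissues and a non-zero maximum (an all-zero profile has no defined
specificity and errors rather than returning a silent 0), lies in [0,1] and
is invariant under positive scaling. Tissue-specific genes use a strict
tau > 0.9 with the argmax tissue, ties to the lexicographically first tissue.

Sample similarity is the Pearson correlation of log10(TPM + 0.1) profiles;
a zero-variance profile is an error naming the sample. Clustering is
agglomerative complete linkage on d = 1 − r (the distance transform is the
package's choice; it is the standard one for correlation clustering and is
stated here because the similarity definition alone does not fix it). The
agglomeration is implemented directly so that tie-breaking is specified:
among minimal-distance pairs, the pair whose clusters contain the smallest
original sample indices wins, making the merge sequence fully deterministic.
Tests cross-check the merge structure against `stats::hclust` through
cophenetic distances on tie-free matrices.

# Orthology

PSL alignments are scored as `matches + repMatches − misMatches −
qNumInsert − tNumInsert`; the best hit per query takes the maximal score,
then more blocks, then first-in-file. Queries map to the target transcript
with the largest same-strand exonic overlap, summed block-by-exon (when
alignment blocks split an exon the base-pair sum is the natural aggregate),
ties to the smallest transcript id. Source genes accumulate the union of
their transcripts' target genes.

Evaluation against a 1-to-1 ortholog truth set defines sensitivity over
source genes colocalizing (>= 1 bp same-strand exonic overlap) with a
truth-bearing reference gene, and precision symmetrically over truth target
genes; percentages are rounded half-up to one decimal, the convention all
summaries in the package share (`recovery_percent()`).

Synteny-based lncRNA orthology extracts (coding, lnc, coding) triplets of
strictly consecutive genes — any other gene between them, including an
uncharacterized one, breaks the triplet — and pairs lnc genes whose flanking
coding genes map to a target triplet's flanks. Flanks are treated as an
unordered pair by default (robust to local inversions); `ordered = TRUE`
restores the strict reading. The published description does not resolve
this; the unordered default is the package's choice.

# The synthetic fixture generator

`fixture_spec()` fixes the study conditions: 2 chromosomes x 200 kb, 60
single-transcript gene loci on a non-overlapping grid with alternating
coding/lncRNA biotypes (so synteny triplets exist), 6 input assemblies,
K = 8 planted novel isoforms (each in >= 2 samples at TPM >= 0.1, with one
splice site shifted by 12 bp so the chain is neither identical to nor a
sub-chain of any reference chain), 4 planted terminal-exon extensions, and
10 noise transcripts that each fail exactly one filter (single-sample, or
two samples below 0.1 TPM). The expression design is 7 tissues x 3
developmental stages x 4 replicates = 84 samples, with 10 planted
tissue-specific genes at a >= 50-fold tissue effect. Planted QC fractions
default to typical reference-annotation levels: canonical introns 0.98,
TSS-in-peak 0.67, TTS-near-polyA 0.43, monoexonic fraction 0.074.

Exactness of the planted truth is engineered, not hoped for: splice-site
dinucleotides are planted at every annotated intron boundary (non-canonical
introns get CC–GG, never at a boundary shared with a planted novel intron);
polyA hexamers are planted 25 bp from the selected TTS; and because all four
hexamer patterns (both strands) are A/T-only while every planted splice
dinucleotide contains G or C, a single scrub pass that mutates one base of
each non-planted occurrence to C removes all accidental signals without
touching planted ones and cannot create new ones. Gene loci are spaced so
peaks and polyA plants can never contaminate a neighbouring site. Every draw
comes from a label-derived seed, so each artifact is reproducible
independently and emitted files are byte-identical across runs.

What the generator does **not** emulate: read-level noise, coverage-driven
fragmentary assemblies, alternative isoforms in the reference itself,
realistic splice-site sequence context beyond the planted dinucleotides,
GC-content or repeat structure, and expression correlation between
neighbouring genes. Passing tests therefore demonstrate the correctness of
the merging/filtering/classification logic under its stated contracts — not
the field performance of any upstream assembler.

# Numerical choices and degenerate inputs

* Percentages are rounded half-up to one decimal everywhere.
* All threshold comparisons are documented as inclusive or strict at the
  function level; boundary cases are tested explicitly (TPM exactly 0.1,
  tau exactly 0.9, detection exactly at threshold).
* Deterministic tie-breaks: lexicographically smallest id (reference-id
  inheritance, overlap assignment), smallest sample index (clustering),
  first-in-file (PSL best hit).
* Degenerate inputs error early with named offenders: empty annotations in
  fraction metrics, all-zero tau profiles, zero-variance similarity
  profiles, introns under 4 bp, malformed GTF/PSL rows (with line numbers).
* Test and acceptance problem sizes — 60-gene fixtures, 6 assemblies,
  <= 200-transcript random sets against brute-force oracles, 20 recovery
  seeds, <= 12-sample clustering oracles — are the package's chosen balance
  between coverage and a test suite that runs in a few minutes.

# Known limitations

* The merge has no fuzzy splice-site tolerance: a 1 bp splice-site wobble
  creates a distinct chain. This is faithful to the chain-identity
  contract but strict for noisy long-read inputs.
* Gene clustering by exonic overlap can fuse neighbouring reference genes
  when a novel transcript bridges them; the fused locus keeps the first
  reference gene id and lists all of them in `ref_gene_id`.
* `read_gtf` keeps the attributes the pipeline uses (ids, biotypes,
  provenance, TPM) and drops others; round-trips are exact on those fields
  only.
* Projection orthology consumes existing PSL alignments; producing the
  liftover itself is out of scope.
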