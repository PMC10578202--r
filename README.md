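# annotweave

Reference genome annotations age quickly: every new RNA-seq project observes
transcripts that the reference does not describe, yet most RNA-seq pipelines
either quantify against the frozen reference or assemble a brand-new
annotation that discards it. `annotweave` implements the middle path for
annotation projects (its design target is multi-tissue, multi-stage
livestock transcriptome atlases, but nothing is species-specific): it takes
a reference annotation plus one transcript assembly per sample and weaves
them into a single non-redundant annotation in which **reference models can
only gain, never lose**.

The package covers the computational core of that workflow:

* **Merging** — transcripts are collapsed only when they share an exact
  intron chain (so merging can only extend first/last exonic positions, and
  never fabricates chimeric structures); strictly included transcripts are
  discarded; transcripts sharing a same-strand exonic position get one gene
  id; a reference transcript is reported verbatim unless a novel transcript
  with the same chain extends a terminal exon, in which case the longer form
  keeps the reference id and biotype.
* **Filtering** — novel transcripts survive only if seen in at least
  `min_transcriptomes` input assemblies (default 2) and reaching a maximal
  TPM of `min_tpm` across assemblies (default 0.1). Reference models are
  exempt.
* **Classification** — each spliced transcript gets one positional class in
  priority order *Exact > Extension > Inclusion > Overlapping >
  Intergenic_or_Antisense*; transcripts/genes get known/unknown and
  known/enriched/unknown novelty labels, unified biotypes (coding labels win
  conflicts), lncRNA-candidate eligibility (length > 200 bp, no same-strand
  exonic mRNA overlap, exon-count rule), lncRNA positional context
  (genic exonic/intronic, intergenic upstream/downstream,
  divergent/convergent), and external-catalog matching via shared introns.
* **QC** — splice-site canonicity (GT–AG, GC–AG, AT–AC over deduplicated
  introns), 5' completion (distinct TSS inside open-chromatin peaks), 3'
  completion (distinct TTS within 50 bp of an AATAAA/ATTAAA signal, or the
  windowed-containment variant), monoexonic fraction.
* **Expression statistics** — expressed-feature calls (TPM >= 0.1 in >= 2
  samples), the tau tissue-specificity index
  `tau = sum_i(1 - x_i / max_j x_j) / (N - 1)` on per-tissue mean TPMs
  (tissue-specific when tau > 0.9), expression breadth, and sample
  similarity (Pearson on log10(TPM + 0.1)) with deterministic
  complete-linkage clustering.
* **Orthology** — PSL alignment scoring
  (`matches + repMatches − misMatches − qNumInsert − tNumInsert`), best-hit
  selection (ties: more blocks, then file order), same-strand exonic-overlap
  assignment to target transcripts/genes, sensitivity/precision evaluation
  against 1-to-1 ortholog truth sets, and synteny-based lncRNA orthology
  through conserved (coding, lnc, coding) gene triplets.
* **Synthetic fixtures** — a deterministic generator of genomes,
  annotations, assemblies, peaks, expression matrices and PSL files with
  exact recorded ground truth, so the whole pipeline is testable offline.

Everything is tidyverse-native: annotations are tibbles (one row per
transcript, exon coordinates in list-columns), every user-facing function
takes a data frame first and returns a tibble, results support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(annotweave)

# deterministic toy dataset: 60 reference genes, 6 assemblies, 8 planted
# novel isoforms, 4 planted extensions, 10 noise transcripts
fx <- simulate_fixtures(fixture_spec(seed = 1))

merged <- merge_annotations(fx$assemblies, fx$reference)
table(merge_report(merged)$action)
#>  absorbed     added collapsed      kept  replaced
#>        60        18       225        56         4

merged <- filter_transcripts(merged)
merged
#> # annotweave annotation (merged): 68 transcripts
```

The 60 reference transcripts are all present (4 of them with a longer
terminal exon adopted from the assemblies, as the `replaced` actions show),
and of the 18 collapsed novel candidates only the 8 planted isoforms survive
the consistency and expression filters — the 10 noise models, each seen in
one sample or below 0.1 TPM, are gone.

```r
qc_report(merged, genome = fx$genome, peaks = fx$peaks)
#>                      metric      value numerator denominator
#> 1       monoexonic_fraction 0.05882353         4          68
#> 2 canonical_intron_fraction 0.98089172       154         157
#> 3            tts_completion 0.40000000        24          60
#> 4            tss_completion 0.66666667        40          60

cls <- classify_transcripts(merged, fx$reference)
table(cls$positional_class, cls$novelty)
#>               known unknown
#>   Exact          56       0
#>   Monoexonic      4       0
#>   Overlapping     0       8

tau(c(1, 2, 4))
#> [1] 0.625
```

All reference-derived transcripts classify as Exact (or Monoexonic) and
known; the planted isoforms — same genes, shifted splice site — come out as
unknown Overlapping transcripts of known genes, i.e. the genes become
`enriched`.

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/cli/annotweave.R simulate --seed 1 --out fixtures/
Rscript inst/cli/annotweave.R run --reference fixtures/reference.gtf \
  --assemblies fixtures/sample*.gtf --genome fixtures/genome.fa \
  --peaks fixtures/peaks.bed --out results/
```

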