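Package: annotweave
Title: Weave RNA-Seq Transcript Assemblies into a Reference Genome Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to extend a reference genome annotation with per-sample
    transcript assemblies from RNA-seq. Transcripts sharing an intron chain
    are collapsed, strictly included models are discarded, and reference
    models are preserved except for terminal-exon extensions. Novel
    transcripts are filtered by cross-sample consistency and expression,
    position-classified against the reference (Exact, Extension, Inclusion,
    Overlapping, Intergenic_or_Antisense), checked for long non-coding RNA
    candidate eligibility and positional context, and quality-controlled
    with splice-site canonicity and 5'/3' completion metrics. Expression
    utilities compute tau tissue specificity, expression breadth and
    complete-linkage sample clustering; a projection-based orthology module
    scores PSL alignments, selects best hits and infers long non-coding gene
    orthology from conserved coding-gene triplets. A deterministic synthetic
    fixture generator emulates genomes, annotations, assemblies, expression
    matrices, peaks and PSL alignments with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
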