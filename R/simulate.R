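#' Synthetic fixture specification
#'
#' Describes a deterministic toy dataset: a random genome with planted
#' splice-site dinucleotides and polyA hexamers, a reference annotation of
#' non-overlapping gene loci with alternating coding / long non-coding
#' biotypes, per-sample assemblies containing jittered reference models, K
#' planted novel isoforms (each in >= 2 samples with TPM >= 0.1), planted
#' terminal-exon extensions, and noise transcripts that fail exactly one of
#' the two transcript filters. Every draw is seeded from `seed` via stable
#' per-artifact labels, so changing one artifact never perturbs another.
#'
#' Default fractions mirror typical reference-annotation levels: canonical
#' introns 0.98, TSS-in-peak 0.67, TTS-near-polyA 0.43, monoexonic
#' transcripts 0.074; the expression design is 7 tissues x 3 stages x 4
#' replicates (84 samples).
#'
#' @param seed master seed (integer).
#' @param n_chrom,chrom_length chromosome count and length in bp.
#' @param n_genes reference gene count (one transcript per gene).
#' @param exon_range min/max exon count for spliced transcripts.
#' @param monoexonic_fraction fraction of monoexonic reference transcripts.
#' @param n_novel planted novel isoform count (K).
#' @param n_extensions planted terminal-exon extension count.
#' @param n_noise noise transcript count.
#' @param n_assemblies number of input transcriptomes.
#' @param detection_prob probability a reference transcript is assembled in
#'   a given sample.
#' @param canonical_fraction planted fraction of canonical reference introns.
#' @param tss_peak_fraction planted fraction of TSS covered by a peak.
#' @param tts_polya_fraction planted fraction of TTS within 50 bp of a
#'   polyA signal.
#' @param tissues,n_stages,n_replicates expression design.
#' @param n_specific planted tissue-specific gene count.
#' @param decoys_per_query decoy alignments per query in the PSL fixture.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_chrom = 2L, chrom_length = 200000L,
                         n_genes = 60L, exon_range = c(2L, 5L),
                         monoexonic_fraction = 0.074, n_novel = 8L,
                         n_extensions = 4L, n_noise = 10L, n_assemblies = 6L,
                         detection_prob = 0.7, canonical_fraction = 0.98,
                         tss_peak_fraction = 0.67, tts_polya_fraction = 0.43,
                         tissues = c("brain", "intestine", "kidney", "liver",
                                     "lung", "muscle", "skin"),
                         n_stages = 3L, n_replicates = 4L, n_specific = 10L,
                         decoys_per_query = 2L) {
  spec <- list(seed = as.integer(seed), n_chrom = n_chrom,
               chrom_length = chrom_length, n_genes = n_genes,
               exon_range = exon_range,
               monoexonic_fraction = monoexonic_fraction, n_novel = n_novel,
               n_extensions = n_extensions, n_noise = n_noise,
               n_assemblies = n_assemblies, detection_prob = detection_prob,
               canonical_fraction = canonical_fraction,
               tss_peak_fraction = tss_peak_fraction,
               tts_polya_fraction = tts_polya_fraction, tissues = tissues,
               n_stages = n_stages, n_replicates = n_replicates,
               n_specific = n_specific, decoys_per_query = decoys_per_query)
  if (any(unlist(spec[c("n_genes", "n_novel", "n_extensions", "n_noise")]) < 0)) {
    stop("fixture counts must be >= 0", call. = FALSE)
  }
  structure(spec, class = "fixture_spec")
}

# per-artifact seeding: stable label-derived stream, independent of call order
fix_seed <- function(spec, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  set.seed(((spec$seed %% 99991L) * 7919L + h) %% .Machine$integer.max)
}

fixture_layout <- function(spec) {
  stride <- 3000L
  margin <- 1000L
  per_chrom <- (spec$chrom_length - margin) %/% stride
  need <- spec$n_genes + spec$n_noise
  if (need > per_chrom * spec$n_chrom) {
    stop("chromosomes too small for requested gene count", call. = FALSE)
  }
  idx <- seq_len(need) - 1L
  tibble::tibble(
    locus = seq_len(need),
    chrom = paste0("chr", (idx %/% per_chrom) + 1L),
    start = margin + (idx %% per_chrom) * stride
  )
}

# full coordinate design: reference, planted novel/extension/noise
# structures, splice-site assignments, polyA and peak placements
design_fixture <- function(spec) {
  layout <- fixture_layout(spec)
  n_mono <- round(spec$monoexonic_fraction * spec$n_genes)

  fix_seed(spec, "structure")
  mono_genes <- sort(sample(spec$n_genes, n_mono))
  ref_rows <- purrr::map(seq_len(spec$n_genes), function(i) {
    loc <- layout[i, ]
    strand <- sample(c("+", "-"), 1)
    offset <- sample(0:100, 1)
    if (i %in% mono_genes) {
      s <- loc$start + offset
      starts <- s
      ends <- s + sample(300:800, 1)
    } else {
      ne <- sample(spec$exon_range[1]:spec$exon_range[2], 1)
      elens <- sample(80:200, ne, replace = TRUE)
      ilens <- if (ne > 1) sample(60:150, ne - 1, replace = TRUE) else integer()
      starts <- integer(ne)
      ends <- integer(ne)
      pos <- loc$start + offset
      for (k in seq_len(ne)) {
        starts[k] <- pos
        ends[k] <- pos + elens[k] - 1L
        pos <- ends[k] + (if (k < ne) ilens[k] + 1L else 0L)
      }
    }
    tibble::tibble(
      transcript_id = sprintf("SIMT%04d", i),
      gene_id = sprintf("SIMG%04d", i),
      chrom = loc$chrom, strand = strand,
      exon_starts = list(as.integer(starts)), exon_ends = list(as.integer(ends)),
      origin = "reference",
      transcript_biotype = if (i %% 2 == 1) "protein_coding" else "lncRNA"
    )
  })
  reference <- annotation(dplyr::bind_rows(ref_rows), provenance = "reference")

  spliced_genes <- setdiff(seq_len(spec$n_genes), mono_genes)
  if (spec$n_novel + spec$n_extensions > length(spliced_genes)) {
    stop("not enough spliced genes for requested planted transcripts",
         call. = FALSE)
  }
  picks <- sample(spliced_genes, spec$n_novel + spec$n_extensions)
  novel_genes <- picks[seq_len(spec$n_novel)]
  ext_genes <- setdiff(picks, novel_genes)

  empty_planted <- tibble::tibble(
    transcript_id = character(), chrom = character(), strand = character(),
    exon_starts = list(), exon_ends = list()
  )

  # planted novel isoform: shrink exon 1 by 12 bp so intron 1 starts earlier;
  # the chain differs from every reference chain and is not a sub-chain
  novel <- purrr::map(novel_genes, function(i) {
    r <- reference[i, ]
    s <- r$exon_starts[[1]]; e <- r$exon_ends[[1]]
    e[1] <- e[1] - 12L
    tibble::tibble(transcript_id = sprintf("NOVL%04d", i), chrom = r$chrom,
                   strand = r$strand, exon_starts = list(s),
                   exon_ends = list(e))
  }) |> dplyr::bind_rows()
  if (nrow(novel) == 0) novel <- empty_planted

  # planted extension: same chain, last exon 60 bp longer
  extensions <- purrr::map(ext_genes, function(i) {
    r <- reference[i, ]
    s <- r$exon_starts[[1]]; e <- r$exon_ends[[1]]
    e[length(e)] <- e[length(e)] + 60L
    tibble::tibble(transcript_id = sprintf("EXTN%04d", i),
                   extends = r$transcript_id, chrom = r$chrom,
                   strand = r$strand, exon_starts = list(s),
                   exon_ends = list(e))
  }) |> dplyr::bind_rows()
  if (nrow(extensions) == 0) {
    extensions <- dplyr::mutate(empty_planted, extends = character())
  }

  noise <- purrr::map(seq_len(spec$n_noise), function(j) {
    loc <- layout[spec$n_genes + j, ]
    strand <- sample(c("+", "-"), 1)
    if (j %% 3 == 0) {
      starts <- loc$start + 100L
      ends <- starts + 399L
    } else {
      starts <- c(loc$start + 100L, loc$start + 400L)
      ends <- c(loc$start + 299L, loc$start + 599L)
    }
    tibble::tibble(
      transcript_id = sprintf("NOIS%04d", j), chrom = loc$chrom,
      strand = strand, exon_starts = list(as.integer(starts)),
      exon_ends = list(as.integer(ends)),
      failure_mode = if (j %% 2 == 1) "consistency" else "expression"
    )
  }) |> dplyr::bind_rows()
  if (nrow(noise) == 0) {
    noise <- dplyr::mutate(empty_planted, failure_mode = character())
  }

  # splice-site assignment over distinct reference introns; introns sharing
  # a boundary with a planted novel intron stay canonical so plantings
  # never conflict
  ref_introns <- introns(reference, distinct = TRUE)
  novel_introns <- if (nrow(novel) > 0) {
    introns(annotation(novel), distinct = TRUE)
  } else ref_introns[0, ]
  fix_seed(spec, "canonicity")
  n_noncanon <- nrow(ref_introns) -
    round(spec$canonical_fraction * nrow(ref_introns))
  protected <- paste(ref_introns$chrom, ref_introns$end) %in%
    paste(novel_introns$chrom, novel_introns$end) |
    paste(ref_introns$chrom, ref_introns$start) %in%
    paste(novel_introns$chrom, novel_introns$start)
  candidates <- which(!protected)
  noncanon_idx <- if (n_noncanon > 0) {
    sort(sample(candidates, min(n_noncanon, length(candidates))))
  } else integer()
  ref_introns$canonical <- TRUE
  ref_introns$canonical[noncanon_idx] <- FALSE

  noise_introns <- introns(annotation(noise[, setdiff(names(noise), "failure_mode")]),
                           distinct = TRUE)
  extra_introns <- dplyr::bind_rows(novel_introns, noise_introns)
  extra_introns$canonical <- TRUE
  all_introns <- dplyr::bind_rows(ref_introns, extra_introns) |>
    dplyr::distinct(.data$chrom, .data$strand, .data$start, .data$end,
                    .keep_all = TRUE)

  # site selection for 5'/3' completion planting
  feats <- transcript_features(reference)
  tss <- dplyr::distinct(feats, .data$chrom, .data$strand, pos = .data$tss)
  tts <- dplyr::distinct(feats, .data$chrom, .data$strand, pos = .data$tts)
  fix_seed(spec, "sites")
  tss_sel <- sort(sample(nrow(tss), round(spec$tss_peak_fraction * nrow(tss))))
  tts_sel <- sort(sample(nrow(tts), round(spec$tts_polya_fraction * nrow(tts))))
  peaks <- tibble::tibble(chrom = tss$chrom[tss_sel],
                          start = tss$pos[tss_sel] - 20L,
                          end = tss$pos[tss_sel] + 20L)
  polya <- tibble::tibble(
    chrom = tts$chrom[tts_sel], strand = tts$strand[tts_sel],
    pos = ifelse(tts$strand[tts_sel] == "+", tts$pos[tts_sel] - 30L,
                 tts$pos[tts_sel] + 25L),
    motif = ifelse(tts$strand[tts_sel] == "+", "AATAAA", "TTTATT")
  )

  list(
    layout = layout, reference = reference, novel = novel,
    extensions = extensions, noise = noise, introns = all_introns,
    peaks = peaks, polya = polya,
    truth = list(
      n_genes = spec$n_genes,
      n_reference_transcripts = nrow(reference),
      monoexonic_fraction = n_mono / spec$n_genes,
      canonical_fraction = sum(ref_introns$canonical) / nrow(ref_introns),
      tss_completion = length(tss_sel) / nrow(tss),
      tts_completion = length(tts_sel) / nrow(tts),
      novel_ids = novel$transcript_id,
      novel_chains = if (nrow(novel) > 0) chain_key(annotation(novel)) else character(),
      extended_reference_ids = extensions$extends,
      noise_ids = noise$transcript_id,
      triplet_count = nrow(extract_triplets(
        dplyr::mutate(gene_table(reference),
                      coding_status = ifelse(
                        as.integer(sub("SIMG", "", .data$gene_id)) %% 2 == 1,
                        "mRNA", "lncRNA"))))
    )
  )
}

#' Generate a synthetic genome
#'
#' Random sequence with, at every annotated intron boundary, planted donor /
#' acceptor dinucleotides (GT..AG for canonical introns, CC..GG otherwise,
#' strand-aware), and planted polyA hexamers near the designated fraction of
#' TTS. All other occurrences of the polyA hexamers (either strand) are
#' scrubbed so that the completion metrics equal the planted fractions
#' exactly. Byte-identical across runs for a fixed seed.
#'
#' @param spec a [fixture_spec()].
#' @return named character vector of chromosome sequences.
#' @export
generate_genome <- function(spec) {
  design <- design_fixture(spec)
  fix_seed(spec, "genome")
  chroms <- paste0("chr", seq_len(spec$n_chrom))
  genome <- stats::setNames(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1)), chroms)

  plant <- function(chrom, at, value) {
    s <- genome[[chrom]]
    substr(s, at, at + nchar(value) - 1L) <- value
    genome[[chrom]] <<- s
  }
  di <- design$introns
  for (i in seq_len(nrow(di))) {
    pair <- if (di$canonical[i]) c("GT", "AG") else c("CC", "GG")
    if (di$strand[i] == "+") {
      plant(di$chrom[i], di$start[i], pair[1])
      plant(di$chrom[i], di$end[i] - 1L, pair[2])
    } else {
      plant(di$chrom[i], di$end[i] - 1L, revcomp(pair[1]))
      plant(di$chrom[i], di$start[i], revcomp(pair[2]))
    }
  }
  for (i in seq_len(nrow(design$polya))) {
    plant(design$polya$chrom[i], design$polya$pos[i], design$polya$motif[i])
  }

  # scrub every non-planted hexamer occurrence: the motifs are A/T-only, so
  # setting one base to C destroys an occurrence and can never create one
  motifs <- c(polya_motifs, revcomp(polya_motifs))
  for (ch in names(genome)) {
    prot <- design$polya[design$polya$chrom == ch, ]
    protected <- unlist(lapply(prot$pos, function(p) p:(p + 5L)))
    s <- genome[[ch]]
    occ <- sort(unique(unlist(lapply(motifs, motif_positions, s = s))))
    occ <- setdiff(occ, prot$pos)
    for (p in occ) {
      bases <- setdiff(p:(p + 5L), protected)
      if (length(bases) == 0) next
      substr(s, bases[1], bases[1]) <- "C"
    }
    genome[[ch]] <- s
  }
  genome
}

#' Generate the synthetic reference annotation
#'
#' Non-overlapping gene loci, one transcript each, with alternating
#' protein_coding / lncRNA biotypes (so coding-lnc-coding triplets exist).
#'
#' @param spec a [fixture_spec()].
#' @param genome unused; accepted so the call mirrors the generation order
#'   (the design is fully determined by `spec`).
#' @return reference annotation tibble.
#' @export
generate_reference <- function(spec, genome = NULL) {
  design_fixture(spec)$reference
}

#' Simulate per-sample transcript assemblies
#'
#' Each sample contains a random subset of reference transcripts with
#' jittered (shrunk) terminal exons, every planted novel isoform and
#' extension in at least two samples with TPM >= 0.1, and noise transcripts
#' that fail exactly one filter: present in a single sample, or present in
#' two samples with TPM below 0.1.
#'
#' @param spec a [fixture_spec()].
#' @param reference reference annotation tibble (consistency-checked against
#'   the design).
#' @return named list of annotation tibbles (one per sample), with a
#'   `"ground_truth"` attribute.
#' @export
simulate_assemblies <- function(spec, reference) {
  design <- design_fixture(spec)
  if (!identical(reference$transcript_id, design$reference$transcript_id)) {
    stop("reference does not match the fixture design", call. = FALSE)
  }
  n_s <- spec$n_assemblies
  samples <- sprintf("sample%02d", seq_len(n_s))
  fix_seed(spec, "assemblies")
  rows_by_sample <- stats::setNames(vector("list", n_s), samples)
  add_row <- function(s, tx_row, tpm) {
    tx_row$tpm <- list(stats::setNames(tpm, samples[s]))
    tx_row$samples <- list(samples[s])
    tx_row$detection_count <- 1L
    tx_row$origin <- "novel"
    rows_by_sample[[s]] <<- c(rows_by_sample[[s]], list(tx_row))
  }
  base_row <- function(id, chrom, strand, starts, ends) {
    tibble::tibble(
      transcript_id = id, gene_id = NA_character_, chrom = chrom,
      strand = strand, exon_starts = list(as.integer(starts)),
      exon_ends = list(as.integer(ends)), origin = "novel",
      detection_count = 1L, samples = list(character()), tpm = list(numeric()),
      transcript_biotype = NA_character_, feelnc_biotype = NA_character_,
      ref_gene_id = NA_character_, contains = NA_character_
    )
  }

  ref <- design$reference
  for (i in seq_len(nrow(ref))) {
    present <- which(stats::runif(n_s) < spec$detection_prob)
    for (s in present) {
      starts <- ref$exon_starts[[i]]
      ends <- ref$exon_ends[[i]]
      starts[1] <- starts[1] + sample(0:10, 1)
      ends[length(ends)] <- ends[length(ends)] - sample(0:10, 1)
      add_row(s, base_row(paste0("asm.", ref$transcript_id[i], ".", s),
                          ref$chrom[i], ref$strand[i], starts, ends),
              max(0.1, stats::rlnorm(1, meanlog = 2, sdlog = 1)))
    }
  }
  planted <- dplyr::bind_rows(
    design$novel,
    design$extensions[, c("transcript_id", "chrom", "strand",
                          "exon_starts", "exon_ends")]
  )
  for (i in seq_len(nrow(planted))) {
    n_in <- 2L + stats::rbinom(1, n_s - 2L, 0.3)
    for (s in sample(n_s, n_in)) {
      add_row(s, base_row(paste0("asm.", planted$transcript_id[i], ".", s),
                          planted$chrom[i], planted$strand[i],
                          planted$exon_starts[[i]], planted$exon_ends[[i]]),
              stats::runif(1, 0.5, 20))
    }
  }
  for (i in seq_len(nrow(design$noise))) {
    nz <- design$noise[i, ]
    if (nz$failure_mode == "consistency") {
      add_row(sample(n_s, 1),
              base_row(paste0("asm.", nz$transcript_id), nz$chrom, nz$strand,
                       nz$exon_starts[[1]], nz$exon_ends[[1]]), 5)
    } else {
      for (s in sample(n_s, 2)) {
        add_row(s, base_row(paste0("asm.", nz$transcript_id, ".", s),
                            nz$chrom, nz$strand,
                            nz$exon_starts[[1]], nz$exon_ends[[1]]), 0.05)
      }
    }
  }
  out <- purrr::map(rows_by_sample, function(rows) {
    if (length(rows) == 0) return(annotation(tibble::tibble()))
    a <- dplyr::bind_rows(rows)
    a <- a[order(a$chrom, tx_start(as_annot(a)), a$transcript_id), ]
    annotation(a)
  })
  attr(out, "ground_truth") <- design$truth
  out
}

#' Simulate an expression matrix with planted tissue-specific genes
#'
#' Log-normal baseline TPMs over a 7-tissue x 3-stage x 4-replicate design;
#' planted tissue-specific genes are at least 50-fold higher in their target
#' tissue than anywhere else, so tau recovers them exactly.
#'
#' @param spec a [fixture_spec()].
#' @param features character vector of feature ids (e.g. gene ids of the
#'   reference annotation).
#' @return list with `matrix` (tibble, `feature_id` + one column per
#'   sample), `metadata` (sample, tissue, stage, replicate), and
#'   `specific` (tibble `feature_id`, `tissue`: the planted map).
#' @export
simulate_expression <- function(spec, features) {
  stages <- paste0("stage", seq_len(spec$n_stages))
  meta <- tidyr::expand_grid(tissue = spec$tissues, stage = stages,
                             replicate = seq_len(spec$n_replicates))
  meta$sample <- paste(meta$tissue, meta$stage, meta$replicate, sep = "_")
  fix_seed(spec, "expression")
  n_f <- length(features)
  m <- matrix(stats::rlnorm(n_f * nrow(meta), meanlog = 1, sdlog = 0.5),
              nrow = n_f,
              dimnames = list(features, meta$sample))
  n_spec <- min(spec$n_specific, n_f)
  spec_idx <- sample(n_f, n_spec)
  spec_tissue <- spec$tissues[((seq_len(n_spec) - 1) %% length(spec$tissues)) + 1]
  for (k in seq_len(n_spec)) {
    target_cols <- meta$sample[meta$tissue == spec_tissue[k]]
    other_cols <- setdiff(meta$sample, target_cols)
    m[spec_idx[k], target_cols] <- stats::runif(length(target_cols), 25, 50)
    m[spec_idx[k], other_cols] <- stats::runif(length(other_cols), 0.01, 0.5)
  }
  mat <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  mat <- dplyr::bind_cols(tibble::tibble(feature_id = features), mat)
  list(
    matrix = mat,
    metadata = meta[, c("sample", "tissue", "stage", "replicate")],
    specific = tibble::tibble(feature_id = features[spec_idx],
                              tissue = spec_tissue)
  )
}

#' Generate a shifted target annotation with a known gene map
#'
#' The target mirrors the source structures on renamed chromosomes with a
#' coordinate offset, giving a 1-to-1 coding-gene orthology map for the
#' synteny and projection fixtures.
#'
#' @param spec a [fixture_spec()].
#' @param source source annotation tibble.
#' @return list with `annotation` and `gene_map` (`source_gene`,
#'   `target_gene`).
#' @export
generate_target <- function(spec, source) {
  tgt <- tibble::as_tibble(source)
  tgt$chrom <- paste0("t", tgt$chrom)
  tgt$exon_starts <- lapply(tgt$exon_starts, function(v) v + 50L)
  tgt$exon_ends <- lapply(tgt$exon_ends, function(v) v + 50L)
  old_gene <- tgt$gene_id
  tgt$transcript_id <- sub("^SIMT", "TGTT", tgt$transcript_id)
  tgt$gene_id <- sub("^SIMG", "TGTG", tgt$gene_id)
  list(
    annotation = annotation(tgt, provenance = "reference"),
    gene_map = dplyr::distinct(tibble::tibble(source_gene = old_gene,
                                              target_gene = tgt$gene_id))
  )
}

#' Simulate PSL alignments with known true targets
#'
#' For each source transcript with a mapped target gene, one true alignment
#' covering the target transcript's exons exactly, plus decoy alignments to
#' other loci with strictly lower scores.
#'
#' @param spec a [fixture_spec()].
#' @param source source annotation tibble.
#' @param target target annotation tibble (from [generate_target()]).
#' @param gene_map tibble `source_gene`, `target_gene`.
#' @return list with `psl` (tibble in [read_psl()] layout) and `truth`
#'   (tibble `q_name`, `target_transcript`, `target_gene`).
#' @export
simulate_psl <- function(spec, source, target, gene_map) {
  fix_seed(spec, "psl")
  t_by_gene <- split(seq_len(nrow(target)), target$gene_id)
  # decoy scores are forced strictly below the true alignment's score
  # (score = matches - misMatches = 2 * matches - block total)
  mk_row <- function(qname, tgt_idx, decoy, true_score = NULL) {
    ts <- target$exon_starts[[tgt_idx]] - 1L
    sz <- target$exon_ends[[tgt_idx]] - target$exon_starts[[tgt_idx]] + 1L
    total <- sum(sz)
    mis <- if (decoy) {
      desired <- min(true_score - 20L, total - 20L)
      matches <- max(0L, (total + desired) %/% 2L)
      total - matches
    } else 0L
    tibble::tibble(
      matches = total - mis, mis_matches = mis, rep_matches = 0L,
      n_count = 0L, q_num_insert = 0L, q_base_insert = 0L,
      t_num_insert = 0L, t_base_insert = 0L,
      strand = target$strand[tgt_idx], q_name = qname, q_size = total,
      q_start = 0L, q_end = total, t_name = target$chrom[tgt_idx],
      t_size = spec$chrom_length, t_start = ts[1],
      t_end = ts[length(ts)] + sz[length(sz)],
      block_count = length(sz), block_sizes = list(sz),
      q_starts = list(c(0L, cumsum(sz)[-length(sz)])), t_starts = list(ts)
    )
  }
  rows <- list()
  truth <- list()
  for (i in seq_len(nrow(source))) {
    sg <- source$gene_id[i]
    tg <- gene_map$target_gene[gene_map$source_gene == sg]
    if (length(tg) == 0) next
    tgt_idx <- t_by_gene[[tg[1]]][1]
    qname <- source$transcript_id[i]
    true_score <- sum(target$exon_ends[[tgt_idx]] -
                        target$exon_starts[[tgt_idx]] + 1L)
    n_dec <- spec$decoys_per_query
    decoy_pool <- setdiff(seq_len(nrow(target)), tgt_idx)
    decoys <- sample(decoy_pool, min(n_dec, length(decoy_pool)))
    bundle <- c(lapply(decoys[seq_len(min(1, length(decoys)))], mk_row,
                       qname = qname, decoy = TRUE, true_score = true_score),
                list(mk_row(qname, tgt_idx, decoy = FALSE)),
                lapply(decoys[-seq_len(min(1, length(decoys)))], mk_row,
                       qname = qname, decoy = TRUE, true_score = true_score))
    rows <- c(rows, bundle)
    truth[[length(truth) + 1]] <- tibble::tibble(
      q_name = qname, target_transcript = target$transcript_id[tgt_idx],
      target_gene = tg[1]
    )
  }
  list(psl = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
}

#' Write a PSL tibble to a file
#'
#' @param psl tibble in [read_psl()] layout.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psl <- function(psl, path) {
  lst <- function(col) {
    vapply(psl[[col]], function(v) paste0(paste(v, collapse = ","), ","),
           character(1))
  }
  lines <- paste(psl$matches, psl$mis_matches, psl$rep_matches, psl$n_count,
                 psl$q_num_insert, psl$q_base_insert, psl$t_num_insert,
                 psl$t_base_insert, psl$strand, psl$q_name, psl$q_size,
                 psl$q_start, psl$q_end, psl$t_name, psl$t_size, psl$t_start,
                 psl$t_end, psl$block_count, lst("block_sizes"),
                 lst("q_starts"), lst("t_starts"), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Emit a complete fixture directory
#'
#' Generates all artifacts (genome FASTA, reference GTF, per-sample
#' assembly GTFs, peak BED, expression matrix and metadata TSVs, target
#' annotation GTF, coding-ortholog TSV, PSL alignments) plus a
#' `ground_truth.json` with every planted quantity; returns everything
#' in-memory as well.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created); `NULL` to skip writing.
#' @return invisible list with `genome`, `reference`, `assemblies`,
#'   `peaks`, `expression`, `target`, `gene_map`, `psl`, `truth`.
#' @export
simulate_fixtures <- function(spec, dir = NULL) {
  design <- design_fixture(spec)
  genome <- generate_genome(spec)
  reference <- design$reference
  assemblies <- simulate_assemblies(spec, reference)
  expr <- simulate_expression(spec, unique(reference$gene_id))
  tgt <- generate_target(spec, reference)
  psl <- simulate_psl(spec, reference, tgt$annotation, tgt$gene_map)
  truth <- design$truth
  truth$tissue_specific <- expr$specific
  truth$psl_truth <- psl$truth
  out <- list(genome = genome, reference = reference,
              assemblies = assemblies, peaks = design$peaks,
              expression = expr, target = tgt$annotation,
              gene_map = tgt$gene_map, psl = psl$psl, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(dir, "genome.fa"))
    write_gtf(reference, file.path(dir, "reference.gtf"))
    for (s in names(assemblies)) {
      write_gtf(assemblies[[s]], file.path(dir, paste0(s, ".gtf")))
    }
    bed <- design$peaks
    writeLines(paste(bed$chrom, bed$start - 1L, bed$end, sep = "\t"),
               file.path(dir, "peaks.bed"))
    utils::write.table(expr$matrix, file.path(dir, "expression_tpm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(expr$metadata, file.path(dir, "sample_metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gtf(tgt$annotation, file.path(dir, "target.gtf"))
    utils::write.table(tgt$gene_map, file.path(dir, "coding_orthologs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_psl(psl$psl, file.path(dir, "alignments.psl"))
    json_truth <- truth
    json_truth$tissue_specific <- NULL
    json_truth$psl_truth <- NULL
    jsonlite::write_json(json_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
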