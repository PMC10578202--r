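#' Read a PSL alignment file
#'
#' UCSC 21-column PSL, headerless or with the standard `psLayout` header.
#' Block lists (comma-terminated) are parsed into integer list-columns and
#' checked against `blockCount`. Source coordinates are 0-based half-open
#' and are kept as such in the `q_start`/`t_start` scalar columns; use
#' [psl_target_blocks()] for 1-based inclusive block intervals.
#'
#' @param path PSL file.
#' @return tibble with one row per alignment, in file order.
#' @export
read_psl <- function(path) {
  if (!file.exists(path)) stop("PSL file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # skip the optional psLayout header block (first field not a number)
  is_data <- grepl("^[0-9]", lines)
  lines <- lines[is_data]
  if (length(lines) == 0) {
    return(tibble::tibble(
      matches = integer(), mis_matches = integer(), rep_matches = integer(),
      n_count = integer(), q_num_insert = integer(), q_base_insert = integer(),
      t_num_insert = integer(), t_base_insert = integer(), strand = character(),
      q_name = character(), q_size = integer(), q_start = integer(),
      q_end = integer(), t_name = character(), t_size = integer(),
      t_start = integer(), t_end = integer(), block_count = integer(),
      block_sizes = list(), q_starts = list(), t_starts = list()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 21L)) {
    bad <- which(lengths(fields) != 21L)[1]
    stop("PSL parse error: row ", bad, " has ", lengths(fields)[bad],
         " columns (expected 21)", call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 21, byrow = TRUE)
  int_list <- function(col) {
    lapply(strsplit(m[, col], ",", fixed = TRUE), as.integer)
  }
  out <- tibble::tibble(
    matches = as.integer(m[, 1]), mis_matches = as.integer(m[, 2]),
    rep_matches = as.integer(m[, 3]), n_count = as.integer(m[, 4]),
    q_num_insert = as.integer(m[, 5]), q_base_insert = as.integer(m[, 6]),
    t_num_insert = as.integer(m[, 7]), t_base_insert = as.integer(m[, 8]),
    strand = m[, 9], q_name = m[, 10], q_size = as.integer(m[, 11]),
    q_start = as.integer(m[, 12]), q_end = as.integer(m[, 13]),
    t_name = m[, 14], t_size = as.integer(m[, 15]),
    t_start = as.integer(m[, 16]), t_end = as.integer(m[, 17]),
    block_count = as.integer(m[, 18]),
    block_sizes = int_list(19), q_starts = int_list(20), t_starts = int_list(21)
  )
  bad <- which(lengths(out$block_sizes) != out$block_count |
                 lengths(out$q_starts) != out$block_count |
                 lengths(out$t_starts) != out$block_count)
  if (length(bad) > 0) {
    stop("PSL parse error: row ", bad[1], " block lists do not match blockCount",
         call. = FALSE)
  }
  if (any(unlist(out$block_sizes) <= 0)) {
    stop("PSL parse error: non-positive block size", call. = FALSE)
  }
  out
}

#' Alignment score
#'
#' `score = matches + repMatches - misMatches - qNumInsert - tNumInsert`
#' (may be negative).
#'
#' @param psl tibble from [read_psl()].
#' @return integer vector of scores.
#' @export
score_alignment <- function(psl) {
  psl$matches + psl$rep_matches - psl$mis_matches -
    psl$q_num_insert - psl$t_num_insert
}

#' Best alignment per query
#'
#' The highest-scoring alignment is kept for each query; ties go to the
#' alignment with more blocks, then to the first alignment in file order.
#'
#' @param psl tibble from [read_psl()] (>= 1 row per query of interest).
#' @return tibble with one row per query, carrying a `score` column.
#' @export
best_hit <- function(psl) {
  if (nrow(psl) == 0) stop("best_hit(): no alignments", call. = FALSE)
  psl$score <- score_alignment(psl)
  psl$.file_order <- seq_len(nrow(psl))
  out <- psl |>
    dplyr::group_by(.data$q_name) |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$block_count),
                   .data$.file_order, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.file_order)
  out$.file_order <- NULL
  out
}

#' Target-side block intervals of PSL alignments
#'
#' @param psl tibble from [read_psl()].
#' @return tibble with `q_name`, `t_name`, `strand`, `start`, `end`
#'   (1-based inclusive target intervals, one row per block).
#' @export
psl_target_blocks <- function(psl) {
  rows <- purrr::map(seq_len(nrow(psl)), function(i) {
    ts <- psl$t_starts[[i]]
    sz <- psl$block_sizes[[i]]
    tibble::tibble(q_name = psl$q_name[i], t_name = psl$t_name[i],
                   strand = psl$strand[i], start = ts + 1L, end = ts + sz)
  })
  dplyr::bind_rows(rows)
}

#' Assign projected queries to target transcripts and genes
#'
#' For each best-hit alignment, the same-strand exonic overlap (in bp,
#' summed over alignment blocks and target exons) is computed against every
#' transcript of the target annotation on the hit chromosome; the transcript
#' with the largest overlap is chosen (ties to the lexicographically
#' smallest transcript id) along with its gene. Queries whose blocks overlap
#' target exons only on the opposite strand get no assignment.
#'
#' @param best_hits tibble from [best_hit()].
#' @param target target annotation tibble with `gene_id` assigned.
#' @return tibble with `q_name`, `target_transcript`, `target_gene`,
#'   `overlap_bp` (queries without assignment are absent).
#' @export
map_to_targets <- function(best_hits, target) {
  t_st <- tx_start(target)
  t_en <- tx_end(target)
  rows <- purrr::map(seq_len(nrow(best_hits)), function(i) {
    bs <- best_hits$t_starts[[i]] + 1L
    be <- best_hits$t_starts[[i]] + best_hits$block_sizes[[i]]
    cand <- which(target$chrom == best_hits$t_name[i] &
                    target$strand == best_hits$strand[i] &
                    t_st <= max(be) & t_en >= min(bs))
    if (length(cand) == 0) return(NULL)
    ov <- vapply(cand, function(j) {
      exonic_overlap_bp(bs, be, target$exon_starts[[j]], target$exon_ends[[j]])
    }, integer(1))
    cand <- cand[ov > 0]
    ov <- ov[ov > 0]
    if (length(cand) == 0) return(NULL)
    j <- cand[order(-ov, target$transcript_id[cand])][1]
    tibble::tibble(q_name = best_hits$q_name[i],
                   target_transcript = target$transcript_id[j],
                   target_gene = target$gene_id[j],
                   overlap_bp = max(ov))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(q_name = character(), target_transcript = character(),
                          target_gene = character(), overlap_bp = integer())
  }
  out
}

#' Aggregate transcript-level target hits to source genes
#'
#' @param assignments tibble from [map_to_targets()].
#' @param source source annotation tibble (maps transcript ids to gene ids).
#' @return tibble with `source_gene`, `target_gene` (distinct pairs).
#' @export
project_genes <- function(assignments, source) {
  map <- tibble::tibble(q_name = source$transcript_id,
                        source_gene = source$gene_id)
  assignments |>
    dplyr::inner_join(map, by = "q_name") |>
    dplyr::distinct(.data$source_gene, .data$target_gene)
}

#' Recovered-over-eligible percentage
#'
#' `100 * recovered / eligible`, rounded half-up to one decimal — the
#' reporting convention for every sensitivity / precision / agreement
#' summary in the package.
#'
#' @param recovered,eligible non-negative counts (`eligible > 0`).
#' @return percentage with one decimal.
#' @export
#' @examples
#' recovery_percent(11206, 12856) # 87.2
recovery_percent <- function(recovered, eligible) {
  if (any(eligible == 0)) stop("empty eligible set", call. = FALSE)
  floor(1000 * recovered / eligible + 0.5) / 10
}

#' Evaluate projection-based orthology against a truth set
#'
#' Sensitivity: among source genes that colocalize with a reference gene
#' having a known 1-to-1 ortholog, the fraction whose predicted target list
#' contains that ortholog. Precision: among truth target genes whose
#' reference partner L exists, the fraction hit by the projection of a
#' source gene colocalizing with L. Percentages are rounded half-up to one
#' decimal.
#'
#' @param predictions tibble with `source_gene`, `target_gene` (one row per
#'   predicted pair, e.g. from [project_genes()]).
#' @param truth tibble of known 1-to-1 orthology with `ref_gene`,
#'   `target_gene`.
#' @param colocalization tibble with `source_gene`, `ref_gene` (>= 1 bp
#'   same-strand exonic overlap between the source gene and the reference
#'   gene).
#' @return object of class `orthology_evaluation` with stored counts;
#'   supports [generics::tidy()] and [generics::glance()].
#' @export
evaluate_orthology <- function(predictions, truth, colocalization) {
  coloc_truth <- dplyr::inner_join(colocalization, truth, by = "ref_gene")
  eligible_src <- unique(coloc_truth$source_gene)
  if (length(eligible_src) == 0) stop("empty eligible set", call. = FALSE)
  pred_key <- paste(predictions$source_gene, predictions$target_gene)
  recovered_src <- vapply(eligible_src, function(g) {
    targets <- coloc_truth$target_gene[coloc_truth$source_gene == g]
    any(paste(g, targets) %in% pred_key)
  }, logical(1))

  eligible_tgt <- unique(truth$target_gene)
  recovered_tgt <- vapply(eligible_tgt, function(t) {
    refs <- truth$ref_gene[truth$target_gene == t]
    srcs <- colocalization$source_gene[colocalization$ref_gene %in% refs]
    any(paste(srcs, t) %in% pred_key)
  }, logical(1))

  structure(
    list(
      sensitivity_eligible = length(eligible_src),
      sensitivity_recovered = sum(recovered_src),
      sensitivity = recovery_percent(sum(recovered_src), length(eligible_src)),
      precision_eligible = length(eligible_tgt),
      precision_recovered = sum(recovered_tgt),
      precision = recovery_percent(sum(recovered_tgt), length(eligible_tgt))
    ),
    class = "orthology_evaluation"
  )
}

#' @export
print.orthology_evaluation <- function(x, ...) {
  cat(sprintf("Orthology evaluation: sensitivity %.1f%% (%d/%d), precision %.1f%% (%d/%d)\n",
              x$sensitivity, x$sensitivity_recovered, x$sensitivity_eligible,
              x$precision, x$precision_recovered, x$precision_eligible))
  invisible(x)
}

#' Tidy an orthology evaluation
#'
#' @param x an `orthology_evaluation`.
#' @param ... unused.
#' @return tibble with one row per metric: `metric`, `eligible`,
#'   `recovered`, `percent`.
#' @method tidy orthology_evaluation
#' @export
tidy.orthology_evaluation <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "precision"),
    eligible = c(x$sensitivity_eligible, x$precision_eligible),
    recovered = c(x$sensitivity_recovered, x$precision_recovered),
    percent = c(x$sensitivity, x$precision)
  )
}

#' One-row summary of an orthology evaluation
#'
#' @param x an `orthology_evaluation`.
#' @param ... unused.
#' @return tibble with `sensitivity`, `precision`.
#' @method glance orthology_evaluation
#' @export
glance.orthology_evaluation <- function(x, ...) {
  tibble::tibble(sensitivity = x$sensitivity, precision = x$precision)
}

#' Extract (coding, lnc, coding) gene triplets
#'
#' For every long non-coding gene whose immediately preceding and following
#' genes along the chromosome (irrespective of strand) are both coding, one
#' triplet is recorded. Genes of any other status between the three break
#' adjacency.
#'
#' @param genes tibble with `gene_id`, `chrom`, `start`, `coding_status`
#'   (`"mRNA"` coding, `"lncRNA"` long non-coding), e.g. from
#'   [gene_table()].
#' @return tibble with `chrom`, `left_coding`, `lnc`, `right_coding`.
#' @export
extract_triplets <- function(genes) {
  g <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  rows <- list()
  for (chrom in unique(g$chrom)) {
    gc <- g[g$chrom == chrom, ]
    if (nrow(gc) < 3) next
    for (i in 2:(nrow(gc) - 1)) {
      if (gc$coding_status[i] == "lncRNA" &&
          gc$coding_status[i - 1] == "mRNA" &&
          gc$coding_status[i + 1] == "mRNA") {
        rows[[length(rows) + 1]] <- tibble::tibble(
          chrom = chrom, left_coding = gc$gene_id[i - 1],
          lnc = gc$gene_id[i], right_coding = gc$gene_id[i + 1]
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), left_coding = character(),
                          lnc = character(), right_coding = character())
  }
  out
}

#' Infer lnc gene orthology from conserved coding-gene triplets
#'
#' A source lnc gene L is paired with a target lnc gene L' when L's flanking
#' coding genes map, through the coding-gene orthology map, to L''s flanking
#' coding genes. By default the flanking pair is treated as unordered
#' (robust to local inversions); set `ordered = TRUE` to require the
#' left/right order to be conserved.
#'
#' @param source_triplets,target_triplets tibbles from [extract_triplets()].
#' @param orthologs coding-gene orthology tibble with `source_gene`,
#'   `target_gene`.
#' @param ordered require conserved flank order (default `FALSE`).
#' @return tibble with distinct pairs `source_lnc`, `target_lnc`.
#' @export
match_triplets <- function(source_triplets, target_triplets, orthologs,
                           ordered = FALSE) {
  omap <- split(orthologs$target_gene, orthologs$source_gene)
  rows <- purrr::map(seq_len(nrow(source_triplets)), function(i) {
    a <- omap[[source_triplets$left_coding[i]]]
    b <- omap[[source_triplets$right_coding[i]]]
    if (is.null(a) || is.null(b)) return(NULL)
    hit_fwd <- target_triplets$left_coding %in% a &
      target_triplets$right_coding %in% b
    hit <- if (ordered) hit_fwd else {
      hit_fwd | (target_triplets$left_coding %in% b &
                   target_triplets$right_coding %in% a)
    }
    if (!any(hit)) return(NULL)
    tibble::tibble(source_lnc = source_triplets$lnc[i],
                   target_lnc = target_triplets$lnc[hit])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(source_lnc = character(), target_lnc = character()))
  }
  dplyr::distinct(out)
}
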