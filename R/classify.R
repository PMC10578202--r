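#' Positional classes of spliced transcripts relative to a reference
#'
#' Each spliced transcript receives the first class in priority order whose
#' predicate holds:
#' \describe{
#'   \item{Exact}{a reference transcript has exactly the same intron chain;}
#'   \item{Extension}{the transcript extends a reference transcript
#'     ([is_extension()] with the prediction as candidate): same strand,
#'     overlapping, identical chain on the overlap, the reference having at
#'     least one less intron in 5' and/or 3';}
#'   \item{Inclusion}{a reference transcript is an Extension of the
#'     prediction;}
#'   \item{Overlapping}{a same-strand overlap of >= 1 bp not qualifying
#'     above (extent overlap by default; set `overlap_mode = "exonic"` to
#'     require exon-level overlap);}
#'   \item{Intergenic_or_Antisense}{otherwise.}
#' }
#' Monoexonic transcripts are outside this five-way partition and raise an
#' error; [classify_transcripts()] labels them `Monoexonic`.
#'
#' @param x annotation tibble of spliced transcripts.
#' @param reference reference annotation tibble.
#' @param overlap_mode `"extent"` (default) or `"exonic"` for the
#'   Overlapping predicate.
#' @return character vector of classes, one per row of `x`.
#' @export
positional_class <- function(x, reference, overlap_mode = c("extent", "exonic")) {
  overlap_mode <- match.arg(overlap_mode)
  if (any(n_exons(x) < 2)) {
    stop("positional_class() is defined for spliced transcripts; ",
         "monoexonic models are classified separately", call. = FALSE)
  }
  ref_spliced_idx <- which(n_exons(reference) >= 2)
  ref_keys <- chain_key(reference)[ref_spliced_idx]
  x_keys <- chain_key(x)
  ref_st <- tx_start(reference)
  ref_en <- tx_end(reference)
  x_st <- tx_start(x)
  x_en <- tx_end(x)
  vapply(seq_len(nrow(x)), function(i) {
    same <- which(reference$chrom == x$chrom[i])
    if (x_keys[i] %in% ref_keys) return("Exact")
    spl <- intersect(same, ref_spliced_idx)
    for (j in spl) {
      if (is_extension_core(x$chrom[i], x$strand[i],
                            x$exon_starts[[i]], x$exon_ends[[i]],
                            reference$chrom[j], reference$strand[j],
                            reference$exon_starts[[j]], reference$exon_ends[[j]]))
        return("Extension")
    }
    for (j in spl) {
      if (is_extension_core(reference$chrom[j], reference$strand[j],
                            reference$exon_starts[[j]], reference$exon_ends[[j]],
                            x$chrom[i], x$strand[i],
                            x$exon_starts[[i]], x$exon_ends[[i]]))
        return("Inclusion")
    }
    ss <- same[reference$strand[same] == x$strand[i] &
                 ref_st[same] <= x_en[i] & ref_en[same] >= x_st[i]]
    if (length(ss) > 0) {
      if (overlap_mode == "extent") return("Overlapping")
      for (j in ss) {
        if (exonic_overlap_bp(x$exon_starts[[i]], x$exon_ends[[i]],
                              reference$exon_starts[[j]],
                              reference$exon_ends[[j]]) > 0)
          return("Overlapping")
      }
    }
    "Intergenic_or_Antisense"
  }, character(1))
}

# total bp of genomic overlap between two exon sets
exonic_overlap_bp <- function(s1, e1, s2, e2) {
  total <- 0L
  for (a in seq_along(s1)) {
    ov <- pmin(e1[a], e2) - pmax(s1[a], s2) + 1L
    total <- total + sum(ov[ov > 0])
  }
  total
}

#' Transcript novelty: known vs unknown
#'
#' A transcript is known when its exon-intron structure exactly corresponds
#' to a reference transcript: for spliced transcripts, an identical intron
#' chain on the same chromosome and strand; for monoexonic transcripts,
#' identical (chromosome, strand, start, end) with a reference monoexonic
#' transcript (set `monoexonic_match = "overlap"` for the laxer stranded-
#' overlap reading).
#'
#' @param x annotation tibble.
#' @param reference reference annotation tibble.
#' @param monoexonic_match `"coordinates"` (default) or `"overlap"`.
#' @return character vector, `"known"` or `"unknown"` per transcript.
#' @export
transcript_novelty <- function(x, reference,
                               monoexonic_match = c("coordinates", "overlap")) {
  monoexonic_match <- match.arg(monoexonic_match)
  ref_spl <- n_exons(reference) >= 2
  ref_keys <- chain_key(reference)[ref_spl]
  ref_mono <- reference[!ref_spl, ]
  rm_st <- tx_start(ref_mono)
  rm_en <- tx_end(ref_mono)
  x_keys <- chain_key(x)
  x_st <- tx_start(x)
  x_en <- tx_end(x)
  spl <- n_exons(x) >= 2
  out <- character(nrow(x))
  out[spl] <- ifelse(x_keys[spl] %in% ref_keys, "known", "unknown")
  for (i in which(!spl)) {
    hit <- if (monoexonic_match == "coordinates") {
      any(ref_mono$chrom == x$chrom[i] & ref_mono$strand == x$strand[i] &
            rm_st == x_st[i] & rm_en == x_en[i])
    } else {
      any(ref_mono$chrom == x$chrom[i] & ref_mono$strand == x$strand[i] &
            rm_st <= x_en[i] & rm_en >= x_st[i])
    }
    out[i] <- if (hit) "known" else "unknown"
  }
  out
}

#' Gene novelty from member transcript novelties
#'
#' A gene is `known` if all its transcripts are known, `unknown` if all are
#' unknown, and `enriched` otherwise.
#'
#' @param novelties character vector of `"known"`/`"unknown"` labels for the
#'   member transcripts of one gene.
#' @return one of `"known"`, `"enriched"`, `"unknown"`.
#' @export
gene_novelty <- function(novelties) {
  if (length(novelties) == 0) stop("gene with no transcripts", call. = FALSE)
  if (all(novelties == "known")) return("known")
  if (all(novelties == "unknown")) return("unknown")
  "enriched"
}

#' Long non-coding candidate eligibility
#'
#' A transcript is an lncRNA classification candidate when it is longer than
#' 200 bp of spliced (exonic) length, has no same-strand exonic overlap with
#' any reference mRNA transcript, and has either strictly more than two
#' exons or exactly two exons both longer than 25 bp.
#'
#' @param x annotation tibble.
#' @param reference reference annotation tibble; its mRNAs are the
#'   transcripts with `transcript_biotype` `"protein_coding"` or `"mRNA"`.
#' @return logical vector per transcript of `x`.
#' @export
feelnc_eligible <- function(x, reference) {
  mrna <- reference[!is.na(reference$transcript_biotype) &
                      reference$transcript_biotype %in% c("protein_coding", "mRNA"), ]
  feats <- transcript_features(x)
  vapply(seq_len(nrow(x)), function(i) {
    if (feats$exonic_length[i] <= 200L) return(FALSE)
    ne <- feats$n_exons[i]
    if (ne < 2) return(FALSE)
    if (ne == 2) {
      lens <- x$exon_ends[[i]] - x$exon_starts[[i]] + 1L
      if (any(lens <= 25L)) return(FALSE)
    }
    cand <- which(mrna$chrom == x$chrom[i] & mrna$strand == x$strand[i])
    for (j in cand) {
      if (exonic_overlap_bp(x$exon_starts[[i]], x$exon_ends[[i]],
                            mrna$exon_starts[[j]], mrna$exon_ends[[j]]) > 0)
        return(FALSE)
    }
    TRUE
  }, logical(1))
}

#' Unified transcript biotype
#'
#' Combines the reference biotype and the FEELnc-style biotype into one
#' label, giving priority to coding labels in case of conflict:
#' `protein_coding`/`mRNA` from either source wins, then `lncRNA`, then
#' `TUCp`, then `noORF`; transcripts with neither label (or with labels
#' outside this vocabulary) are `uncharacterized`.
#'
#' @param x annotation tibble with `transcript_biotype` and
#'   `feelnc_biotype` columns.
#' @return character vector of unified biotypes.
#' @export
unified_transcript_biotype <- function(x) {
  ref <- x$transcript_biotype
  fee <- x$feelnc_biotype
  coding <- c("protein_coding", "mRNA")
  dplyr::case_when(
    ref %in% coding | fee %in% coding ~ "mRNA",
    (!is.na(ref) & ref == "lncRNA") | (!is.na(fee) & fee == "lncRNA") ~ "lncRNA",
    !is.na(fee) & fee == "TUCp" ~ "TUCp",
    !is.na(fee) & fee == "noORF" ~ "noORF",
    TRUE ~ "uncharacterized"
  )
}

#' Gene coding status from member transcript biotypes
#'
#' A gene with at least one mRNA transcript is `mRNA` (coding); otherwise a
#' gene with at least one lncRNA transcript is `lncRNA`; otherwise it is
#' `uncharacterized`.
#'
#' @param biotypes character vector of unified transcript biotypes of one
#'   gene's members.
#' @return one of `"mRNA"`, `"lncRNA"`, `"uncharacterized"`.
#' @export
gene_coding_status <- function(biotypes) {
  if (length(biotypes) == 0) stop("gene with no transcripts", call. = FALSE)
  if (any(biotypes == "mRNA")) return("mRNA")
  if (any(biotypes == "lncRNA")) return("lncRNA")
  "uncharacterized"
}

#' Position of lncRNA transcripts relative to their closest mRNA
#'
#' An lncRNA overlapping an mRNA transcript extent is `genic` (sub-location
#' `exonic` when at least 1 bp of exon-level overlap with that mRNA exists,
#' else `intronic`); otherwise the nearest mRNA within `window` bp defines
#' the `intergenic` direction (`upstream`/`downstream` relative to the
#' mRNA's orientation). Orientation is `sense`/`antisense` by strand
#' equality; intergenic antisense lncRNAs are additionally labelled
#' `divergent` (upstream) or `convergent` (downstream). With no mRNA in the
#' window the scope is `unclassified`.
#'
#' @param lnc annotation tibble of lncRNA transcripts.
#' @param mrna annotation tibble of mRNA (coding) transcripts.
#' @param window search window in bp (default 100000).
#' @return tibble with `transcript_id`, `scope`, `sublocation`,
#'   `orientation`, `label`, `closest_mrna`, `distance`.
#' @export
classify_lnc_position <- function(lnc, mrna, window = 100000L) {
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  m_st <- tx_start(mrna)
  m_en <- tx_end(mrna)
  l_st <- tx_start(lnc)
  l_en <- tx_end(lnc)
  rows <- purrr::map(seq_len(nrow(lnc)), function(i) {
    out <- tibble::tibble(
      transcript_id = lnc$transcript_id[i], scope = "unclassified",
      sublocation = NA_character_, orientation = NA_character_,
      label = NA_character_, closest_mrna = NA_character_,
      distance = NA_integer_
    )
    same <- which(mrna$chrom == lnc$chrom[i])
    if (length(same) == 0) return(out)
    ov <- pmin(m_en[same], l_en[i]) - pmax(m_st[same], l_st[i]) + 1L
    genic <- same[ov > 0]
    if (length(genic) > 0) {
      j <- genic[order(-ov[ov > 0], mrna$transcript_id[genic])][1]
      exonic <- exonic_overlap_bp(lnc$exon_starts[[i]], lnc$exon_ends[[i]],
                                  mrna$exon_starts[[j]], mrna$exon_ends[[j]]) > 0
      out$scope <- "genic"
      out$sublocation <- if (exonic) "exonic" else "intronic"
      out$orientation <- if (mrna$strand[j] == lnc$strand[i]) "sense" else "antisense"
      out$closest_mrna <- mrna$transcript_id[j]
      out$distance <- 0L
      return(out)
    }
    gap <- ifelse(m_en[same] < l_st[i], l_st[i] - m_en[same],
                  m_st[same] - l_en[i])
    near <- same[gap <= window]
    if (length(near) == 0) return(out)
    j <- near[order(gap[gap <= window], mrna$transcript_id[near])][1]
    d <- gap[match(j, same)]
    lnc_is_left <- l_en[i] < m_st[j]
    upstream <- (mrna$strand[j] == "+" && lnc_is_left) ||
      (mrna$strand[j] == "-" && !lnc_is_left)
    anti <- mrna$strand[j] != lnc$strand[i]
    out$scope <- "intergenic"
    out$sublocation <- if (upstream) "upstream" else "downstream"
    out$orientation <- if (anti) "antisense" else "sense"
    out$label <- if (anti && upstream) "divergent"
      else if (anti) "convergent" else NA_character_
    out$closest_mrna <- mrna$transcript_id[j]
    out$distance <- as.integer(d)
    out
  })
  dplyr::bind_rows(rows)
}

#' Match transcripts against an external catalog annotation
#'
#' A monoexonic transcript matches when it strandedly overlaps a monoexonic
#' catalog transcript; a spliced transcript matches when it shares at least
#' one identical intron (chromosome, strand, start, end) with a catalog
#' transcript.
#'
#' @param x annotation tibble.
#' @param catalog catalog annotation tibble.
#' @return logical vector per transcript of `x`.
#' @export
catalog_match <- function(x, catalog) {
  cat_introns <- introns(catalog)
  cat_keys <- paste(cat_introns$chrom, cat_introns$strand,
                    cat_introns$start, cat_introns$end)
  cat_mono <- catalog[n_exons(catalog) == 1, ]
  cm_st <- tx_start(cat_mono)
  cm_en <- tx_end(cat_mono)
  x_st <- tx_start(x)
  x_en <- tx_end(x)
  vapply(seq_len(nrow(x)), function(i) {
    ic <- intron_chain(x$exon_starts[[i]], x$exon_ends[[i]])
    if (length(ic$starts) > 0) {
      any(paste(x$chrom[i], x$strand[i], ic$starts, ic$ends) %in% cat_keys)
    } else {
      any(cat_mono$chrom == x$chrom[i] & cat_mono$strand == x$strand[i] &
            cm_st <= x_en[i] & cm_en >= x_st[i])
    }
  }, logical(1))
}

#' Full transcript classification table
#'
#' Combines positional classes (spliced transcripts; monoexonic models are
#' labelled `Monoexonic`), known/unknown transcript novelty,
#' known/enriched/unknown gene novelty, unified biotypes, gene coding
#' status, lncRNA positional context (against the annotation's own mRNA
#' transcripts) and optionally catalog matching.
#'
#' @param x annotation tibble with `gene_id` assigned.
#' @param reference reference annotation tibble.
#' @param catalog optional catalog annotation tibble.
#' @param lnc_window window for [classify_lnc_position()].
#' @return tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `positional_class`, `novelty`, `gene_novelty`, `unified_biotype`,
#'   `gene_status`, `lnc_position`, `catalog_match`.
#' @export
classify_transcripts <- function(x, reference, catalog = NULL,
                                 lnc_window = 100000L) {
  spl <- n_exons(x) >= 2
  pclass <- character(nrow(x))
  pclass[!spl] <- "Monoexonic"
  if (any(spl)) pclass[spl] <- positional_class(x[spl, ], reference)
  novelty <- transcript_novelty(x, reference)
  biotype <- unified_transcript_biotype(x)
  out <- tibble::tibble(
    transcript_id = x$transcript_id,
    gene_id = x$gene_id,
    positional_class = pclass,
    novelty = novelty,
    unified_biotype = biotype
  )
  out <- out |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(
      gene_novelty = gene_novelty(.data$novelty),
      gene_status = gene_coding_status(.data$unified_biotype)
    ) |>
    dplyr::ungroup()
  lnc_rows <- which(biotype == "lncRNA")
  out$lnc_position <- NA_character_
  if (length(lnc_rows) > 0) {
    mrna <- x[biotype == "mRNA", ]
    pos <- classify_lnc_position(x[lnc_rows, ], mrna, window = lnc_window)
    out$lnc_position[lnc_rows] <- ifelse(
      pos$scope == "unclassified", "unclassified",
      paste(pos$scope, pos$sublocation, pos$orientation,
            ifelse(is.na(pos$label), "", pos$label), sep = ":") |>
        sub(pattern = ":$", replacement = "")
    )
  }
  out$catalog_match <- if (!is.null(catalog)) catalog_match(x, catalog) else NA
  out
}
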