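#' Read a GTF file into an annotation tibble
#'
#' Exon features are grouped by `transcript_id`; all other feature types are
#' ignored for structure. Attributes recognised on exon rows are `gene_id`,
#' `transcript_id`, `transcript_biotype`, `feelnc_biotype`, `ref_gene_id`,
#' `contains`, `origin`, `detection_count`, and the per-assembly TPM under
#' the key named by `tpm_attribute` (StringTie writes `TPM`).
#'
#' Unstranded (`.`) transcripts are dropped with a warning giving their
#' count, because every downstream rule is strand-aware; set
#' `drop_unstranded = FALSE` to make this a hard error.
#'
#' @param path GTF file path.
#' @param tpm_attribute attribute key carrying the assembly TPM (default
#'   `"TPM"`).
#' @param sample optional sample name; when given, parsed TPMs are stored as
#'   per-sample values under this name and the transcript's `samples` list
#'   is initialised to it.
#' @param provenance provenance label for the returned set.
#' @param drop_unstranded drop unstranded transcripts (default) or error.
#' @return an annotation tibble (see [annotation()]).
#' @export
read_gtf <- function(path, tpm_attribute = "TPM", sample = NULL,
                     provenance = NULL, drop_unstranded = TRUE) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(annotation(tibble::tibble(), provenance = provenance %||% "merged"))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1]]
    stop("GTF parse error at line ", bad, " of ", path,
         ": expected 9 tab-separated columns, found ", nf[which(nf != 9L)[1]],
         call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  is_exon <- m[, 3] == "exon"
  if (!any(is_exon)) {
    return(annotation(tibble::tibble(), provenance = provenance %||% "merged"))
  }
  m <- m[is_exon, , drop = FALSE]
  line_no <- idx[is_exon]
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    bad <- line_no[which(is.na(start) | is.na(end))[1]]
    stop("GTF parse error at line ", bad, " of ", path,
         ": unparsable coordinates", call. = FALSE)
  }
  if (any(end < start)) {
    bad <- line_no[which(end < start)[1]]
    stop("GTF parse error at line ", bad, " of ", path,
         ": exon end < start", call. = FALSE)
  }
  attr_str <- m[, 9]
  get_attr <- function(key) {
    mm <- stringr::str_match(attr_str,
                             paste0("(?:^|; ?)", key, "\\s+\"?([^\";]*)\"?"))
    mm[, 2]
  }
  tid <- get_attr("transcript_id")
  gid <- get_attr("gene_id")
  if (anyNA(tid)) {
    bad <- line_no[which(is.na(tid))[1]]
    stop("GTF parse error at line ", bad, " of ", path,
         ": exon feature without transcript_id attribute", call. = FALSE)
  }
  ex <- tibble::tibble(
    transcript_id = tid, gene_id = gid, chrom = m[, 1], strand = m[, 7],
    start = start, end = end, line = line_no,
    transcript_biotype = get_attr("transcript_biotype"),
    feelnc_biotype = get_attr("feelnc_biotype"),
    ref_gene_id = get_attr("ref_gene_id"),
    contains = get_attr("contains"),
    origin = get_attr("origin"),
    detection_count = suppressWarnings(as.integer(get_attr("detection_count"))),
    tpm_val = suppressWarnings(as.numeric(get_attr(tpm_attribute)))
  )

  # unstranded transcripts: count and drop (or error)
  unstranded_ids <- unique(ex$transcript_id[!ex$strand %in% c("+", "-")])
  if (length(unstranded_ids) > 0) {
    if (!drop_unstranded) {
      stop(length(unstranded_ids), " unstranded transcript(s) in ", path,
           " (first: ", unstranded_ids[1], ")", call. = FALSE)
    }
    warning("dropped ", length(unstranded_ids),
            " unstranded transcript(s) from ", path, call. = FALSE)
    ex <- ex[!ex$transcript_id %in% unstranded_ids, ]
  }
  if (nrow(ex) == 0) {
    return(annotation(tibble::tibble(), provenance = provenance %||% "merged"))
  }

  grouped <- ex |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      gene_id = first_non_na(.data$gene_id),
      chrom = .data$chrom[1],
      n_chrom = dplyr::n_distinct(.data$chrom),
      strand = .data$strand[1],
      n_strand = dplyr::n_distinct(.data$strand),
      exon_starts = list(.data$start),
      exon_ends = list(.data$end),
      dup_exon = anyDuplicated(paste(.data$start, .data$end)) > 0,
      transcript_biotype = first_non_na(.data$transcript_biotype),
      feelnc_biotype = first_non_na(.data$feelnc_biotype),
      ref_gene_id = first_non_na(.data$ref_gene_id),
      contains = first_non_na(.data$contains),
      origin_attr = first_non_na(.data$origin),
      detection_max = if (all(is.na(.data$detection_count))) NA_integer_ else
        max(.data$detection_count, na.rm = TRUE),
      tpm_val = if (all(is.na(.data$tpm_val))) NA_real_ else
        max(.data$tpm_val, na.rm = TRUE),
      .groups = "drop"
    )
  if (any(grouped$n_chrom > 1 | grouped$n_strand > 1)) {
    bad <- grouped$transcript_id[which(grouped$n_chrom > 1 | grouped$n_strand > 1)[1]]
    stop("transcript ", bad, " in ", path,
         " has exons on multiple chromosomes or strands", call. = FALSE)
  }
  if (any(grouped$dup_exon)) {
    bad <- grouped$transcript_id[which(grouped$dup_exon)[1]]
    stop("duplicate exon for transcript ", bad, " in ", path, call. = FALSE)
  }

  sample_name <- sample %||% "assembly"
  tpm_list <- lapply(grouped$tpm_val, function(v) {
    if (is.na(v)) stats::setNames(numeric(), character())
    else stats::setNames(v, sample_name)
  })
  samples_list <- lapply(seq_len(nrow(grouped)), function(i) {
    if (!is.null(sample)) sample else character()
  })
  out <- tibble::tibble(
    transcript_id = grouped$transcript_id,
    gene_id = grouped$gene_id,
    chrom = grouped$chrom,
    strand = grouped$strand,
    exon_starts = grouped$exon_starts,
    exon_ends = grouped$exon_ends,
    origin = dplyr::coalesce(grouped$origin_attr,
                             rep(if (is.null(sample)) "reference" else "novel",
                                 nrow(grouped))),
    detection_count = dplyr::coalesce(grouped$detection_max,
                                      if (is.null(sample)) 0L else 1L),
    samples = samples_list,
    tpm = tpm_list,
    transcript_biotype = grouped$transcript_biotype,
    feelnc_biotype = grouped$feelnc_biotype,
    ref_gene_id = grouped$ref_gene_id,
    contains = grouped$contains
  )
  prov <- provenance %||% (if (is.null(sample)) "reference"
                           else paste0("sample:", sample))
  annotation(out, provenance = prov)
}

#' Write an annotation tibble as GTF
#'
#' Emits one exon row per exon, sorted by (chromosome, start,
#' transcript_id), with attributes serialised as `key "value";` pairs.
#' Reading the result back with [read_gtf()] reproduces the exon structures
#' and the attributes listed in [read_gtf()]; per-sample TPMs are written as
#' a single `TPM` attribute holding the across-sample maximum (the value the
#' expression filter uses).
#'
#' @param x annotation tibble.
#' @param path output file path.
#' @param source value for the GTF source column (default `"annotweave"`).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path, source = "annotweave") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#gtf-version 2.2", con)
  if (nrow(x) == 0) return(invisible(path))
  mt <- max_tpm(x)
  rows <- purrr::map(seq_len(nrow(x)), function(i) {
    attrs <- c(
      gene_id = x$gene_id[i] %|na|% "NA",
      transcript_id = x$transcript_id[i],
      transcript_biotype = x$transcript_biotype[i],
      feelnc_biotype = x$feelnc_biotype[i],
      ref_gene_id = x$ref_gene_id[i],
      contains = x$contains[i],
      origin = x$origin[i],
      detection_count = as.character(x$detection_count[i]),
      TPM = if (length(x$tpm[[i]]) > 0) {
        format(mt[i], scientific = FALSE, digits = 15)
      } else NA_character_
    )
    attrs <- attrs[!is.na(attrs)]
    attr_str <- paste0(names(attrs), " \"", attrs, "\";", collapse = " ")
    tibble::tibble(
      chrom = x$chrom[i], start = x$exon_starts[[i]], end = x$exon_ends[[i]],
      strand = x$strand[i], transcript_id = x$transcript_id[i],
      attr = attr_str
    )
  })
  ex <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$chrom, .data$start, .data$transcript_id)
  writeLines(
    paste(ex$chrom, source, "exon", ex$start, ex$end, ".", ex$strand, ".",
          ex$attr, sep = "\t"),
    con
  )
  invisible(path)
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

`%||%` <- function(a, b) if (is.null(a)) b else a
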