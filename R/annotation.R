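#' Build an annotation tibble
#'
#' The central container of annotweave is a tibble with one row per
#' transcript, carrying the exon structure in list-columns. All coordinates
#' are 1-based inclusive genomic positions; exons are stored in ascending
#' genomic order regardless of strand.
#'
#' Columns:
#' \describe{
#'   \item{transcript_id}{character, unique.}
#'   \item{gene_id}{character (may be `NA` before gene assignment).}
#'   \item{chrom, strand}{character; strand is `"+"` or `"-"`.}
#'   \item{exon_starts, exon_ends}{list of integer vectors, sorted,
#'     non-overlapping, non-adjacent (consecutive exons are separated by at
#'     least one intronic base).}
#'   \item{origin}{`"reference"` or `"novel"`.}
#'   \item{detection_count}{integer, number of input transcriptomes the
#'     model was seen in.}
#'   \item{samples}{list of character vectors naming those transcriptomes.}
#'   \item{tpm}{list of named numeric vectors, per-sample TPM.}
#'   \item{transcript_biotype, feelnc_biotype, ref_gene_id, contains}{
#'     character attributes (comma-separated lists where multi-valued).}
#' }
#'
#' @param transcripts a data frame with at least `transcript_id`, `chrom`,
#'   `strand`, `exon_starts`, `exon_ends`; missing bookkeeping columns are
#'   filled with defaults.
#' @param provenance label for the set: `"reference"`, `"sample:<name>"`, or
#'   `"merged"`.
#' @return a tibble of class `annot_tbl`.
#' @export
annotation <- function(transcripts, provenance = "merged") {
  x <- tibble::as_tibble(transcripts)
  if (nrow(x) == 0 && !"transcript_id" %in% names(x)) {
    x <- tibble::tibble(
      transcript_id = character(), chrom = character(), strand = character(),
      exon_starts = list(), exon_ends = list()
    )
  }
  need <- c("transcript_id", "chrom", "strand", "exon_starts", "exon_ends")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("annotation(): missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(x)
  if (!"gene_id" %in% names(x)) x$gene_id <- rep(NA_character_, n)
  if (!"origin" %in% names(x)) x$origin <- rep("novel", n)
  if (!"detection_count" %in% names(x)) x$detection_count <- rep(0L, n)
  if (!"samples" %in% names(x)) x$samples <- rep(list(character()), n)
  if (!"tpm" %in% names(x)) x$tpm <- rep(list(stats::setNames(numeric(), character())), n)
  for (col in c("transcript_biotype", "feelnc_biotype", "ref_gene_id", "contains")) {
    if (!col %in% names(x)) x[[col]] <- rep(NA_character_, n)
  }
  x$exon_starts <- lapply(x$exon_starts, function(v) as.integer(v))
  x$exon_ends <- lapply(x$exon_ends, function(v) as.integer(v))
  x$detection_count <- as.integer(x$detection_count)
  x <- x[, unique(c(need[1], "gene_id", need[-1], "origin", "detection_count",
                    "samples", "tpm", "transcript_biotype", "feelnc_biotype",
                    "ref_gene_id", "contains", names(x)))]
  x <- validate_annotation(x)
  attr(x, "provenance") <- provenance
  class(x) <- unique(c("annot_tbl", class(x)))
  x
}

#' Validate the structural invariants of an annotation tibble
#'
#' Checks transcript-id uniqueness, strand values, and exon structure
#' (at least one exon, strictly increasing starts, end >= start, consecutive
#' exons separated by >= 1 bp).
#'
#' @param x annotation tibble.
#' @return `x`, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_annotation <- function(x) {
  if (anyDuplicated(x$transcript_id)) {
    dup <- x$transcript_id[duplicated(x$transcript_id)][1]
    stop("duplicate transcript_id: ", dup, call. = FALSE)
  }
  bad_strand <- !x$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("invalid strand for transcript ", x$transcript_id[which(bad_strand)[1]],
         " (must be '+' or '-')", call. = FALSE)
  }
  for (i in seq_len(nrow(x))) {
    s <- x$exon_starts[[i]]
    e <- x$exon_ends[[i]]
    id <- x$transcript_id[i]
    if (length(s) == 0 || length(s) != length(e)) {
      stop("transcript ", id, ": needs >= 1 exon with matching starts/ends",
           call. = FALSE)
    }
    if (any(e < s)) stop("transcript ", id, ": exon end < start", call. = FALSE)
    if (length(s) > 1) {
      if (any(diff(s) <= 0)) {
        stop("transcript ", id, ": exon starts must strictly increase",
             call. = FALSE)
      }
      gap <- s[-1] - e[-length(e)] - 1L
      if (any(gap < 1L)) {
        stop("transcript ", id, ": overlapping or adjacent exons",
             call. = FALSE)
      }
    }
  }
  invisible(x)
}

# restore annot_tbl class/attributes after dplyr verbs strip them
as_annot <- function(x, provenance = "merged") {
  x <- tibble::as_tibble(x)
  attr(x, "provenance") <- provenance
  class(x) <- unique(c("annot_tbl", class(x)))
  x
}

#' Intron chain of a transcript
#'
#' Introns are the 1-based inclusive gaps between consecutive exons: for
#' exons `(100,200),(300,400)` the single intron is `(201,299)`. Monoexonic
#' transcripts have an empty chain.
#'
#' @param exon_starts,exon_ends integer vectors of exon coordinates (sorted).
#' @return a list with integer vectors `starts` and `ends` (possibly empty).
#' @export
#' @examples
#' intron_chain(c(100L, 300L), c(200L, 400L))
intron_chain <- function(exon_starts, exon_ends) {
  n <- length(exon_starts)
  if (n < 2) return(list(starts = integer(), ends = integer()))
  list(
    starts = exon_ends[-n] + 1L,
    ends = exon_starts[-1] - 1L
  )
}

#' Intron-chain identity keys
#'
#' One string per transcript encoding (chromosome, strand, intron chain);
#' two spliced transcripts are chain-identical exactly when their keys are
#' equal. Monoexonic transcripts get an empty chain part and must never be
#' chain-matched.
#'
#' @param x annotation tibble.
#' @return character vector of keys.
#' @export
chain_key <- function(x) {
  vapply(seq_len(nrow(x)), function(i) {
    ic <- intron_chain(x$exon_starts[[i]], x$exon_ends[[i]])
    paste0(x$chrom[i], "|", x$strand[i], "|",
           paste(ic$starts, ic$ends, sep = "-", collapse = ";"))
  }, character(1))
}

n_exons <- function(x) lengths(x$exon_starts)

tx_start <- function(x) vapply(x$exon_starts, function(v) v[1], integer(1))

tx_end <- function(x) vapply(x$exon_ends, function(v) v[length(v)], integer(1))

#' Per-transcript genomic features
#'
#' Convenience accessor adding scalar columns derived from the exon
#' structure: `start`, `end` (genomic extent), `n_exons`, `exonic_length`
#' (sum of exon lengths), `tss` and `tts` (5'-most and 3'-most position on
#' the transcript strand).
#'
#' @param x annotation tibble.
#' @return `x` with the derived columns appended.
#' @export
transcript_features <- function(x) {
  st <- tx_start(x)
  en <- tx_end(x)
  plus <- x$strand == "+"
  dplyr::mutate(
    tibble::as_tibble(x),
    start = st,
    end = en,
    n_exons = n_exons(x),
    exonic_length = vapply(
      seq_len(nrow(x)),
      function(i) sum(x$exon_ends[[i]] - x$exon_starts[[i]] + 1L),
      integer(1)
    ),
    tss = ifelse(plus, st, en),
    tts = ifelse(plus, en, st)
  )
}

#' Distinct introns of an annotation
#'
#' @param x annotation tibble.
#' @param distinct deduplicate on (chrom, strand, start, end)? Default `TRUE`.
#' @return tibble with columns `chrom`, `strand`, `start`, `end` (and
#'   `transcript_id` when `distinct = FALSE`).
#' @export
introns <- function(x, distinct = TRUE) {
  rows <- purrr::map(seq_len(nrow(x)), function(i) {
    ic <- intron_chain(x$exon_starts[[i]], x$exon_ends[[i]])
    if (length(ic$starts) == 0) return(NULL)
    tibble::tibble(
      transcript_id = x$transcript_id[i], chrom = x$chrom[i],
      strand = x$strand[i], start = ic$starts, end = ic$ends
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(transcript_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer())
  }
  if (distinct) {
    out <- dplyr::distinct(out, .data$chrom, .data$strand, .data$start, .data$end)
  }
  out
}

#' Summarize genes of an annotation
#'
#' One row per gene with its extent, member count and (when the annotation
#' carries biotype labels) a coding status via [gene_coding_status()].
#'
#' @param x annotation tibble with `gene_id` assigned.
#' @return tibble with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `n_transcripts`, `coding_status`.
#' @export
gene_table <- function(x) {
  if (any(is.na(x$gene_id))) {
    stop("gene_table(): gene_id missing; run assign_gene_ids() first",
         call. = FALSE)
  }
  feats <- transcript_features(x)
  feats$unified_biotype <- unified_transcript_biotype(x)
  out <- feats |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      start = min(.data$start),
      end = max(.data$end),
      n_transcripts = dplyr::n(),
      coding_status = gene_coding_status(.data$unified_biotype),
      .groups = "drop"
    )
  out
}

# merged per-sample TPM: elementwise maximum over named numeric vectors
merge_tpm <- function(tpms) {
  all_names <- unique(unlist(lapply(tpms, names)))
  if (length(all_names) == 0) return(stats::setNames(numeric(), character()))
  out <- stats::setNames(rep(-Inf, length(all_names)), all_names)
  for (v in tpms) {
    if (length(v) == 0) next
    out[names(v)] <- pmax(out[names(v)], v)
  }
  out[sort(names(out))]
}

max_tpm <- function(x) {
  vapply(x$tpm, function(v) if (length(v) == 0) 0 else max(v), numeric(1))
}

# combine comma-separated attribute lists, dropping NA, keeping sorted unique
combine_csv <- function(...) {
  vals <- unlist(stringr::str_split(stats::na.omit(c(...)), ","))
  vals <- sort(unique(vals[vals != ""]))
  if (length(vals) == 0) NA_character_ else paste(vals, collapse = ",")
}

first_non_na <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_character_ else v[1]
}

#' @export
print.annot_tbl <- function(x, ...) {
  cat("# annotweave annotation (", attr(x, "provenance") %||% "merged", "): ",
      nrow(x), " transcripts\n", sep = "")
  NextMethod()
}
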