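#' Read a genome FASTA into a named character vector
#'
#' Sequences are uppercased and restricted to the `A/C/G/T/N` alphabet;
#' chromosome names are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence", conditionMessage(w))) {
        stop("FASTA sequence in ", path,
             " contains characters outside {A,C,G,T,N}", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(ss) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence ", names(seqs)[which(bad)[1]],
         " contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over `A/C/G/T/N`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# fetch genome bases [start, end] 1-based inclusive, with bounds checking
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("chromosome ", chrom, " not in genome", call. = FALSE)
  }
  len <- nchar(genome[[chrom]])
  if (start < 1 || end > len || end < start) {
    stop("coordinates [", start, ",", end, "] out of bounds for ", chrom,
         " (length ", len, ")", call. = FALSE)
  }
  substr(genome[[chrom]], start, end)
}

#' Read a BED file of (strandless) peak intervals
#'
#' BED is 0-based half-open; intervals are converted to 1-based inclusive at
#' ingestion so that all internal coordinates share one convention.
#'
#' @param path BED file (>= 3 columns).
#' @return tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    stop("BED parse error in ", path, ": fewer than 3 columns", call. = FALSE)
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  s0 <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  e0 <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  if (anyNA(s0) || anyNA(e0) || any(e0 <= s0)) {
    stop("BED parse error in ", path, ": invalid interval", call. = FALSE)
  }
  tibble::tibble(chrom = chrom, start = s0 + 1L, end = e0)
}
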