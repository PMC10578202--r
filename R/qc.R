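#' Donor and acceptor dinucleotides of introns
#'
#' On the + strand the donor is the first two intronic bases and the
#' acceptor the last two; on the - strand they are the reverse complements
#' of the last two and first two forward-strand bases respectively.
#'
#' @param genome named character vector from [read_fasta()].
#' @param chrom,strand,start,end vectors describing introns (1-based
#'   inclusive, forward-strand coordinates). Introns shorter than 4 bp are
#'   rejected (donor and acceptor would overlap).
#' @return tibble with columns `donor`, `acceptor`.
#' @export
splice_dinucleotides <- function(genome, chrom, strand, start, end) {
  n <- length(chrom)
  donor <- acceptor <- character(n)
  for (i in seq_len(n)) {
    if (end[i] - start[i] + 1L < 4L) {
      stop("intron [", start[i], ",", end[i], "] on ", chrom[i],
           " is shorter than 4 bp", call. = FALSE)
    }
    left <- genome_slice(genome, chrom[i], start[i], start[i] + 1L)
    right <- genome_slice(genome, chrom[i], end[i] - 1L, end[i])
    if (strand[i] == "+") {
      donor[i] <- left
      acceptor[i] <- right
    } else {
      donor[i] <- revcomp(right)
      acceptor[i] <- revcomp(left)
    }
  }
  tibble::tibble(donor = donor, acceptor = acceptor)
}

#' Is a donor/acceptor pair canonical?
#'
#' Canonical pairs are (GT,AG), (GC,AG) and (AT,AC).
#'
#' @param donor,acceptor character vectors of dinucleotides.
#' @return logical vector.
#' @export
is_canonical <- function(donor, acceptor) {
  paste(donor, acceptor) %in% c("GT AG", "GC AG", "AT AC")
}

#' Fraction of distinct introns with canonical splice sites
#'
#' Introns are deduplicated on (chromosome, strand, start, end) before
#' counting.
#'
#' @param x annotation tibble.
#' @param genome named character vector from [read_fasta()].
#' @return numeric fraction in \[0,1\], with integer attributes `numerator`
#'   and `denominator`.
#' @export
canonicity_fraction <- function(x, genome) {
  di <- introns(x, distinct = TRUE)
  if (nrow(di) == 0) {
    return(structure(NA_real_, numerator = 0L, denominator = 0L))
  }
  dn <- splice_dinucleotides(genome, di$chrom, di$strand, di$start, di$end)
  num <- sum(is_canonical(dn$donor, dn$acceptor))
  structure(num / nrow(di), numerator = as.integer(num),
            denominator = nrow(di))
}

polya_motifs <- c("AATAAA", "ATTAAA")

# all start positions of fixed motif in s (overlapping matches included)
motif_positions <- function(s, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
  if (hits[1] == -1) integer() else as.integer(hits)
}

#' Scan a genome for polyadenylation signal hexamers
#'
#' Records every exact occurrence of the AATAAA and ATTAAA consensus
#' hexamers on both strands (reverse-strand occurrences are found as the
#' reverse complements TTTATT/TTTAAT on the forward sequence). Positions are
#' the forward-strand start coordinate of the 6-mer.
#'
#' @param genome named character vector from [read_fasta()].
#' @return tibble with `chrom`, `strand`, `pos`, sorted.
#' @export
scan_polya <- function(genome) {
  rows <- purrr::imap(genome, function(s, chrom) {
    fw <- sort(unique(unlist(lapply(polya_motifs, motif_positions, s = s))))
    rv <- sort(unique(unlist(lapply(revcomp(polya_motifs), motif_positions, s = s))))
    dplyr::bind_rows(
      tibble::tibble(chrom = chrom, strand = "+", pos = fw),
      tibble::tibble(chrom = chrom, strand = "-", pos = rv)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(chrom = character(), strand = character(),
                          pos = integer()))
  }
  dplyr::arrange(out, .data$chrom, .data$strand, .data$pos)
}

# distinct (chrom, strand, position) site tables
distinct_tss <- function(x) {
  f <- transcript_features(x)
  dplyr::distinct(f, .data$chrom, .data$strand, pos = .data$tss)
}

distinct_tts <- function(x) {
  f <- transcript_features(x)
  dplyr::distinct(f, .data$chrom, .data$strand, pos = .data$tts)
}

#' Transcript 3' completion: TTS near a polyA signal
#'
#' Over distinct (chromosome, strand, TTS position) triples, the fraction
#' with a same-strand polyA hexamer at distance strictly less than
#' `window` bp, where the distance to a motif is the minimum absolute
#' difference between the TTS position and any of the motif's six bases.
#'
#' @param x annotation tibble.
#' @param polya_sites tibble from [scan_polya()].
#' @param window distance bound in bp (default 50, strict `<`).
#' @return numeric fraction with `numerator`/`denominator` attributes.
#' @export
tts_completion <- function(x, polya_sites, window = 50L) {
  tts <- distinct_tts(x)
  if (nrow(tts) == 0) {
    return(structure(NA_real_, numerator = 0L, denominator = 0L))
  }
  hit <- vapply(seq_len(nrow(tts)), function(i) {
    p <- polya_sites$pos[polya_sites$chrom == tts$chrom[i] &
                           polya_sites$strand == tts$strand[i]]
    if (length(p) == 0) return(FALSE)
    d <- pmax(0L, pmax(p - tts$pos[i], tts$pos[i] - (p + 5L)))
    min(d) < window
  }, logical(1))
  structure(sum(hit) / nrow(tts), numerator = as.integer(sum(hit)),
            denominator = nrow(tts))
}

#' Transcript 3' completion, windowed-containment mode
#'
#' The alternative 3'-completion reading: the fraction of distinct TTS whose
#' last `span` bp (on the transcript strand, ending at the TTS) contain a
#' complete polyA hexamer.
#'
#' @param x annotation tibble.
#' @param genome named character vector from [read_fasta()].
#' @param span window length in bp (default 30).
#' @return numeric fraction with `numerator`/`denominator` attributes.
#' @export
tts_polya_span <- function(x, genome, span = 30L) {
  tts <- distinct_tts(x)
  if (nrow(tts) == 0) {
    return(structure(NA_real_, numerator = 0L, denominator = 0L))
  }
  hit <- vapply(seq_len(nrow(tts)), function(i) {
    len <- nchar(genome[[tts$chrom[i]]])
    if (tts$strand[i] == "+") {
      lo <- max(1L, tts$pos[i] - span + 1L)
      s <- genome_slice(genome, tts$chrom[i], lo, tts$pos[i])
    } else {
      hi <- min(len, tts$pos[i] + span - 1L)
      s <- revcomp(genome_slice(genome, tts$chrom[i], tts$pos[i], hi))
    }
    any(vapply(polya_motifs, function(m) grepl(m, s, fixed = TRUE), logical(1)))
  }, logical(1))
  structure(sum(hit) / nrow(tts), numerator = as.integer(sum(hit)),
            denominator = nrow(tts))
}

#' Transcript 5' completion: TSS inside an open-chromatin peak
#'
#' Over distinct (chromosome, strand, TSS position) triples, the fraction
#' whose position lies within at least one (strandless) peak interval.
#'
#' @param x annotation tibble.
#' @param peaks tibble from [read_bed()] (1-based inclusive intervals).
#' @return numeric fraction with `numerator`/`denominator` attributes.
#' @export
tss_completion <- function(x, peaks) {
  tss <- distinct_tss(x)
  if (nrow(tss) == 0) {
    return(structure(NA_real_, numerator = 0L, denominator = 0L))
  }
  if (nrow(peaks) == 0) {
    warning("empty peak set; 5' completion is 0", call. = FALSE)
    return(structure(0, numerator = 0L, denominator = nrow(tss)))
  }
  hit <- vapply(seq_len(nrow(tss)), function(i) {
    any(peaks$chrom == tss$chrom[i] & peaks$start <= tss$pos[i] &
          peaks$end >= tss$pos[i])
  }, logical(1))
  structure(sum(hit) / nrow(tss), numerator = as.integer(sum(hit)),
            denominator = nrow(tss))
}

#' Fraction of monoexonic transcripts
#'
#' @param x non-empty annotation tibble.
#' @return numeric fraction with `numerator`/`denominator` attributes.
#' @export
monoexonic_fraction <- function(x) {
  if (nrow(x) == 0) stop("empty annotation", call. = FALSE)
  num <- sum(n_exons(x) == 1)
  structure(num / nrow(x), numerator = as.integer(num), denominator = nrow(x))
}

#' Structural QC report for an annotation
#'
#' Computes the monoexonic fraction and, when the corresponding inputs are
#' given, splice-site canonicity, 5' completion against peaks and 3'
#' completion against polyA signals.
#'
#' @param x annotation tibble.
#' @param genome optional genome (canonicity, polyA scan).
#' @param peaks optional peak tibble from [read_bed()].
#' @param polya_sites optional site tibble from [scan_polya()]; computed
#'   from `genome` when omitted.
#' @param tts_window distance bound for [tts_completion()].
#' @return tibble of class `qc_report` with columns `metric`, `value`,
#'   `numerator`, `denominator`.
#' @export
qc_report <- function(x, genome = NULL, peaks = NULL, polya_sites = NULL,
                      tts_window = 50L) {
  metric <- function(name, v) {
    tibble::tibble(metric = name, value = as.numeric(v),
                   numerator = attr(v, "numerator"),
                   denominator = attr(v, "denominator"))
  }
  out <- list(metric("monoexonic_fraction", monoexonic_fraction(x)))
  if (!is.null(genome)) {
    out <- c(out, list(metric("canonical_intron_fraction",
                              canonicity_fraction(x, genome))))
    if (is.null(polya_sites)) polya_sites <- scan_polya(genome)
  }
  if (!is.null(polya_sites)) {
    out <- c(out, list(metric("tts_completion",
                              tts_completion(x, polya_sites, tts_window))))
  }
  if (!is.null(peaks)) {
    out <- c(out, list(metric("tss_completion", tss_completion(x, peaks))))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("qc_report", class(res))
  res
}
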