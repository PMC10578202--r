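# in-code fixture builders and independent brute-force oracles

# one-row transcript tibble; exons given as list(c(start, end), ...)
tx <- function(id, exons, chrom = "chr1", strand = "+", gene = NA_character_,
               origin = "novel", det = 0L, tpm = numeric(),
               biotype = NA_character_, feelnc = NA_character_) {
  tibble::tibble(
    transcript_id = id, gene_id = gene, chrom = chrom, strand = strand,
    exon_starts = list(as.integer(vapply(exons, `[`, numeric(1), 1))),
    exon_ends = list(as.integer(vapply(exons, `[`, numeric(1), 2))),
    origin = origin, detection_count = as.integer(det),
    samples = list(character()), tpm = list(tpm),
    transcript_biotype = biotype, feelnc_biotype = feelnc,
    ref_gene_id = NA_character_, contains = NA_character_
  )
}

ann <- function(..., provenance = "merged") {
  annotation(dplyr::bind_rows(...), provenance = provenance)
}

# random transcript sets reusing a pool of base chains so that collapse,
# containment and clustering branches are all exercised
random_transcripts <- function(n, seed) {
  set.seed(seed)
  base <- lapply(seq_len(max(3, n %/% 4)), function(b) {
    ne <- sample(1:4, 1)
    start <- sample(seq(1000, 50000, by = 500), 1)
    elens <- sample(80:200, ne, replace = TRUE)
    ilens <- if (ne > 1) sample(60:150, ne - 1, replace = TRUE) else integer()
    starts <- integer(ne); ends <- integer(ne); pos <- start
    for (k in seq_len(ne)) {
      starts[k] <- pos; ends[k] <- pos + elens[k] - 1L
      pos <- ends[k] + (if (k < ne) ilens[k] + 1L else 0L)
    }
    list(chrom = sample(c("chr1", "chr2"), 1),
         strand = sample(c("+", "-"), 1), starts = starts, ends = ends)
  })
  rows <- lapply(seq_len(n), function(i) {
    b <- base[[sample(length(base), 1)]]
    s <- b$starts; e <- b$ends
    s[1] <- s[1] + sample(-15:15, 1)
    e[length(e)] <- e[length(e)] + sample(-15:15, 1)
    if (e[1] <= s[1]) s[1] <- e[1] - 30L
    if (length(s) > 1 && e[length(e)] <= s[length(s)]) {
      e[length(e)] <- s[length(s)] + 30L
    }
    tibble::tibble(
      transcript_id = sprintf("T%03d", i), gene_id = NA_character_,
      chrom = b$chrom, strand = b$strand,
      exon_starts = list(s), exon_ends = list(e), origin = "novel",
      detection_count = 1L, samples = list(sprintf("s%02d", sample(6, 1))),
      tpm = list(stats::setNames(stats::runif(1, 0.1, 10), "x")),
      transcript_biotype = NA_character_, feelnc_biotype = NA_character_,
      ref_gene_id = NA_character_, contains = NA_character_
    )
  })
  annotation(dplyr::bind_rows(rows))
}

# ---- independent oracles ------------------------------------------------

chain_string <- function(starts, ends) {
  n <- length(starts)
  if (n < 2) return("")
  paste(ends[-n] + 1L, starts[-1] - 1L, sep = "-", collapse = ";")
}

# Extension predicate re-derived via string matching on chains
oracle_extends <- function(cand, base) {
  if (cand$chrom != base$chrom || cand$strand != base$strand) return(FALSE)
  cs <- cand$exon_starts[[1]]; ce <- cand$exon_ends[[1]]
  bs <- base$exon_starts[[1]]; be <- base$exon_ends[[1]]
  if (length(cs) < 2 || length(bs) < 2) return(FALSE)
  if (cs[1] > be[length(be)] || bs[1] > ce[length(ce)]) return(FALSE)
  cc <- chain_string(cs, ce); bc <- chain_string(bs, be)
  if (nchar(cc) <= nchar(bc)) return(FALSE)
  full <- paste0(";", cc, ";")
  if (!grepl(paste0(";", bc, ";"), full, fixed = TRUE)) return(FALSE)
  # every extra candidate intron must lie strictly outside the base extent
  ci <- cbind(ce[-length(ce)] + 1L, cs[-1] - 1L)
  bi_keys <- strsplit(bc, ";", fixed = TRUE)[[1]]
  extra <- !(paste(ci[, 1], ci[, 2], sep = "-") %in% bi_keys)
  all(ci[extra, 2] < bs[1] | ci[extra, 1] > be[length(be)])
}

# all-predicates positional classification, first true in priority order
oracle_positional_class <- function(trow, reference) {
  classes <- character()
  tkey <- paste(trow$chrom, trow$strand,
                chain_string(trow$exon_starts[[1]], trow$exon_ends[[1]]))
  for (j in seq_len(nrow(reference))) {
    r <- reference[j, ]
    rk <- paste(r$chrom, r$strand,
                chain_string(r$exon_starts[[1]], r$exon_ends[[1]]))
    if (length(r$exon_starts[[1]]) >= 2 && rk == tkey) {
      classes <- c(classes, "Exact")
    }
    if (length(r$exon_starts[[1]]) >= 2) {
      if (oracle_extends(trow, r)) classes <- c(classes, "Extension")
      if (oracle_extends(r, trow)) classes <- c(classes, "Inclusion")
    }
    if (r$chrom == trow$chrom && r$strand == trow$strand) {
      r_ext <- c(r$exon_starts[[1]][1], max(r$exon_ends[[1]]))
      t_ext <- c(trow$exon_starts[[1]][1], max(trow$exon_ends[[1]]))
      if (r_ext[1] <= t_ext[2] && t_ext[1] <= r_ext[2]) {
        classes <- c(classes, "Overlapping")
      }
    }
  }
  for (cl in c("Exact", "Extension", "Inclusion", "Overlapping")) {
    if (cl %in% classes) return(cl)
  }
  "Intergenic_or_Antisense"
}

# connected components of the same-strand exonic-overlap graph by BFS over
# an explicit O(n^2) adjacency matrix
oracle_gene_components <- function(x) {
  n <- nrow(x)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (x$chrom[i] != x$chrom[j] || x$strand[i] != x$strand[j]) next
      hit <- FALSE
      for (a in seq_along(x$exon_starts[[i]])) {
        for (b in seq_along(x$exon_starts[[j]])) {
          if (x$exon_starts[[i]][a] <= x$exon_ends[[j]][b] &&
              x$exon_starts[[j]][b] <= x$exon_ends[[i]][a]) hit <- TRUE
        }
      }
      adj[i, j] <- adj[j, i] <- hit
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# do two cluster labellings define the same partition of rows?
same_partition <- function(a, b) {
  identical(
    unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 1))]),
    unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 1))])
  )
}

# structural equality of two annotations up to row order
same_structure <- function(a, b) {
  key <- function(x) {
    sort(vapply(seq_len(nrow(x)), function(i) {
      paste(x$chrom[i], x$strand[i],
            paste(x$exon_starts[[i]], collapse = ","),
            paste(x$exon_ends[[i]], collapse = ","))
    }, character(1)))
  }
  identical(key(a), key(b))
}
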