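# plant a sequence with known intron boundaries
mk_genome <- function(len = 1000, seed = 1) {
  set.seed(seed)
  g <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  stats::setNames(g, "chr1")
}

plant <- function(genome, chrom, at, value) {
  s <- genome[[chrom]]
  substr(s, at, at + nchar(value) - 1L) <- value
  genome[[chrom]] <- s
  genome
}

test_that("splice dinucleotides are read strand-aware", {
  g <- mk_genome()
  g <- plant(g, "chr1", 201, "GT")
  g <- plant(g, "chr1", 298, "AG")
  dn <- splice_dinucleotides(g, "chr1", "+", 201L, 299L)
  expect_equal(dn$donor, "GT")
  expect_equal(dn$acceptor, "AG")

  # minus strand: forward shows CT..AC; reverse-complement oracle via
  # Biostrings confirms the expected read-off
  g2 <- mk_genome(seed = 2)
  g2 <- plant(g2, "chr1", 401, "CT")
  g2 <- plant(g2, "chr1", 498, "AC")
  dn2 <- splice_dinucleotides(g2, "chr1", "-", 401L, 499L)
  expect_equal(dn2$donor, "GT")
  expect_equal(dn2$acceptor, "AG")
  oracle <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(g2[["chr1"]], 498, 499))))
  expect_equal(dn2$donor, oracle)

  expect_error(splice_dinucleotides(g, "chr1", "+", 10L, 12L), "shorter than 4")
  expect_error(splice_dinucleotides(g, "chr1", "+", 990L, 1100L), "out of bounds")
})

test_that("canonical pairs are exactly GT-AG, GC-AG and AT-AC", {
  expect_true(all(is_canonical(c("GT", "GC", "AT"), c("AG", "AG", "AC"))))
  expect_false(any(is_canonical(c("GT", "AG", "CC"), c("GG", "GT", "GG"))))
})

test_that("canonicity is computed over deduplicated introns", {
  g <- mk_genome(5000)
  # four distinct introns, three canonical
  introns <- list(c(201, 299), c(501, 599), c(801, 899), c(1101, 1199))
  for (k in seq_along(introns)) {
    pair <- if (k < 4) c("GT", "AG") else c("CC", "GG")
    g <- plant(g, "chr1", introns[[k]][1], pair[1])
    g <- plant(g, "chr1", introns[[k]][2] - 1, pair[2])
  }
  x <- ann(
    tx("a", list(c(100, 200), c(300, 400))),
    tx("b", list(c(450, 500), c(600, 700))),
    tx("c", list(c(750, 800), c(900, 1000))),
    tx("d", list(c(1050, 1100), c(1200, 1300)))
  )
  expect_equal(as.numeric(canonicity_fraction(x, g)), 0.75)

  # the same intron shared by several transcripts counts once
  shared <- ann(
    tx("a", list(c(100, 200), c(300, 400))),
    tx("b", list(c(150, 200), c(300, 450))),
    tx("c", list(c(50, 200), c(300, 500)))
  )
  cf <- canonicity_fraction(shared, g)
  expect_equal(attr(cf, "denominator"), 1L)
  expect_equal(as.numeric(cf), 1)
})

test_that("polyA scanning finds hexamers on both strands, overlapping included", {
  g <- stats::setNames(paste0(strrep("C", 9), "AATAAA", strrep("C", 5),
                              "TTTATT", strrep("C", 5)), "chr1")
  sites <- scan_polya(g)
  expect_equal(sites$pos[sites$strand == "+"], 10L)
  expect_equal(sites$pos[sites$strand == "-"], 21L)

  # overlapping occurrences: AATAAATAAA holds AATAAA at 1 and ATTAAA-free,
  # AATAAA again at 5
  g2 <- stats::setNames(paste0("AATAAATAAA", strrep("C", 10)), "chr1")
  s2 <- scan_polya(g2)
  expect_true(all(c(1L, 5L) %in% s2$pos[s2$strand == "+"]))

  # reverse-complement oracle: forward positions of motifs in the
  # reverse-complemented sequence map back to minus-strand sites
  g3 <- mk_genome(300, seed = 5)
  g3 <- plant(g3, "chr1", 100, "TTTAAT")
  s3 <- scan_polya(g3)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g3[[1]])))
  fwd_in_rc <- unlist(lapply(c("AATAAA", "ATTAAA"), function(m) {
    as.integer(gregexpr(paste0("(?=", m, ")"), rc, perl = TRUE)[[1]])
  }))
  fwd_in_rc <- fwd_in_rc[fwd_in_rc > 0]
  mapped <- sort(nchar(g3[[1]]) - fwd_in_rc - 4L)
  expect_equal(sort(s3$pos[s3$strand == "-"]), mapped)

  expect_equal(nrow(scan_polya(stats::setNames("CGCGCGCG", "chr1"))), 0)
})

test_that("3' completion counts distinct TTS within the distance bound", {
  sites <- tibble::tibble(chrom = "chr1", strand = "+", pos = 460L)
  # TTS at 500, motif at 460..465: distance 35 < 50
  x <- ann(tx("a", list(c(100, 500))))
  expect_equal(as.numeric(tts_completion(x, sites)), 1)
  # motif 60 bp away fails
  far <- tibble::tibble(chrom = "chr1", strand = "+", pos = 560L)
  expect_equal(as.numeric(tts_completion(x, far)), 0)
  # opposite strand site never counts
  anti <- tibble::tibble(chrom = "chr1", strand = "-", pos = 460L)
  expect_equal(as.numeric(tts_completion(x, anti)), 0)
  # two transcripts sharing a TTS make one denominator entry
  y <- ann(tx("a", list(c(100, 500))), tx("b", list(c(200, 500))))
  expect_equal(attr(tts_completion(y, sites), "denominator"), 1L)
})

test_that("windowed-containment 3' completion needs the hexamer in the last bases", {
  g <- mk_genome(2000, seed = 7)
  g[["chr1"]] <- gsub("AATAAA|ATTAAA|TTTATT|TTTAAT", "CCCCCC", g[["chr1"]])
  g <- plant(g, "chr1", 480, "AATAAA")   # within the last 30 bp of TTS 500
  x <- ann(tx("a", list(c(100, 500))), tx("b", list(c(600, 900))))
  sp <- tts_polya_span(x, g, span = 30)
  expect_equal(as.numeric(sp), 0.5)
  # minus strand: hexamer must lie downstream in forward coordinates
  g2 <- mk_genome(2000, seed = 8)
  g2[["chr1"]] <- gsub("AATAAA|ATTAAA|TTTATT|TTTAAT", "CCCCCC", g2[["chr1"]])
  g2 <- plant(g2, "chr1", 610, "TTTATT")
  y <- ann(tx("a", list(c(600, 900)), strand = "-"))
  expect_equal(as.numeric(tts_polya_span(y, g2, span = 30)), 1)
})

test_that("5' completion counts TSS inside peaks after BED conversion", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200", path)   # 1-based [100, 200]
  peaks <- read_bed(path)
  at150 <- ann(tx("a", list(c(150, 600), c(700, 800))))
  expect_equal(as.numeric(tss_completion(at150, peaks)), 1)
  at99 <- ann(tx("a", list(c(99, 600), c(700, 800))))
  expect_equal(as.numeric(tss_completion(at99, peaks)), 0)
  # minus-strand TSS is the rightmost coordinate
  minus <- ann(tx("a", list(c(50, 90), c(150, 200)), strand = "-"))
  expect_equal(as.numeric(tss_completion(minus, peaks)), 1)
  expect_warning(z <- tss_completion(at150, peaks[0, ]), "empty peak set")
  expect_equal(as.numeric(z), 0)
})

test_that("monoexonic fraction is a plain count ratio", {
  x <- ann(tx("m", list(c(1, 100))),
           tx("s1", list(c(200, 300), c(400, 500))),
           tx("s2", list(c(600, 700), c(800, 900))))
  expect_equal(as.numeric(monoexonic_fraction(x)), 1 / 3)
  allspl <- ann(tx("s1", list(c(200, 300), c(400, 500))))
  expect_equal(as.numeric(monoexonic_fraction(allspl)), 0)
  expect_error(monoexonic_fraction(annotation(tibble::tibble())), "empty")
})

test_that("QC metrics equal the generator-planted fractions exactly", {
  for (seed in c(2, 17)) {
    fx <- simulate_fixtures(fixture_spec(seed = seed))
    qc <- qc_report(fx$reference, genome = fx$genome, peaks = fx$peaks)
    val <- function(m) qc$value[qc$metric == m]
    expect_identical(val("monoexonic_fraction"), fx$truth$monoexonic_fraction)
    expect_identical(val("canonical_intron_fraction"),
                     fx$truth$canonical_fraction)
    expect_identical(val("tss_completion"), fx$truth$tss_completion)
    expect_identical(val("tts_completion"), fx$truth$tts_completion)
    expect_true(all(qc$value >= 0 & qc$value <= 1))
    expect_equal(qc$value, qc$numerator / qc$denominator)
  }
})

test_that("QC metrics are invariant under reverse-complementing the genome", {
  fx <- simulate_fixtures(fixture_spec(seed = 4, n_genes = 20, n_noise = 0,
                                       n_novel = 2, n_extensions = 1))
  L <- nchar(fx$genome[[1]])
  flipped_genome <- vapply(fx$genome, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  flip <- tibble::as_tibble(fx$reference)
  for (i in seq_len(nrow(flip))) {
    s <- flip$exon_starts[[i]]; e <- flip$exon_ends[[i]]
    flip$exon_starts[[i]] <- rev(L - e + 1L)
    flip$exon_ends[[i]] <- rev(L - s + 1L)
  }
  flip$strand <- ifelse(flip$strand == "+", "-", "+")
  flip <- annotation(flip)
  expect_equal(as.numeric(canonicity_fraction(flip, flipped_genome)),
               as.numeric(canonicity_fraction(fx$reference, fx$genome)))
  expect_equal(as.numeric(tts_completion(flip, scan_polya(flipped_genome))),
               as.numeric(tts_completion(fx$reference, scan_polya(fx$genome))))
})
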