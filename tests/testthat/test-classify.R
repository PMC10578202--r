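mk_reference <- function() {
  ann(
    tx("R1", list(c(100, 200), c(300, 400)), origin = "reference",
       biotype = "protein_coding"),                       # intron (201,299)
    tx("R2", list(c(1000, 1100), c(1200, 1300), c(1400, 1500)),
       origin = "reference"),                             # 2 introns
    tx("R3", list(c(5000, 5200)), origin = "reference"),  # monoexonic
    provenance = "reference"
  )
}

test_that("positional classes follow the priority order on constructed cases", {
  ref <- mk_reference()
  # Exact: chain identical to R1
  expect_equal(positional_class(ann(tx("t", list(c(150, 200), c(300, 350)))), ref),
               "Exact")
  # Extension beats Overlapping: adds a 5' intron to R1's chain while another
  # reference transcript merely overlaps
  ref2 <- ann(dplyr::bind_rows(tibble::as_tibble(ref),
                               tx("R4", list(c(10, 60), c(90, 140)),
                                  origin = "reference")),
              provenance = "reference")
  extn <- ann(tx("t", list(c(10, 50), c(100, 200), c(300, 400))))
  expect_equal(positional_class(extn, ref2), "Extension")
  # Inclusion: R2 extends the prediction
  incl <- ann(tx("t", list(c(1050, 1100), c(1200, 1300))))
  expect_equal(positional_class(incl, ref), "Inclusion")
  # Overlapping: same strand, incompatible chain
  ovl <- ann(tx("t", list(c(150, 260), c(330, 420))))
  expect_equal(positional_class(ovl, ref), "Overlapping")
  # no same-strand overlap at all
  far <- ann(tx("t", list(c(9000, 9100), c(9200, 9300))))
  expect_equal(positional_class(far, ref), "Intergenic_or_Antisense")
  anti <- ann(tx("t", list(c(100, 200), c(300, 400)), strand = "-"))
  expect_equal(positional_class(anti, ref), "Intergenic_or_Antisense")

  expect_error(positional_class(ann(tx("m", list(c(1, 50)))), ref), "monoexonic")
})

test_that("positional classes agree with the all-predicates oracle", {
  set.seed(42)
  ref <- random_transcripts(40, seed = 31)
  ref$origin <- "reference"
  preds <- random_transcripts(60, seed = 32)
  preds <- preds[lengths(preds$exon_starts) >= 2, ]
  got <- positional_class(preds, ref)
  want <- vapply(seq_len(nrow(preds)), function(i) {
    oracle_positional_class(preds[i, ], ref)
  }, character(1))
  expect_equal(got, want)
})

test_that("transcript novelty is exact structure correspondence", {
  ref <- mk_reference()
  x <- ann(
    tx("exact", list(c(150, 200), c(300, 350))),   # chain matches R1
    tx("ext", list(c(10, 50), c(100, 200), c(300, 400))),
    tx("mono_same", list(c(5000, 5200))),
    tx("mono_shift", list(c(5001, 5200)))
  )
  expect_equal(transcript_novelty(x, ref),
               c("known", "unknown", "known", "unknown"))
  # coordinate-identity oracle: any 1 bp shift in either coordinate is unknown
  for (ds in -1:1) for (de in -1:1) {
    m <- ann(tx("m", list(c(5000 + ds, 5200 + de))))
    expect_equal(transcript_novelty(m, ref) == "known", ds == 0 && de == 0)
  }
  # the laxer overlap mode accepts stranded overlap
  expect_equal(transcript_novelty(ann(tx("m", list(c(5100, 5300)))), ref,
                                  monoexonic_match = "overlap"), "known")
})

test_that("gene novelty follows the all/any rules and ignores member order", {
  expect_equal(gene_novelty(c("known", "known")), "known")
  expect_equal(gene_novelty(c("known", "unknown")), "enriched")
  expect_equal(gene_novelty(c("unknown", "unknown", "unknown")), "unknown")
  expect_error(gene_novelty(character()), "no transcripts")
  set.seed(1)
  for (i in 1:10) {
    v <- sample(c("known", "unknown"), 5, replace = TRUE)
    expect_equal(gene_novelty(v), gene_novelty(sample(v)))
  }
})

test_that("lncRNA candidate eligibility applies all three clauses", {
  ref <- mk_reference()
  # too short: 150 bp total
  short <- ann(tx("t", list(c(9000, 9074), c(9100, 9174))))
  expect_false(feelnc_eligible(short, ref))
  # two exons, one of 20 bp
  small_exon <- ann(tx("t", list(c(9000, 9299), c(9400, 9419))))
  expect_false(feelnc_eligible(small_exon, ref))
  # three exons, > 200 bp, no mRNA overlap
  good <- ann(tx("t", list(c(9000, 9100), c(9200, 9300), c(9400, 9500))))
  expect_true(feelnc_eligible(good, ref))
  # same-strand exonic overlap with a reference mRNA disqualifies
  ovl <- ann(tx("t", list(c(150, 250), c(300, 400), c(500, 600))))
  expect_false(feelnc_eligible(ovl, ref))
  # opposite strand overlap is allowed
  anti <- ann(tx("t", list(c(150, 250), c(300, 400), c(500, 600)), strand = "-"))
  expect_true(feelnc_eligible(anti, ref))
  # monoexonic never qualifies
  mono <- ann(tx("t", list(c(9000, 9500))))
  expect_false(feelnc_eligible(mono, ref))
})

test_that("unified biotypes give priority to coding labels", {
  x <- ann(
    tx("a", list(c(1, 300)), biotype = "protein_coding", feelnc = "lncRNA"),
    tx("b", list(c(400, 700)), feelnc = "lncRNA"),
    tx("c", list(c(800, 1100))),
    tx("d", list(c(1200, 1500)), feelnc = "TUCp"),
    tx("e", list(c(1600, 1900)), feelnc = "noORF"),
    tx("f", list(c(2000, 2300)), biotype = "lncRNA", feelnc = "mRNA")
  )
  expect_equal(unified_transcript_biotype(x),
               c("mRNA", "lncRNA", "uncharacterized", "TUCp", "noORF", "mRNA"))
  # a reference protein_coding transcript is never relabelled non-coding
  for (fl in c("lncRNA", "TUCp", "noORF", NA)) {
    y <- ann(tx("p", list(c(1, 300)), biotype = "protein_coding", feelnc = fl))
    expect_equal(unified_transcript_biotype(y), "mRNA")
  }
})

test_that("gene coding status is any-mRNA, then any-lncRNA", {
  expect_equal(gene_coding_status(c("mRNA", "lncRNA")), "mRNA")
  expect_equal(gene_coding_status(c("lncRNA", "TUCp")), "lncRNA")
  expect_equal(gene_coding_status("noORF"), "uncharacterized")
  expect_error(gene_coding_status(character()), "no transcripts")
})

test_that("lncRNA positional context covers genic and intergenic cases", {
  mrna <- ann(tx("M", list(c(10000, 10200), c(12000, 12200)), strand = "+"))
  # inside the intron, opposite strand
  lnc1 <- ann(tx("L1", list(c(10500, 10900)), strand = "-"))
  p1 <- classify_lnc_position(lnc1, mrna)
  expect_equal(p1$scope, "genic")
  expect_equal(p1$sublocation, "intronic")
  expect_equal(p1$orientation, "antisense")
  # exonic overlap, same strand
  lnc2 <- ann(tx("L2", list(c(10100, 10400)), strand = "+"))
  p2 <- classify_lnc_position(lnc2, mrna)
  expect_equal(p2$sublocation, "exonic")
  expect_equal(p2$orientation, "sense")
  # 5 kb upstream of the mRNA TSS, opposite strand: divergent
  lnc3 <- ann(tx("L3", list(c(4500, 4900)), strand = "-"))
  p3 <- classify_lnc_position(lnc3, mrna)
  expect_equal(p3$scope, "intergenic")
  expect_equal(p3$sublocation, "upstream")
  expect_equal(p3$label, "divergent")
  # downstream antisense: convergent
  lnc4 <- ann(tx("L4", list(c(13000, 13400)), strand = "-"))
  p4 <- classify_lnc_position(lnc4, mrna)
  expect_equal(p4$sublocation, "downstream")
  expect_equal(p4$label, "convergent")
  # for a minus-strand mRNA, upstream flips to the right side
  mrna_m <- ann(tx("M2", list(c(10000, 10200), c(12000, 12200)), strand = "-"))
  p5 <- classify_lnc_position(lnc4, mrna_m)
  expect_equal(p5$sublocation, "upstream")
  # beyond the window: unclassified
  farlnc <- ann(tx("L5", list(c(500000, 500400))))
  expect_equal(classify_lnc_position(farlnc, mrna)$scope, "unclassified")
})

test_that("catalog matching uses shared introns or stranded monoexonic overlap", {
  catalog <- ann(
    tx("C1", list(c(100, 200), c(300, 400), c(500, 600))),
    tx("C2", list(c(5000, 5400)))
  )
  # shares exactly one of three introns (201,299)
  one <- ann(tx("t", list(c(50, 200), c(300, 330))))
  expect_true(catalog_match(one, catalog))
  # overlapping but all-distinct introns
  distinct <- ann(tx("t", list(c(50, 210), c(320, 430))))
  expect_false(catalog_match(distinct, catalog))
  # monoexonic stranded overlap
  expect_true(catalog_match(ann(tx("m", list(c(5300, 5600)))), catalog))
  expect_false(catalog_match(ann(tx("m", list(c(5300, 5600)), strand = "-")),
                             catalog))
})

test_that("the classification table is one consistent row per transcript", {
  fx <- simulate_fixtures(fixture_spec(seed = 13))
  merged <- filter_transcripts(merge_annotations(fx$assemblies, fx$reference))
  cls <- classify_transcripts(merged, fx$reference)
  expect_equal(nrow(cls), nrow(merged))
  expect_true(all(cls$positional_class[lengths(merged$exon_starts) == 1] ==
                    "Monoexonic"))
  # Exact implies known; Intergenic_or_Antisense implies unknown
  expect_true(all(cls$novelty[cls$positional_class == "Exact"] == "known"))
  expect_true(all(cls$novelty[cls$positional_class == "Intergenic_or_Antisense"]
                  == "unknown"))
})
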