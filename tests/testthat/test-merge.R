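# pairwise fixpoint oracle for spliced collapse: repeatedly merge any two
# transcripts with identical chains (same chromosome/strand) that overlap
oracle_collapse_spliced <- function(x) {
  rows <- lapply(seq_len(nrow(x)), function(i) {
    list(chrom = x$chrom[i], strand = x$strand[i],
         s = x$exon_starts[[i]], e = x$exon_ends[[i]])
  })
  repeat {
    merged <- FALSE
    for (i in seq_along(rows)) {
      for (j in seq_along(rows)) {
        if (j <= i || merged) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom != b$chrom || a$strand != b$strand) next
        if (chain_string(a$s, a$e) != chain_string(b$s, b$e)) next
        if (a$s[1] > b$e[length(b$e)] || b$s[1] > a$e[length(a$e)]) next
        a$s[1] <- min(a$s[1], b$s[1])
        a$e[length(a$e)] <- max(a$e[length(a$e)], b$e[length(b$e)])
        rows[[i]] <- a
        rows <- rows[-j]
        merged <- TRUE
      }
      if (merged) break
    }
    if (!merged) break
  }
  rows
}

test_that("spliced collapse extends terminal exons only", {
  # identical transcripts collapse without coordinate change
  a <- ann(tx("a", list(c(100, 200), c(300, 400))),
           tx("b", list(c(100, 200), c(300, 400))))
  out <- collapse_spliced(a)
  expect_equal(nrow(out), 1)
  expect_equal(out$exon_starts[[1]], c(100L, 300L))
  expect_equal(out$exon_ends[[1]], c(200L, 400L))

  # same chain, different terminal ends: union of extremities
  b <- ann(tx("a", list(c(100, 200), c(300, 400))),
           tx("b", list(c(150, 200), c(300, 450))))
  out <- collapse_spliced(b)
  expect_equal(nrow(out), 1)
  expect_equal(out$exon_starts[[1]], c(100L, 300L))
  expect_equal(out$exon_ends[[1]], c(200L, 450L))

  # same chain coordinates on different chromosomes: kept apart
  c2 <- ann(tx("a", list(c(100, 200), c(300, 400)), chrom = "chr1"),
            tx("b", list(c(100, 200), c(300, 400)), chrom = "chr2"))
  expect_equal(nrow(collapse_spliced(c2)), 2)

  expect_error(collapse_spliced(ann(tx("m", list(c(1, 50))))), "monoexonic")
})

test_that("spliced collapse agrees with the pairwise fixpoint oracle", {
  for (seed in 1:5) {
    x <- random_transcripts(40, seed = seed)
    x <- x[lengths(x$exon_starts) >= 2, ]
    out <- collapse_spliced(x)
    oracle <- oracle_collapse_spliced(x)
    expect_equal(nrow(out), length(oracle))
    key <- function(ch, st, s, e) paste(ch, st, paste(s, collapse = ","),
                                        paste(e, collapse = ","))
    got <- sort(vapply(seq_len(nrow(out)), function(i) {
      key(out$chrom[i], out$strand[i], out$exon_starts[[i]], out$exon_ends[[i]])
    }, character(1)))
    want <- sort(vapply(oracle, function(r) key(r$chrom, r$strand, r$s, r$e),
                        character(1)))
    expect_equal(got, want)
  }
})

test_that("collapse merges provenance: detection counts and per-sample TPM maxima", {
  a <- ann(tx("a", list(c(100, 200), c(300, 400))),
           tx("b", list(c(150, 200), c(300, 450))))
  a$samples <- list("s1", "s2")
  a$tpm <- list(c(s1 = 2, s2 = 1), c(s2 = 5))
  out <- collapse_spliced(a)
  expect_equal(out$detection_count, 2L)
  expect_equal(out$tpm[[1]], c(s1 = 2, s2 = 5))
})

test_that("monoexonic collapse unions transitively overlapping intervals", {
  a <- ann(tx("a", list(c(100, 200))), tx("b", list(c(150, 250))))
  out <- collapse_monoexonic(a)
  expect_equal(nrow(out), 1)
  expect_equal(out$exon_starts[[1]], 100L)
  expect_equal(out$exon_ends[[1]], 250L)

  s <- ann(tx("a", list(c(100, 200)), strand = "+"),
           tx("b", list(c(150, 250)), strand = "-"))
  expect_equal(nrow(collapse_monoexonic(s)), 2)

  chain3 <- ann(tx("a", list(c(1, 10))), tx("b", list(c(5, 15))),
                tx("c", list(c(12, 20))))
  out <- collapse_monoexonic(chain3)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$exon_starts[[1]], out$exon_ends[[1]]), c(1L, 20L))

  expect_error(collapse_monoexonic(ann(tx("s", list(c(1, 10), c(30, 40))))),
               "spliced")
})

test_that("extension detection requires a contiguous sub-chain with outside extras", {
  base <- tx("base", list(c(25, 30), c(41, 60)))          # intron (31,40)
  cand <- tx("cand", list(c(1, 10), c(21, 30), c(41, 60)))  # introns (11,20),(31,40)
  expect_true(is_extension(ann(cand), ann(base)))
  expect_false(is_extension(ann(base), ann(cand)))
  # identical chains: no extra intron
  expect_false(is_extension(ann(base), ann(tx("b2", list(c(20, 30), c(41, 65))))))
  # chain mismatch
  mism <- tx("m", list(c(1, 10), c(21, 30), c(46, 60)))   # introns (11,20),(31,45)
  expect_false(is_extension(ann(mism), ann(base)))
  # opposite strand never extends
  expect_false(is_extension(ann(tx("c2", list(c(1, 10), c(21, 30), c(41, 60)),
                                  strand = "-")), ann(base)))
})

test_that("strictly included transcripts are discarded, incompatible ones kept", {
  u <- tx("U", list(c(100, 200), c(300, 400), c(500, 600)))
  # monoexonic inside a single exon of U
  m <- tx("m", list(c(310, 380)))
  out <- remove_contained(ann(u, m), protect = FALSE)
  expect_equal(out$transcript_id, "U")
  expect_match(out$contains, "m")

  # spliced prefix of U with extent inside U
  p <- tx("p", list(c(100, 200), c(300, 400)))
  out <- remove_contained(ann(u, p), protect = FALSE)
  expect_equal(out$transcript_id, "U")

  # monoexonic spanning an intron of U is not within a single exon
  sp <- tx("sp", list(c(150, 350)))
  out <- remove_contained(ann(u, sp), protect = FALSE)
  expect_setequal(out$transcript_id, c("U", "sp"))

  # protected rows survive containment
  m2 <- tx("m2", list(c(310, 380)), origin = "reference")
  out <- remove_contained(ann(u, m2))
  expect_setequal(out$transcript_id, c("U", "m2"))
})

test_that("containment scan agrees with a brute-force oracle", {
  for (seed in 6:9) {
    x <- random_transcripts(30, seed = seed)
    x <- collapse_spliced(x[lengths(x$exon_starts) >= 2, ])
    out <- remove_contained(x, protect = FALSE)
    # oracle: T removed iff some U extends it and covers its extent
    removed <- vapply(seq_len(nrow(x)), function(i) {
      any(vapply(seq_len(nrow(x)), function(j) {
        if (i == j) return(FALSE)
        oracle_extends(x[j, ], x[i, ]) &&
          x$exon_starts[[j]][1] <= x$exon_starts[[i]][1] &&
          max(x$exon_ends[[j]]) >= max(x$exon_ends[[i]])
      }, logical(1)))
    }, logical(1))
    expect_setequal(out$transcript_id, x$transcript_id[!removed])
  }
})

test_that("reference models are preserved except for terminal-exon extension", {
  ref <- ann(tx("R1", list(c(100, 200), c(300, 400)), gene = "G1",
                origin = "reference", biotype = "protein_coding"),
             tx("R2", list(c(1000, 1100), c(1200, 1300)), gene = "G2",
                origin = "reference"),
             provenance = "reference")
  # same chain, 60 bp longer last exon: replaced, reference id kept
  nov <- ann(tx("n1", list(c(100, 200), c(300, 460))))
  out <- integrate_reference(nov, ref)
  expect_equal(nrow(out), 2)
  r1 <- out[out$transcript_id == "R1", ]
  expect_equal(r1$exon_ends[[1]][2], 460L)
  expect_equal(r1$transcript_biotype, "protein_coding")
  acts <- attr(out, "actions")
  expect_equal(acts$action[acts$transcript_id == "R1"], "replaced")
  expect_equal(acts$action[acts$transcript_id == "R2"], "kept")

  # novel adding a 5' intron is an isoform: both kept
  nov2 <- ann(tx("n2", list(c(10, 50), c(100, 200), c(300, 400))))
  out2 <- integrate_reference(nov2, ref)
  expect_equal(nrow(out2), 3)
  expect_equal(out2$exon_ends[[match("R1", out2$transcript_id)]][2], 400L)

  # count identity: every reference id present exactly once
  expect_equal(sum(out2$transcript_id %in% c("R1", "R2")), 2)

  expect_error(integrate_reference(ann(tx("R1", list(c(1, 50), c(80, 99)))), ref),
               "collision")
})

test_that("gene clustering matches the union-find oracle and strand rule", {
  # A overlaps B, B overlaps C, A and C disjoint: one gene
  x <- ann(tx("A", list(c(100, 200))), tx("B", list(c(180, 320))),
           tx("C", list(c(300, 380))))
  out <- assign_gene_ids(x)
  expect_equal(dplyr::n_distinct(out$gene_id), 1)

  # exonic overlap only on opposite strands: two genes
  y <- ann(tx("A", list(c(100, 200)), strand = "+"),
           tx("B", list(c(150, 250)), strand = "-"))
  expect_equal(dplyr::n_distinct(assign_gene_ids(y)$gene_id), 2)

  # random sets up to 200 transcripts against the brute-force components
  for (seed in c(21, 22)) {
    x <- random_transcripts(200, seed = seed)
    out <- assign_gene_ids(x)
    expect_true(same_partition(out$gene_id, oracle_gene_components(x)))
  }
})

test_that("components with reference members keep the first reference gene id", {
  x <- ann(
    tx("R1", list(c(100, 200)), gene = "ENSG2", origin = "reference"),
    tx("R2", list(c(150, 260)), gene = "ENSG1", origin = "reference"),
    tx("n1", list(c(240, 330))),
    tx("n2", list(c(5000, 5100)))
  )
  out <- assign_gene_ids(x)
  expect_equal(unique(out$gene_id[1:3]), "ENSG1")
  expect_equal(out$ref_gene_id[3], "ENSG1,ENSG2")
  expect_match(out$gene_id[4], "^TAGG")
})

test_that("reference ids are inherited on exact structure match only", {
  ref <- ann(tx("RB", list(c(100, 200), c(300, 400)), origin = "reference",
                biotype = "lncRNA"),
             tx("RA", list(c(90, 200), c(300, 420)), origin = "reference",
                biotype = "protein_coding"),
             tx("RM", list(c(900, 990)), origin = "reference"))
  # duplicate reference chains: both RA and RB share the chain (201,299);
  # the lexicographically smaller id wins
  x <- ann(tx("n", list(c(120, 200), c(300, 390))))
  out <- assign_reference_ids(x, ref)
  expect_equal(out$transcript_id, "RA")
  expect_equal(out$transcript_biotype, "protein_coding")

  # monoexonic: inheritance needs identical coordinates
  near <- assign_reference_ids(ann(tx("m", list(c(901, 990)))), ref)
  expect_equal(near$transcript_id, "m")
  exact <- assign_reference_ids(ann(tx("m", list(c(900, 990)))), ref)
  expect_equal(exact$transcript_id, "RM")
})

test_that("merge is idempotent and conserves every reference transcript", {
  fx <- simulate_fixtures(fixture_spec(seed = 5))
  merged <- merge_annotations(fx$assemblies, fx$reference)
  expect_equal(sum(merged$transcript_id %in% fx$reference$transcript_id),
               nrow(fx$reference))
  # no two spliced outputs share a chain
  keys <- chain_key(merged[lengths(merged$exon_starts) >= 2, ])
  expect_false(anyDuplicated(keys) > 0)
  # merging the merged output with itself and the reference changes nothing
  again <- merge_annotations(list(rerun = merged), fx$reference)
  expect_true(same_structure(merged, again))
})
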