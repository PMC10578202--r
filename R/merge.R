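#' Merge configuration
#'
#' @param keep_reference keep every reference transcript (default `TRUE`;
#'   reference models are never removed, only extended).
#' @param monoexonic_collapse collapse overlapping same-strand monoexonic
#'   transcripts into their union extent (default `TRUE`).
#' @param gene_prefix,tx_prefix id prefixes for novel genes and transcripts;
#'   ids are numbered in (chromosome, start) order so runs are deterministic.
#' @return a `merge_config` list.
#' @export
merge_config <- function(keep_reference = TRUE, monoexonic_collapse = TRUE,
                         gene_prefix = "TAGG", tx_prefix = "TAGT") {
  if (!nzchar(gene_prefix) || !nzchar(tx_prefix) || gene_prefix == tx_prefix) {
    stop("id prefixes must be non-empty and distinct", call. = FALSE)
  }
  structure(
    list(keep_reference = keep_reference,
         monoexonic_collapse = monoexonic_collapse,
         gene_prefix = gene_prefix, tx_prefix = tx_prefix),
    class = "merge_config"
  )
}

# collapse a set of member rows (same chain or same mono cluster) into one
collapse_members <- function(x, rows, new_starts, new_ends) {
  members <- x[rows, ]
  ord <- order(members$transcript_id)
  members <- members[ord, ]
  samples <- sort(unique(unlist(members$samples)))
  det <- if (length(samples) > 0) length(samples) else max(members$detection_count)
  tibble::tibble(
    transcript_id = members$transcript_id[1],
    gene_id = first_non_na(members$gene_id),
    chrom = members$chrom[1],
    strand = members$strand[1],
    exon_starts = list(as.integer(new_starts)),
    exon_ends = list(as.integer(new_ends)),
    origin = if (any(members$origin == "reference")) "reference" else "novel",
    detection_count = as.integer(det),
    samples = list(samples),
    tpm = list(merge_tpm(members$tpm)),
    transcript_biotype = first_non_na(members$transcript_biotype),
    feelnc_biotype = first_non_na(members$feelnc_biotype),
    ref_gene_id = combine_csv(members$ref_gene_id),
    contains = combine_csv(members$contains)
  )
}

#' Collapse spliced transcripts sharing an intron chain
#'
#' Transcripts on the same chromosome and strand with exactly the same
#' intron chain are collapsed into a single model whose first exon starts at
#' the minimum of the members' first-exon starts and whose last exon ends at
#' the maximum of the members' last-exon ends; internal exons are unchanged.
#' This restricts merging-time modifications to extending the first or last
#' exonic position. Per-sample TPMs are merged by maximum and the detection
#' count becomes the number of distinct source transcriptomes among members.
#'
#' @param x annotation tibble of spliced (>= 2 exon) transcripts.
#' @return collapsed annotation tibble; attribute `"collapse_map"` is a
#'   tibble mapping each input `member_id` to the surviving `transcript_id`.
#' @export
collapse_spliced <- function(x) {
  if (any(n_exons(x) < 2)) {
    stop("collapse_spliced(): monoexonic transcript in input", call. = FALSE)
  }
  keys <- chain_key(x)
  groups <- split(seq_len(nrow(x)), keys)
  out <- purrr::map(groups, function(rows) {
    starts <- x$exon_starts[[rows[1]]]
    ends <- x$exon_ends[[rows[1]]]
    starts[1] <- min(vapply(x$exon_starts[rows], `[`, integer(1), 1))
    k <- length(ends)
    ends[k] <- max(vapply(x$exon_ends[rows], function(v) v[length(v)], integer(1)))
    collapse_members(x, rows, starts, ends)
  })
  res <- as_annot(dplyr::bind_rows(out), attr(x, "provenance") %||% "merged")
  cmap <- dplyr::bind_rows(purrr::map2(groups, out, function(rows, o) {
    tibble::tibble(member_id = x$transcript_id[rows],
                   transcript_id = o$transcript_id)
  }))
  res <- res[order(res$chrom, tx_start(res), res$transcript_id), ]
  attr(res, "collapse_map") <- cmap
  res
}

#' Collapse overlapping monoexonic transcripts
#'
#' Monoexonic transcripts on the same chromosome and strand whose intervals
#' overlap (transitively) are replaced by their union extent.
#'
#' @param x annotation tibble of monoexonic transcripts.
#' @return collapsed annotation tibble with a `"collapse_map"` attribute as
#'   in [collapse_spliced()].
#' @export
collapse_monoexonic <- function(x) {
  if (any(n_exons(x) > 1)) {
    stop("collapse_monoexonic(): spliced transcript in input", call. = FALSE)
  }
  if (nrow(x) == 0) {
    attr(x, "collapse_map") <- tibble::tibble(member_id = character(),
                                              transcript_id = character())
    return(x)
  }
  st <- tx_start(x)
  en <- tx_end(x)
  key <- paste(x$chrom, x$strand)
  groups <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(st[idx], en[idx])]
    cluster_max <- -Inf
    cl <- integer(length(idx))
    cid <- 0L
    for (j in seq_along(idx)) {
      if (st[idx[j]] > cluster_max) cid <- cid + 1L
      cl[j] <- cid
      cluster_max <- max(cluster_max, en[idx[j]])
    }
    groups <- c(groups, split(idx, cl))
  }
  out <- purrr::map(groups, function(rows) {
    collapse_members(x, rows, min(st[rows]), max(en[rows]))
  })
  res <- as_annot(dplyr::bind_rows(out), attr(x, "provenance") %||% "merged")
  cmap <- dplyr::bind_rows(purrr::map2(groups, out, function(rows, o) {
    tibble::tibble(member_id = x$transcript_id[rows],
                   transcript_id = o$transcript_id)
  }))
  res <- res[order(res$chrom, tx_start(res), res$transcript_id), ]
  attr(res, "collapse_map") <- cmap
  res
}

# core extension test on raw structures; candidate extends base iff the
# base chain is a contiguous sub-chain of the candidate chain, all extra
# candidate introns lie strictly outside the base extent, and there is at
# least one extra intron 5'-ward and/or 3'-ward
is_extension_core <- function(c_chrom, c_strand, c_starts, c_ends,
                              b_chrom, b_strand, b_starts, b_ends) {
  if (c_chrom != b_chrom || c_strand != b_strand) return(FALSE)
  c_ext <- c(c_starts[1], c_ends[length(c_ends)])
  b_ext <- c(b_starts[1], b_ends[length(b_ends)])
  if (c_ext[1] > b_ext[2] || b_ext[1] > c_ext[2]) return(FALSE)
  ci <- intron_chain(c_starts, c_ends)
  bi <- intron_chain(b_starts, b_ends)
  k <- length(ci$starts)
  m <- length(bi$starts)
  if (m == 0 || k <= m) return(FALSE)
  for (j in seq_len(k - m + 1)) {
    if (all(ci$starts[j:(j + m - 1)] == bi$starts) &&
        all(ci$ends[j:(j + m - 1)] == bi$ends)) {
      before <- seq_len(j - 1)
      after <- if (j + m <= k) (j + m):k else integer()
      ok_before <- length(before) == 0 || all(ci$ends[before] < b_ext[1])
      ok_after <- length(after) == 0 || all(ci$starts[after] > b_ext[2])
      if (ok_before && ok_after) return(TRUE)
    }
  }
  FALSE
}

#' Does one spliced transcript extend another?
#'
#' `candidate` extends `base` when both are spliced on the same chromosome
#' and strand, their extents overlap by at least 1 bp, `base`'s intron chain
#' is a contiguous sub-chain of `candidate`'s chain on the overlapping
#' portion, and `candidate` has at least one additional intron 5'-ward
#' and/or 3'-ward of `base`'s chain.
#'
#' @param candidate,base one-row annotation tibbles (spliced).
#' @return logical scalar.
#' @export
is_extension <- function(candidate, base) {
  if (nrow(candidate) != 1 || nrow(base) != 1) {
    stop("is_extension() compares exactly one candidate and one base",
         call. = FALSE)
  }
  if (length(candidate$exon_starts[[1]]) < 2 || length(base$exon_starts[[1]]) < 2) {
    stop("is_extension() requires spliced transcripts", call. = FALSE)
  }
  is_extension_core(candidate$chrom, candidate$strand,
                    candidate$exon_starts[[1]], candidate$exon_ends[[1]],
                    base$chrom, base$strand,
                    base$exon_starts[[1]], base$exon_ends[[1]])
}

# is monoexonic interval [s, e] within a single exon of row j of x?
mono_in_exon <- function(x, j, s, e) {
  any(x$exon_starts[[j]] <= s & x$exon_ends[[j]] >= e)
}

#' Discard transcripts strictly included in others
#'
#' A spliced transcript is removed when another same-strand transcript
#' extends it ([is_extension()]) and covers its extent; a monoexonic
#' transcript is removed when its interval lies within a single exon of
#' another same-strand transcript. Removal requires intron-chain
#' compatibility: a transcript is never discarded merely because its extent
#' lies inside an incompatible model. Removed ids are recorded in the
#' surviving container's `contains` attribute.
#'
#' @param x annotation tibble (collapse already applied).
#' @param protect logical vector (recycled); protected rows are never
#'   removed. Defaults to protecting reference-origin transcripts.
#' @return annotation tibble of survivors; attribute `"removed"` is a tibble
#'   with columns `transcript_id`, `container`.
#' @export
remove_contained <- function(x, protect = x$origin == "reference") {
  n <- nrow(x)
  protect <- rep_len(protect, n)
  st <- tx_start(x)
  en <- tx_end(x)
  nex <- n_exons(x)
  removed <- logical(n)
  container <- rep(NA_character_, n)
  ord <- order(x$transcript_id)
  for (i in seq_len(n)) {
    if (protect[i]) next
    cand <- ord[x$chrom[ord] == x$chrom[i] & x$strand[ord] == x$strand[i] &
                  ord != i & st[ord] <= st[i] & en[ord] >= en[i]]
    for (j in cand) {
      hit <- if (nex[i] == 1) {
        mono_in_exon(x, j, st[i], en[i])
      } else if (nex[j] >= 2) {
        is_extension_core(x$chrom[j], x$strand[j],
                          x$exon_starts[[j]], x$exon_ends[[j]],
                          x$chrom[i], x$strand[i],
                          x$exon_starts[[i]], x$exon_ends[[i]])
      } else FALSE
      if (hit) {
        removed[i] <- TRUE
        container[i] <- x$transcript_id[j]
        break
      }
    }
  }
  out <- x[!removed, ]
  # record removed ids on surviving containers
  if (any(removed)) {
    rem <- tibble::tibble(transcript_id = x$transcript_id[removed],
                          container = container[removed])
    for (k in seq_len(nrow(rem))) {
      # walk up to a surviving container
      cont <- rem$container[k]
      seen <- character()
      while (cont %in% rem$transcript_id && !cont %in% seen) {
        seen <- c(seen, cont)
        cont <- rem$container[match(cont, rem$transcript_id)]
      }
      idx <- match(cont, out$transcript_id)
      if (!is.na(idx)) {
        out$contains[idx] <- combine_csv(out$contains[idx], rem$transcript_id[k])
      }
    }
  } else {
    rem <- tibble::tibble(transcript_id = character(), container = character())
  }
  out <- as_annot(out, attr(x, "provenance") %||% "merged")
  attr(out, "removed") <- rem
  out
}

#' Integrate collapsed novel transcripts into the reference annotation
#'
#' Every reference transcript is reported unchanged, except that a reference
#' transcript whose intron chain equals a novel transcript's chain but with
#' shorter terminal exon(s) is extended to the longer form, keeping the
#' reference transcript id and biotype. Novel transcripts with a reference
#' chain but no extension are absorbed into the reference model; all other
#' novel transcripts are added. Monoexonic novel transcripts overlapping a
#' same-strand reference monoexonic transcript are merged into it the same
#' way (union extent).
#'
#' @param novel collapsed, novel-only annotation tibble.
#' @param reference reference annotation tibble.
#' @param config a [merge_config()].
#' @return merged annotation tibble; attribute `"actions"` is a tibble with
#'   columns `transcript_id`, `action`
#'   (`kept`/`replaced`/`absorbed`/`added`) and `partner`.
#' @export
integrate_reference <- function(novel, reference, config = merge_config()) {
  clash <- intersect(novel$transcript_id, reference$transcript_id)
  if (length(clash) > 0) {
    stop("transcript id collision between novel and reference: ", clash[1],
         call. = FALSE)
  }
  ref <- tibble::as_tibble(reference)
  ref$origin <- "reference"
  nov <- tibble::as_tibble(novel)
  nov$origin <- "novel"
  actions <- tibble::tibble(
    transcript_id = ref$transcript_id,
    action = rep("kept", nrow(ref)),
    partner = rep(NA_character_, nrow(ref))
  )
  nov_spliced <- n_exons(nov) >= 2
  ref_spliced <- n_exons(ref) >= 2
  ref_keys <- chain_key(ref)
  nov_keys <- chain_key(nov)
  absorb <- logical(nrow(nov))

  for (i in which(nov_spliced)) {
    hits <- which(ref_spliced & ref_keys == nov_keys[i])
    if (length(hits) == 0) next
    j <- hits[order(ref$transcript_id[hits])][1]
    rs <- ref$exon_starts[[j]]; re <- ref$exon_ends[[j]]
    ns <- nov$exon_starts[[i]]; ne <- nov$exon_ends[[i]]
    extended <- ns[1] < rs[1] || ne[length(ne)] > re[length(re)]
    rs[1] <- min(rs[1], ns[1])
    re[length(re)] <- max(re[length(re)], ne[length(ne)])
    ref$exon_starts[[j]] <- rs
    ref$exon_ends[[j]] <- re
    ref$samples[[j]] <- sort(unique(c(ref$samples[[j]], nov$samples[[i]])))
    ref$detection_count[j] <- max(length(ref$samples[[j]]),
                                  nov$detection_count[i])
    ref$tpm[[j]] <- merge_tpm(list(ref$tpm[[j]], nov$tpm[[i]]))
    ref$contains[j] <- combine_csv(ref$contains[j], nov$contains[i])
    k <- match(ref$transcript_id[j], actions$transcript_id)
    if (extended) actions$action[k] <- "replaced"
    actions$partner[k] <- nov$transcript_id[i]
    absorb[i] <- TRUE
  }

  nov_st <- tx_start(nov); nov_en <- tx_end(nov)
  ref_st <- tx_start(ref); ref_en <- tx_end(ref)
  mono_assign <- list()
  for (i in which(!nov_spliced)) {
    hits <- which(!ref_spliced & ref$chrom == nov$chrom[i] &
                    ref$strand == nov$strand[i] &
                    ref_st <= nov_en[i] & ref_en >= nov_st[i])
    if (length(hits) == 0) next
    ov <- pmin(ref_en[hits], nov_en[i]) - pmax(ref_st[hits], nov_st[i]) + 1L
    j <- hits[order(-ov, ref$transcript_id[hits])][1]
    mono_assign[[as.character(j)]] <- c(mono_assign[[as.character(j)]], i)
    absorb[i] <- TRUE
  }
  for (js in names(mono_assign)) {
    j <- as.integer(js)
    ids <- mono_assign[[js]]
    new_s <- min(ref_st[j], nov_st[ids])
    new_e <- max(ref_en[j], nov_en[ids])
    extended <- new_s < ref_st[j] || new_e > ref_en[j]
    ref$exon_starts[[j]] <- new_s
    ref$exon_ends[[j]] <- new_e
    ref$samples[[j]] <- sort(unique(c(ref$samples[[j]],
                                      unlist(nov$samples[ids]))))
    ref$detection_count[j] <- max(length(ref$samples[[j]]),
                                  nov$detection_count[ids])
    ref$tpm[[j]] <- merge_tpm(c(list(ref$tpm[[j]]), nov$tpm[ids]))
    ref$contains[j] <- combine_csv(ref$contains[j], nov$contains[ids])
    k <- match(ref$transcript_id[j], actions$transcript_id)
    if (extended) actions$action[k] <- "replaced"
    actions$partner[k] <- paste(sort(nov$transcript_id[ids]), collapse = ",")
  }

  added <- nov[!absorb, ]
  actions <- dplyr::bind_rows(
    actions,
    tibble::tibble(transcript_id = added$transcript_id,
                   action = rep("added", nrow(added)),
                   partner = rep(NA_character_, nrow(added))),
    tibble::tibble(transcript_id = nov$transcript_id[absorb],
                   action = rep("absorbed", sum(absorb)),
                   partner = rep(NA_character_, sum(absorb)))
  )
  out <- dplyr::bind_rows(ref, added)
  out <- out[order(out$chrom, tx_start(out), out$transcript_id), ]
  out <- as_annot(out, "merged")
  validate_annotation(out)
  stopifnot(sum(out$origin == "reference") == nrow(reference))
  attr(out, "actions") <- actions
  out
}

#' Inherit reference transcript ids and biotypes
#'
#' A novel spliced transcript whose intron chain exactly matches a reference
#' transcript's chain (same chromosome and strand) inherits that reference
#' transcript id and `transcript_biotype`; a monoexonic transcript inherits
#' only on identical (chromosome, strand, start, end). Ties between
#' duplicate reference chains go to the lexicographically smallest reference
#' transcript id. Inheritance is skipped when it would duplicate an id
#' already present in the annotation.
#'
#' @param x merged annotation tibble.
#' @param reference reference annotation tibble.
#' @return `x` with ids/biotypes inherited where applicable.
#' @export
assign_reference_ids <- function(x, reference) {
  ref_spliced <- n_exons(reference) >= 2
  ref_keys <- chain_key(reference)
  ref_mono_key <- paste(reference$chrom, reference$strand,
                        tx_start(reference), tx_end(reference))
  x_keys <- chain_key(x)
  x_mono_key <- paste(x$chrom, x$strand, tx_start(x), tx_end(x))
  spliced <- n_exons(x) >= 2
  for (i in seq_len(nrow(x))) {
    if (x$origin[i] != "novel") next
    hits <- if (spliced[i]) {
      which(ref_spliced & ref_keys == x_keys[i])
    } else {
      which(!ref_spliced & ref_mono_key == x_mono_key[i])
    }
    if (length(hits) == 0) next
    j <- hits[order(reference$transcript_id[hits])][1]
    new_id <- reference$transcript_id[j]
    if (new_id %in% x$transcript_id) next
    x$transcript_id[i] <- new_id
    x$transcript_biotype[i] <- reference$transcript_biotype[j]
  }
  x
}

# minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

#' Cluster transcripts into gene loci and assign gene ids
#'
#' Gene membership is the connected components of the graph joining
#' transcripts with >= 1 bp of same-strand exonic overlap. Components
#' containing reference transcripts keep the lexicographically first
#' reference gene id and list every same-strand exonically overlapping
#' reference gene in `ref_gene_id`; purely novel components receive
#' deterministic ids in (chromosome, start) order.
#'
#' @param x annotation tibble.
#' @param config a [merge_config()] (id prefix).
#' @return `x` with `gene_id` and `ref_gene_id` assigned.
#' @export
assign_gene_ids <- function(x, config = merge_config()) {
  n <- nrow(x)
  if (n == 0) return(x)
  parent <- uf_new(n)
  key <- paste(x$chrom, x$strand)
  for (k in unique(key)) {
    idx <- which(key == k)
    ex <- dplyr::bind_rows(purrr::map(idx, function(i) {
      tibble::tibble(tx = i, s = x$exon_starts[[i]], e = x$exon_ends[[i]])
    }))
    ex <- ex[order(ex$s, ex$e), ]
    # sweep: an exon starting at or before the running maximum end overlaps
    # the exon achieving that maximum, so it joins the cluster's union set
    cluster_max <- -Inf
    rep_tx <- NA_integer_
    for (r in seq_len(nrow(ex))) {
      if (ex$s[r] <= cluster_max) {
        parent <- uf_union(parent, ex$tx[r], rep_tx)
      } else {
        rep_tx <- ex$tx[r]
      }
      cluster_max <- max(cluster_max, ex$e[r])
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  groups <- split(seq_len(n), comp)
  st <- tx_start(x)
  # order novel components genomically for deterministic numbering
  comp_info <- tibble::tibble(
    comp = names(groups),
    chrom = vapply(groups, function(g) x$chrom[g[1]], character(1)),
    start = vapply(groups, function(g) min(st[g]), integer(1)),
    has_ref = vapply(groups, function(g) {
      any(x$origin[g] == "reference" & !is.na(x$gene_id[g]))
    }, logical(1))
  )
  comp_info <- comp_info[order(comp_info$chrom, comp_info$start, comp_info$comp), ]
  counter <- 0L
  for (r in seq_len(nrow(comp_info))) {
    g <- groups[[comp_info$comp[r]]]
    refs <- sort(unique(x$gene_id[g][x$origin[g] == "reference" &
                                       !is.na(x$gene_id[g])]))
    if (length(refs) > 0) {
      gid <- refs[1]
      x$ref_gene_id[g] <- paste(refs, collapse = ",")
    } else {
      counter <- counter + 1L
      gid <- paste0(config$gene_prefix, sprintf("%06d", counter))
    }
    x$gene_id[g] <- gid
  }
  x
}

#' Merge per-sample transcript assemblies with a reference annotation
#'
#' End-to-end merge: pools the sample assemblies, collapses spliced
#' transcripts by intron chain and monoexonic transcripts by interval union,
#' discards strictly included models, integrates the reference (which is
#' preserved except for terminal-exon extensions), inherits reference
#' transcript ids, renumbers surviving novel transcripts deterministically,
#' and clusters transcripts into gene loci.
#'
#' @param assemblies named list of annotation tibbles, one per input
#'   transcriptome (names are the sample names; use
#'   `read_gtf(path, sample = name)`).
#' @param reference reference annotation tibble.
#' @param config a [merge_config()].
#' @return merged annotation tibble. The attribute `"merge_report"`
#'   (accessor [merge_report()]) records, for every input and reference
#'   transcript, the action taken: `kept`, `collapsed`, `contained`,
#'   `absorbed`, `replaced`, or `added`.
#' @export
merge_annotations <- function(assemblies, reference, config = merge_config()) {
  if (length(assemblies) > 0 &&
      (is.null(names(assemblies)) || any(!nzchar(names(assemblies))))) {
    stop("assemblies must be a named list (sample names)", call. = FALSE)
  }
  pool <- purrr::imap(assemblies, function(a, s) {
    a <- tibble::as_tibble(a)
    if (nrow(a) == 0) return(NULL)
    a$origin <- "novel"
    a$transcript_id <- paste0(s, ":", a$transcript_id)
    a$gene_id <- NA_character_
    a$samples <- rep(list(s), nrow(a))
    a$detection_count <- 1L
    a$tpm <- lapply(a$tpm, function(v) {
      if (length(v) == 0) return(v)
      stats::setNames(max(v), s)
    })
    a
  })
  pool <- dplyr::bind_rows(pool)
  report <- tibble::tibble(transcript_id = character(), action = character())

  if (nrow(pool) > 0) {
    pool <- as_annot(pool)
    spl <- pool[n_exons(pool) >= 2, ]
    mono <- pool[n_exons(pool) == 1, ]
    maps <- list()
    if (nrow(spl) > 0) {
      spl <- collapse_spliced(spl)
      maps$spl <- attr(spl, "collapse_map")
    }
    if (nrow(mono) > 0 && config$monoexonic_collapse) {
      mono <- collapse_monoexonic(mono)
      maps$mono <- attr(mono, "collapse_map")
    }
    cmap <- dplyr::bind_rows(maps)
    collapsed_ids <- cmap$member_id[cmap$member_id != cmap$transcript_id]
    novel <- as_annot(dplyr::bind_rows(spl, mono))
    novel <- remove_contained(novel, protect = FALSE)
    contained_ids <- attr(novel, "removed")$transcript_id
    report <- dplyr::bind_rows(
      report,
      tibble::tibble(transcript_id = collapsed_ids,
                     action = rep("collapsed", length(collapsed_ids))),
      tibble::tibble(transcript_id = contained_ids,
                     action = rep("contained", length(contained_ids)))
    )
  } else {
    novel <- annotation(tibble::tibble())
  }

  merged <- integrate_reference(novel, reference, config)
  actions <- attr(merged, "actions")
  merged <- remove_contained(merged, protect = merged$origin == "reference")
  contained2 <- attr(merged, "removed")$transcript_id
  if (length(contained2) > 0) {
    actions <- actions[!actions$transcript_id %in% contained2, ]
    actions <- dplyr::bind_rows(
      actions,
      tibble::tibble(transcript_id = contained2,
                     action = rep("contained", length(contained2)),
                     partner = rep(NA_character_, length(contained2)))
    )
  }
  merged <- assign_reference_ids(merged, reference)

  # deterministic novel transcript ids in genomic order
  is_novel <- merged$origin == "novel" &
    !merged$transcript_id %in% reference$transcript_id
  if (any(is_novel)) {
    idx <- which(is_novel)
    ord <- idx[order(merged$chrom[idx], tx_start(merged)[idx],
                     tx_end(merged)[idx], merged$transcript_id[idx])]
    new_ids <- paste0(config$tx_prefix, sprintf("%06d", seq_along(ord)))
    old <- merged$transcript_id[ord]
    merged$transcript_id[ord] <- new_ids
    actions$transcript_id[match(old, actions$transcript_id)] <- new_ids
  }
  merged <- assign_gene_ids(merged, config)
  merged <- merged[order(merged$chrom, tx_start(merged), merged$transcript_id), ]
  merged <- as_annot(merged, "merged")
  validate_annotation(merged)
  report <- dplyr::bind_rows(report, actions[, c("transcript_id", "action")])
  attr(merged, "merge_report") <- report
  merged
}

#' Per-transcript merge actions
#'
#' @param x result of [merge_annotations()].
#' @return tibble with columns `transcript_id`, `action`.
#' @export
merge_report <- function(x) {
  attr(x, "merge_report") %||%
    stop("no merge report attached; run merge_annotations()", call. = FALSE)
}
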