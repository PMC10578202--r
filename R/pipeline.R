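#' Run the annotation-improvement pipeline end to end
#'
#' Executes merge, filtering, classification, QC and (when an expression
#' matrix is given) expression statistics in order, writing headered TSV
#' reports plus the merged GTF and a run manifest to `out_dir`. All outputs
#' are deterministic given the inputs.
#'
#' @param reference_gtf path to the reference annotation GTF.
#' @param assembly_gtfs named character vector of per-sample assembly GTFs
#'   (names are the sample names; unnamed vectors use the file base names).
#' @param out_dir output directory (created).
#' @param genome_fasta optional genome FASTA (enables canonicity and 3'
#'   completion QC).
#' @param peaks_bed optional BED of open-chromatin peaks (5' completion QC).
#' @param expression_tsv,metadata_tsv optional expression matrix and sample
#'   metadata (tau, breadth, similarity, clustering).
#' @param catalog_gtf optional external catalog for [catalog_match()].
#' @param min_transcriptomes,min_tpm transcript filter thresholds
#'   (defaults 2 and 0.1).
#' @param tau_threshold tissue-specificity threshold (default 0.9).
#' @param tts_window polyA distance bound in bp (default 50).
#' @param lnc_window lncRNA positional search window in bp (default 100000).
#' @param tpm_attribute GTF attribute carrying assembly TPMs.
#' @return invisible list with the merged annotation, classification table,
#'   QC report and expression results.
#' @export
run_pipeline <- function(reference_gtf, assembly_gtfs, out_dir,
                         genome_fasta = NULL, peaks_bed = NULL,
                         expression_tsv = NULL, metadata_tsv = NULL,
                         catalog_gtf = NULL, min_transcriptomes = 2L,
                         min_tpm = 0.1, tau_threshold = 0.9, tts_window = 50L,
                         lnc_window = 100000L, tpm_attribute = "TPM") {
  if (!file.exists(reference_gtf)) {
    stop("configuration error: reference GTF not found: ", reference_gtf,
         call. = FALSE)
  }
  if (!is.null(expression_tsv) && is.null(metadata_tsv)) {
    stop("configuration error: expression matrix given without metadata",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reference <- read_gtf(reference_gtf, tpm_attribute = tpm_attribute)
  if (length(assembly_gtfs) > 0 && is.null(names(assembly_gtfs))) {
    names(assembly_gtfs) <- sub("\\.gtf$", "", basename(assembly_gtfs))
  }
  assemblies <- purrr::imap(as.list(assembly_gtfs), function(p, s) {
    read_gtf(p, tpm_attribute = tpm_attribute, sample = s)
  })

  merged <- merge_annotations(assemblies, reference)
  fcfg <- filter_config(min_transcriptomes = min_transcriptomes,
                        min_tpm = min_tpm)
  filtered <- filter_transcripts(merged, fcfg)
  filtered <- assign_gene_ids(filtered)
  write_gtf(filtered, file.path(out_dir, "novel_annotation.gtf"))
  utils::write.table(merge_report(merged),
                     file.path(out_dir, "merge_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  catalog <- if (!is.null(catalog_gtf)) read_gtf(catalog_gtf) else NULL
  classes <- classify_transcripts(filtered, reference, catalog = catalog,
                                  lnc_window = lnc_window)
  utils::write.table(classes, file.path(out_dir, "transcript_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  genome <- if (!is.null(genome_fasta)) read_fasta(genome_fasta) else NULL
  peaks <- if (!is.null(peaks_bed)) read_bed(peaks_bed) else NULL
  qc <- qc_report(filtered, genome = genome, peaks = peaks,
                  tts_window = tts_window)
  utils::write.table(qc, file.path(out_dir, "qc_metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  expr_out <- NULL
  if (!is.null(expression_tsv)) {
    mat <- read_expression_matrix(expression_tsv)
    meta <- read_sample_metadata(metadata_tsv)
    specific <- tissue_specific_genes(mat, meta, tau_threshold = tau_threshold)
    breadth <- expression_breadth(mat, meta)
    sim <- sample_similarity(mat)
    clust <- cluster_samples(sim)
    utils::write.table(specific,
                       file.path(out_dir, "tissue_specific_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(breadth, file.path(out_dir, "expression_breadth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tidy(clust), file.path(out_dir, "sample_clustering.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    expr_out <- list(specific = specific, breadth = breadth, similarity = sim,
                     clustering = clust)
  }

  manifest <- c(
    paste0("annotweave version: ",
           as.character(utils::packageVersion("annotweave"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("reference: ", reference_gtf, " md5=",
           unname(tools::md5sum(reference_gtf))),
    vapply(seq_along(assembly_gtfs), function(i) {
      paste0("assembly ", names(assembly_gtfs)[i], ": ", assembly_gtfs[i],
             " md5=", unname(tools::md5sum(assembly_gtfs[[i]])))
    }, character(1)),
    paste0("min_transcriptomes: ", min_transcriptomes),
    paste0("min_tpm: ", min_tpm),
    paste0("tau_threshold: ", tau_threshold),
    paste0("tts_window: ", tts_window),
    paste0("lnc_window: ", lnc_window)
  )
  writeLines(manifest, file.path(out_dir, "run_manifest.txt"))

  invisible(list(annotation = filtered, classes = classes, qc = qc,
                 expression = expr_out))
}
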