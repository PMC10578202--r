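#' Read a TPM expression matrix
#'
#' Tab-separated, header row of sample names, first column feature ids.
#'
#' @param path TSV file.
#' @return tibble with column `feature_id` followed by one numeric column
#'   per sample.
#' @export
read_expression_matrix <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(x)[1] <- "feature_id"
  x <- tibble::as_tibble(x)
  vals <- as.matrix(x[, -1])
  if (anyNA(vals)) stop("missing TPM values in ", path, call. = FALSE)
  if (any(vals < 0)) stop("negative TPM values in ", path, call. = FALSE)
  if (anyDuplicated(names(x)[-1])) {
    stop("duplicate sample names in ", path, call. = FALSE)
  }
  x
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample`, `tissue`, `stage`, `replicate`.
#' @return tibble.
#' @export
read_sample_metadata <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  need <- c("sample", "tissue", "stage", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x
}

expr_values <- function(mat) {
  m <- as.matrix(mat[, setdiff(names(mat), "feature_id")])
  rownames(m) <- mat$feature_id
  storage.mode(m) <- "double"
  m
}

#' Expressed-feature calls
#'
#' A feature is expressed when at least `min_samples` samples have TPM at or
#' above `min_tpm` (both bounds inclusive).
#'
#' @param mat expression tibble (`feature_id` + sample columns).
#' @param min_tpm TPM threshold (default 0.1).
#' @param min_samples sample-count threshold (default 2).
#' @return logical vector, one entry per feature.
#' @export
is_expressed <- function(mat, min_tpm = 0.1, min_samples = 2L) {
  m <- expr_values(mat)
  rowSums(m >= min_tpm) >= min_samples
}

#' Tau tissue-specificity index
#'
#' For per-tissue mean expression x_1..x_N,
#' tau = sum_i (1 - x_i / max_j x_j) / (N - 1): 0 for uniform expression, 1
#' for single-tissue expression. Defined for N >= 2 tissues and a non-zero
#' maximum; invariant under positive scaling.
#'
#' @param x numeric vector of per-tissue means (non-negative).
#' @return tau in \[0,1\].
#' @export
#' @examples
#' tau(c(0, 0, 8)) # 1
#' tau(c(5, 5, 5)) # 0
#' tau(c(1, 2, 4)) # 0.625
tau <- function(x) {
  if (length(x) < 2) stop("tau requires >= 2 tissues", call. = FALSE)
  if (any(x < 0)) stop("tau requires non-negative values", call. = FALSE)
  mx <- max(x)
  if (mx == 0) stop("tau undefined for an all-zero profile", call. = FALSE)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Per-tissue mean expression
#'
#' @param mat expression tibble.
#' @param metadata tibble with `sample`, `tissue` covering every sample
#'   column of `mat`.
#' @return matrix of per-tissue means (features x tissues).
#' @export
tissue_means <- function(mat, metadata) {
  m <- expr_values(mat)
  miss <- setdiff(colnames(m), metadata$sample)
  if (length(miss) > 0) {
    stop("metadata missing for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tissues <- sort(unique(metadata$tissue))
  out <- vapply(tissues, function(t) {
    cols <- metadata$sample[metadata$tissue == t]
    rowMeans(m[, colnames(m) %in% cols, drop = FALSE])
  }, numeric(nrow(m)))
  matrix(out, nrow = nrow(m), dimnames = list(rownames(m), tissues))
}

#' Tissue-specific features by tau
#'
#' Features with tau strictly above the threshold are assigned to the tissue
#' where their mean expression is highest (ties go to the lexicographically
#' first tissue). Features with an all-zero profile have undefined tau and
#' are skipped.
#'
#' @param mat expression tibble.
#' @param metadata sample metadata with `sample` and `tissue`.
#' @param tau_threshold strict lower bound for calling specificity
#'   (default 0.9).
#' @return tibble with `feature_id`, `tau`, `tissue`.
#' @export
tissue_specific_genes <- function(mat, metadata, tau_threshold = 0.9) {
  tm <- tissue_means(mat, metadata)
  keep <- apply(tm, 1, max) > 0
  taus <- apply(tm[keep, , drop = FALSE], 1, tau)
  best <- colnames(tm)[apply(tm[keep, , drop = FALSE], 1, which.max)]
  out <- tibble::tibble(feature_id = rownames(tm)[keep], tau = taus,
                        tissue = best)
  out[out$tau > tau_threshold, ]
}

#' Expression breadth
#'
#' The number of tissues in which a feature is expressed, where expressed in
#' a tissue means TPM strictly above `min_tpm` in at least `min_samples` of
#' that tissue's samples. (Note the strict bound here versus the inclusive
#' bound of [is_expressed()]; the two calls follow different conventions.)
#'
#' @param mat expression tibble.
#' @param metadata sample metadata with `sample` and `tissue`.
#' @param min_tpm strict TPM bound (default 0.1).
#' @param min_samples per-tissue sample-count threshold (default 4).
#' @return tibble with `feature_id`, `breadth`.
#' @export
expression_breadth <- function(mat, metadata, min_tpm = 0.1, min_samples = 4L) {
  m <- expr_values(mat)
  tissues <- sort(unique(metadata$tissue))
  counts <- vapply(tissues, function(t) {
    cols <- metadata$sample[metadata$tissue == t]
    rowSums(m[, colnames(m) %in% cols, drop = FALSE] > min_tpm)
  }, numeric(nrow(m)))
  counts <- matrix(counts, nrow = nrow(m))
  tibble::tibble(feature_id = rownames(m),
                 breadth = as.integer(rowSums(counts >= min_samples)))
}

#' Sample similarity matrix
#'
#' Pearson correlation of log10(TPM + pseudo-count) profiles over all
#' features, for every pair of samples.
#'
#' @param mat expression tibble (>= 2 features, >= 2 samples).
#' @param pseudo_count added before the log (default 0.1).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sample_similarity <- function(mat, pseudo_count = 0.1) {
  m <- expr_values(mat)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("similarity needs >= 2 features and >= 2 samples", call. = FALSE)
  }
  lg <- log10(m + pseudo_count)
  sds <- apply(lg, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance expression profile for sample ",
         colnames(m)[which(sds == 0)[1]], call. = FALSE)
  }
  s <- stats::cor(lg)
  diag(s) <- 1
  s
}
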