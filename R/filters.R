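#' Transcript filter configuration
#'
#' @param min_transcriptomes minimum number of input transcriptomes a novel
#'   transcript must be detected in (default 2).
#' @param min_tpm minimum across-sample maximum TPM a novel transcript must
#'   reach (default 0.1); a maximum exactly equal to the threshold survives.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_transcriptomes = 2L, min_tpm = 0.1) {
  if (min_transcriptomes < 1) stop("min_transcriptomes must be >= 1", call. = FALSE)
  if (min_tpm < 0) stop("min_tpm must be >= 0", call. = FALSE)
  structure(list(min_transcriptomes = as.integer(min_transcriptomes),
                 min_tpm = min_tpm),
            class = "filter_config")
}

#' Cross-sample consistency filter
#'
#' Novel transcripts detected in fewer than `min_transcriptomes` input
#' transcriptomes are discarded; reference transcripts are always kept.
#'
#' @param x annotation tibble carrying `detection_count` and `origin`.
#' @param config a [filter_config()].
#' @return filtered annotation tibble; attribute `"removed"` lists the
#'   discarded transcript ids.
#' @export
consistency_filter <- function(x, config = filter_config()) {
  novel <- x$origin == "novel"
  if (any(novel & is.na(x$detection_count))) {
    bad <- x$transcript_id[which(novel & is.na(x$detection_count))[1]]
    stop("novel transcript ", bad, " has no detection count", call. = FALSE)
  }
  drop <- novel & x$detection_count < config$min_transcriptomes
  out <- as_annot(x[!drop, ], attr(x, "provenance") %||% "merged")
  attr(out, "removed") <- x$transcript_id[drop]
  out
}

#' Expression filter
#'
#' Novel transcripts whose highest TPM across all transcriptomes does not
#' reach `min_tpm` are discarded (a maximum exactly at the threshold is
#' kept); reference transcripts are always kept. A novel transcript with no
#' TPM values has maximum 0 and is discarded for any positive threshold.
#'
#' @inheritParams consistency_filter
#' @return filtered annotation tibble; attribute `"removed"` lists the
#'   discarded transcript ids.
#' @export
expression_filter <- function(x, config = filter_config()) {
  if (any(unlist(x$tpm) < 0)) {
    stop("negative TPM value in annotation", call. = FALSE)
  }
  drop <- x$origin == "novel" & max_tpm(x) < config$min_tpm
  out <- as_annot(x[!drop, ], attr(x, "provenance") %||% "merged")
  attr(out, "removed") <- x$transcript_id[drop]
  out
}

#' Apply both transcript filters
#'
#' Runs the consistency filter then the expression filter (the two commute).
#'
#' @inheritParams consistency_filter
#' @return filtered annotation tibble; attribute `"removed"` lists all
#'   discarded transcript ids.
#' @export
filter_transcripts <- function(x, config = filter_config()) {
  a <- consistency_filter(x, config)
  b <- expression_filter(a, config)
  attr(b, "removed") <- c(attr(a, "removed"), attr(b, "removed"))
  b
}
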