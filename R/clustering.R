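#' Complete-linkage clustering of samples
#'
#' Agglomerative clustering on the distance d = 1 - similarity with complete
#' linkage. At every step the pair of clusters with the smallest maximum
#' pairwise distance is merged; ties are broken by the smallest original
#' sample index (of either cluster), making the merge sequence fully
#' deterministic.
#'
#' @param similarity symmetric similarity matrix (e.g. from
#'   [sample_similarity()]) with sample names as dimnames.
#' @return an object of class `sample_clustering`: list with `labels`,
#'   `merge` (hclust-style merge matrix), `height`, and `members` (the
#'   sample labels in each merged cluster, per step). Supports
#'   [generics::tidy()], [generics::glance()], `as.hclust()` and
#'   [ggplot2::autoplot()].
#' @export
cluster_samples <- function(similarity) {
  if (!isTRUE(all.equal(similarity, t(similarity), tolerance = 1e-8))) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  n <- ncol(similarity)
  if (n < 2) stop("need >= 2 samples to cluster", call. = FALSE)
  labels <- colnames(similarity) %||% paste0("S", seq_len(n))
  d <- 1 - similarity
  diag(d) <- 0
  # active clusters: list of member indices; id encoding as in hclust:
  # -k for singleton sample k, +m for the cluster formed at step m
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- NULL
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        dist_ab <- max(d[clusters[[a]], clusters[[b]]])
        cand <- list(a = a, b = b, dist = dist_ab,
                     tie = sort(c(min(clusters[[a]]), min(clusters[[b]]))))
        if (is.null(best) || cand$dist < best$dist - 1e-15 ||
            (abs(cand$dist - best$dist) <= 1e-15 &&
               (cand$tie[1] < best$tie[1] ||
                  (cand$tie[1] == best$tie[1] && cand$tie[2] < best$tie[2])))) {
          best <- cand
        }
      }
    }
    pair <- sort(c(ids[best$a], ids[best$b]))
    # hclust convention: singletons (negative) before clusters (positive)
    merge[step, ] <- if (pair[1] < 0 && pair[2] < 0) pair
      else if (pair[1] < 0) pair else sort(pair)
    height[step] <- best$dist
    new_members <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    members[[step]] <- labels[new_members]
    clusters <- c(clusters[-c(best$a, best$b)], list(new_members))
    ids <- c(ids[-c(best$a, best$b)], step)
  }
  structure(
    list(labels = labels, merge = merge, height = height, members = members),
    class = "sample_clustering"
  )
}

#' Convert a sample clustering to an hclust object
#'
#' @param x a `sample_clustering`.
#' @param ... unused.
#' @return an object of class `hclust`.
#' @export
as.hclust.sample_clustering <- function(x, ...) {
  h <- list(
    merge = x$merge, height = x$height,
    order = leaf_order(x$merge),
    labels = x$labels, method = "complete",
    dist.method = "1 - similarity", call = match.call()
  )
  class(h) <- "hclust"
  h
}

# leaf order for plotting: left-to-right traversal of the merge tree
leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("Complete-linkage sample clustering:", length(x$labels), "samples,",
      nrow(x$merge), "merges\n")
  cat("merge heights:", paste(signif(x$height, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a sample clustering into one row per merge
#'
#' @param x a `sample_clustering` from [cluster_samples()].
#' @param ... unused.
#' @return tibble with `step`, `height`, `merged` (labels of the cluster
#'   formed at that step).
#' @method tidy sample_clustering
#' @export
tidy.sample_clustering <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$height),
    height = x$height,
    merged = vapply(x$members, paste, character(1), collapse = ",")
  )
}

#' One-row summary of a sample clustering
#'
#' @param x a `sample_clustering`.
#' @param ... unused.
#' @return tibble with `n_samples`, `n_merges`, `min_height`, `max_height`.
#' @method glance sample_clustering
#' @export
glance.sample_clustering <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$labels),
    n_merges = nrow(x$merge),
    min_height = min(x$height),
    max_height = max(x$height)
  )
}

#' Dendrogram of a sample clustering
#'
#' @param object a `sample_clustering`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sample_clustering
#' @export
autoplot.sample_clustering <- function(object, ...) {
  ord <- leaf_order(object$merge)
  xpos <- numeric(length(object$labels))
  xpos[ord] <- seq_along(ord)
  node_x <- numeric(nrow(object$merge))
  node_pos <- function(id) if (id < 0) xpos[-id] else node_x[id]
  node_h <- function(id) if (id < 0) 0 else object$height[id]
  segs <- list()
  for (m in seq_len(nrow(object$merge))) {
    a <- object$merge[m, 1]
    b <- object$merge[m, 2]
    xa <- node_pos(a); xb <- node_pos(b)
    node_x[m] <- (xa + xb) / 2
    h <- object$height[m]
    segs[[m]] <- tibble::tibble(
      x = c(xa, xa, xb), xend = c(xa, xb, xb),
      y = c(node_h(a), h, h), yend = c(h, h, node_h(b))
    )
  }
  segs <- dplyr::bind_rows(segs)
  leaves <- tibble::tibble(x = xpos, label = object$labels)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaves$x, labels = leaves$label) +
    ggplot2::labs(x = NULL, y = "1 - Pearson correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Heatmap of a sample similarity matrix
#'
#' @param similarity matrix from [sample_similarity()].
#' @param order reorder samples by the complete-linkage dendrogram
#'   (default `TRUE`).
#' @return a ggplot object.
#' @export
plot_sample_similarity <- function(similarity, order = TRUE) {
  labs <- colnames(similarity)
  if (order) {
    cl <- cluster_samples(similarity)
    labs <- cl$labels[leaf_order(cl$merge)]
  }
  df <- tibble::as_tibble(as.data.frame.table(similarity,
                                              stringsAsFactors = FALSE))
  names(df) <- c("sample_a", "sample_b", "similarity")
  df$sample_a <- factor(df$sample_a, levels = labs)
  df$sample_b <- factor(df$sample_b, levels = labs)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(df$similarity), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
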