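#' Intersubject amplitude-covariation matrix
#'
#' Pearson correlation across subjects between every pair of network columns
#' of a measure table; the matrix whose hierarchical structure separates
#' networks into covarying groups.
#'
#' @param measure S x K measure table (subjects x networks).
#' @return K x K correlation matrix.
#' @export
amplitude_covariation <- function(measure) {
  measure <- as_matrix_numeric(measure, "measure")
  if (nrow(measure) < 3L) stop("need at least 3 subjects")
  sds <- apply(measure, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(measure)[sds == 0] %||% which(sds == 0)
    stop(sprintf("constant network column(s): %s", paste(bad, collapse = ", ")))
  }
  stats::cor(measure)
}

#' Ward clustering of the covariation matrix
#'
#' Agglomerative Ward linkage on the rows of the covariation matrix treated
#' as feature vectors. The default dissimilarity is the Euclidean distance
#' between rows (the standard Ward contract); \code{dissimilarity = "one_minus_r"}
#' uses 1 - r directly instead.
#'
#' @param covariation K x K correlation matrix from
#'   \code{\link{amplitude_covariation}}.
#' @param n_clusters number of clusters at the reported cut (default 2:
#'   a sensory-like and a cognitive-like group).
#' @param dissimilarity \code{"euclidean_rows"} (default) or
#'   \code{"one_minus_r"}.
#' @return object of class \code{"rsn_clusters"}: list with \code{hclust}
#'   (the merge tree), \code{assignment} (named integer vector), \code{order}
#'   (dendrogram leaf order), \code{covariation}, \code{n_clusters}.
#' @export
ward_cluster <- function(covariation, n_clusters = 2L,
                         dissimilarity = c("euclidean_rows", "one_minus_r")) {
  dissimilarity <- match.arg(dissimilarity)
  covariation <- as_matrix_numeric(covariation, "covariation")
  K <- nrow(covariation)
  if (n_clusters < 1L || n_clusters > K) stop("n_clusters must lie in 1..K")
  d <- switch(dissimilarity,
              euclidean_rows = stats::dist(covariation),
              one_minus_r = stats::as.dist(1 - covariation))
  hc <- stats::hclust(d, method = "ward.D2")
  assignment <- stats::cutree(hc, k = n_clusters)
  names(assignment) <- rownames(covariation) %||% sprintf("net%02d", seq_len(K))
  structure(list(hclust = hc, assignment = assignment, order = hc$order,
                 covariation = covariation, n_clusters = n_clusters,
                 dissimilarity = dissimilarity),
            class = "rsn_clusters")
}

#' @export
print.rsn_clusters <- function(x, ...) {
  cat(sprintf("Ward clustering of %d networks into %d clusters (%s dissimilarity)\n",
              length(x$assignment), x$n_clusters, x$dissimilarity))
  for (cl in sort(unique(x$assignment))) {
    cat(sprintf("  cluster %d: %s\n", cl,
                paste(names(x$assignment)[x$assignment == cl], collapse = ", ")))
  }
  invisible(x)
}

#' Per-subject cluster-mean amplitudes
#'
#' The unweighted mean of the member networks' values per cluster, per
#' subject (e.g. the "sensory amplitude" and "cognitive amplitude" of a
#' two-cluster solution).
#'
#' @param measure S x K measure table.
#' @param clusters a \code{\link{ward_cluster}} result, or an integer
#'   assignment vector of length K.
#' @return S x n_clusters matrix.
#' @export
cluster_amplitude <- function(measure, clusters) {
  measure <- as_matrix_numeric(measure, "measure")
  assignment <- if (inherits(clusters, "rsn_clusters")) clusters$assignment else clusters
  if (length(assignment) != ncol(measure))
    stop("assignment must cover all network columns")
  ids <- sort(unique(assignment))
  out <- vapply(ids, function(cl) {
    cols <- which(assignment == cl)
    if (!length(cols)) stop(sprintf("empty cluster %d", cl))
    rowMeans(measure[, cols, drop = FALSE])
  }, numeric(nrow(measure)))
  colnames(out) <- sprintf("cluster%d", ids)
  rownames(out) <- rownames(measure)
  out
}

#' Export a linkage as a four-column merge table
#'
#' Rows are merges: the two children (negative = leaf index, positive = prior
#' merge), the merge height, and the size of the merged cluster.
#'
#' @param clusters an \code{rsn_clusters} result.
#' @return data.frame(child1, child2, height, size).
#' @export
linkage_table <- function(clusters) {
  hc <- clusters$hclust
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    s <- 0L
    for (ch in hc$merge[i, ]) s <- s + if (ch < 0) 1L else sizes[ch]
    sizes[i] <- s
  }
  data.frame(child1 = hc$merge[, 1], child2 = hc$merge[, 2],
             height = hc$height, size = sizes)
}
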