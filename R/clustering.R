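#' Hierarchical clustering of samples on a beta submatrix
#'
#' Agglomerative clustering of samples (columns), by default Euclidean
#' distance with average linkage. Probes with any masked value are dropped
#' first. Ties are broken deterministically by the input sample order.
#'
#' @param betas probes x samples beta matrix (typically restricted to a
#'   probe set of interest, e.g. the DMC panel).
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson).
#' @param linkage linkage method passed to [stats::hclust()].
#' @return an object of class `hclust`.
#' @export
hier_cluster <- function(betas, metric = c("euclidean", "correlation"),
                         linkage = "average") {
  metric <- match.arg(metric)
  if (ncol(betas) < 2) stop("hier_cluster: need >= 2 samples", call. = FALSE)
  keep <- rowSums(is.na(betas)) == 0
  b <- betas[keep, , drop = FALSE]
  d <- if (metric == "euclidean") stats::dist(t(b))
  else stats::as.dist(1 - stats::cor(b))
  stats::hclust(d, method = linkage)
}

#' Majority-label purity of a dendrogram cut
#'
#' Cuts the tree into `k` clusters and scores the fraction of samples whose
#' label matches their cluster's majority label. 1.0 means the cut separates
#' the label groups perfectly; purity is non-decreasing in `k`.
#'
#' @param dendrogram an `hclust` object over samples.
#' @param k number of clusters.
#' @param labels vector of sample labels in the tree's leaf (input) order.
#' @return purity in `[0, 1]`.
#' @export
cluster_purity <- function(dendrogram, k, labels) {
  n <- length(dendrogram$order)
  if (k > n) stop("cluster_purity: k exceeds sample count", call. = FALSE)
  stopifnot(length(labels) == n)
  cl <- stats::cutree(dendrogram, k = k)
  sum(vapply(split(labels, cl), function(l) max(table(l)), numeric(1))) / n
}

#' Classical multidimensional scaling of samples
#'
#' Double-centered Gram eigendecomposition (via [stats::cmdscale()]) of a
#' sample-sample distance matrix, default 1 - Pearson correlation of beta
#' profiles. The sign of each axis is fixed so its largest-magnitude loading
#' is positive, making coordinates reproducible.
#'
#' @param betas probes x samples beta matrix.
#' @param k embedding dimension.
#' @param metric `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @return samples x k coordinate matrix.
#' @export
classical_mds <- function(betas, k = 2, metric = c("correlation",
                                                   "euclidean")) {
  metric <- match.arg(metric)
  if (ncol(betas) < 3) stop("classical_mds: need >= 3 samples", call. = FALSE)
  keep <- rowSums(is.na(betas)) == 0
  b <- betas[keep, , drop = FALSE]
  d <- if (metric == "euclidean") stats::dist(t(b))
  else stats::as.dist(1 - stats::cor(b))
  if (any(!is.finite(as.matrix(d))))
    stop("classical_mds: non-finite distances", call. = FALSE)
  xy <- stats::cmdscale(d, k = k)
  for (j in seq_len(ncol(xy))) {
    i <- which.max(abs(xy[, j]))
    if (xy[i, j] < 0) xy[, j] <- -xy[, j]
  }
  colnames(xy) <- paste0("MDS", seq_len(ncol(xy)))
  xy
}
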