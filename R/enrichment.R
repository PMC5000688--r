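#' Hypergeometric gene-set over-representation
#'
#' For every term, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap `k` between the query and the term's members
#' when `n` genes are sampled from a universe of `N` containing `K` term
#' members: `P(X >= k)`. A transparent replacement for network-based
#' enrichment services. Terms are significant when `p < p_threshold` and the
#' overlap reaches `min_overlap`.
#'
#' @param genes query gene set (character).
#' @param sets named list of member vectors (e.g. from [read_gmt()]).
#' @param universe background gene universe; query genes outside it are
#'   dropped with a warning.
#' @param p_threshold significance threshold on the raw hypergeometric p.
#' @param min_overlap minimum overlap for significance.
#' @return data.frame term, overlap, set_size, query_size, universe_size,
#'   p_value, significant; sorted by p.
#' @export
enrich <- function(genes, sets, universe, p_threshold = 1e-3,
                   min_overlap = 2) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop("enrich: empty universe", call. = FALSE)
  genes <- unique(toupper(genes))
  outside <- setdiff(genes, universe)
  if (length(outside) > 0) {
    warning("enrich: query genes outside universe dropped: ",
            paste(utils::head(outside, 10), collapse = ", "))
    genes <- intersect(genes, universe)
  }
  N <- length(universe)
  n <- length(genes)
  res <- do.call(rbind, lapply(names(sets), function(term) {
    members <- intersect(unique(toupper(sets[[term]])), universe)
    K <- length(members)
    k <- length(intersect(genes, members))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = k, set_size = K, query_size = n,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  }))
  res$significant <- res$p_value < p_threshold & res$overlap >= min_overlap
  res[order(res$p_value, res$term), , drop = FALSE]
}
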