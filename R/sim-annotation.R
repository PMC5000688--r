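#' Simulate a compact genome annotation (gene models and CpG islands)
#'
#' Lays out `n_genes` gene models along a single synthetic chromosome and
#' places CpG-island intervals: one spanning the TSS for a fraction of genes
#' (promoter islands, the compartment where colitis-associated
#' hypermethylation concentrates) and additional intergenic islands. All
#' intervals use 0-based half-open coordinates; the TSS is a 0-based position.
#'
#' @param n_genes number of gene models.
#' @param seq_id chromosome name.
#' @param gene_spacing average distance between consecutive TSSs (bp).
#' @param frac_promoter_island fraction of genes whose promoter overlaps an
#'   island.
#' @param seed integer seed.
#' @return list with `gene_models` (data.frame: gene, seq_id, strand, tss,
#'   exons as `"start-end,start-end"` 0-based half-open) and `islands`
#'   (data.frame: seq_id, start, end, gc_fraction, obs_exp).
#' @export
simulate_annotation <- function(n_genes = 120, seq_id = "chr1",
                                gene_spacing = 20000,
                                frac_promoter_island = 0.6, seed) {
  if (missing(seed)) stop("simulate_annotation: 'seed' is required", call. = FALSE)
  if (n_genes < 1) stop("simulate_annotation: need at least one gene", call. = FALSE)
  set.seed(as.integer(seed))
  tss <- as.integer(round((seq_len(n_genes) - 0.5) * gene_spacing +
                            stats::runif(n_genes, -0.15, 0.15) * gene_spacing))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  gene <- sprintf("GENE%04d", seq_len(n_genes))
  exons <- character(n_genes)
  for (i in seq_len(n_genes)) {
    n_ex <- sample(3:6, 1)
    body_len <- round(stats::runif(1, 5000, 12000))
    # exon grid within the gene body, transcribed downstream of the TSS
    cuts <- sort(sample(seq(200L, body_len - 200L, by = 50L), 2L * n_ex - 1L))
    bounds <- c(0L, cuts, body_len)
    starts_rel <- bounds[seq(1L, 2L * n_ex, by = 2L)]
    ends_rel <- bounds[seq(2L, 2L * n_ex + 1L, by = 2L)]
    if (strand[i] == "+") {
      s <- tss[i] + starts_rel; e <- tss[i] + ends_rel
    } else {
      s <- tss[i] - ends_rel + 1L; e <- tss[i] - starts_rel + 1L
      o <- order(s); s <- s[o]; e <- e[o]
    }
    exons[i] <- paste(sprintf("%d-%d", pmax(s, 0L), e), collapse = ",")
  }
  gene_models <- data.frame(gene = gene, seq_id = seq_id, strand = strand,
                            tss = tss, exons = exons,
                            stringsAsFactors = FALSE)

  # promoter islands straddle the TSS; intergenic islands sit mid-spacing
  prom_idx <- sort(sample(n_genes, round(frac_promoter_island * n_genes)))
  prom_len <- round(stats::runif(length(prom_idx), 800, 1500))
  prom_start <- pmax(tss[prom_idx] - round(0.4 * prom_len), 0L)
  n_inter <- max(1L, round(n_genes / 3))
  inter_mid <- as.integer(round(stats::runif(n_inter, 0.3, 0.45) * gene_spacing +
                                  sample(tss, n_inter) ))
  inter_len <- round(stats::runif(n_inter, 300, 900))
  islands <- data.frame(
    seq_id = seq_id,
    start = as.integer(c(prom_start, inter_mid)),
    end = as.integer(c(prom_start + prom_len, inter_mid + inter_len)),
    gc_fraction = round(stats::runif(length(prom_idx) + n_inter, 0.55, 0.75), 3),
    obs_exp = round(stats::runif(length(prom_idx) + n_inter, 0.65, 1.2), 3),
    stringsAsFactors = FALSE)
  islands <- islands[order(islands$start), , drop = FALSE]
  # drop overlaps so the island set is disjoint (keep the earlier interval)
  keep <- rep(TRUE, nrow(islands))
  last_end <- -1L
  for (i in seq_len(nrow(islands))) {
    if (islands$start[i] < last_end) keep[i] <- FALSE
    else last_end <- islands$end[i]
  }
  islands <- islands[keep, , drop = FALSE]
  rownames(islands) <- NULL
  list(gene_models = gene_models, islands = islands)
}

# Parse "start-end,start-end" exon encoding into a 2-column integer matrix.
parse_exons <- function(txt) {
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  m <- vapply(strsplit(parts, "-", fixed = TRUE),
              function(p) as.integer(p), integer(2))
  t(m)
}
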