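#' Simulate a bisulfite-sequencing clone matrix
#'
#' Binary clones x CpG matrix with i.i.d. Bernoulli entries: 1 marks a
#' methylated cytosine (a filled box in a lollipop plot).
#'
#' @param n_clones,n_cpgs matrix dimensions.
#' @param p_meth per-CpG methylation probability in `[0,1]`.
#' @param seed integer seed.
#' @return integer matrix of 0/1 with clone/CpG dimnames.
#' @export
simulate_clone_matrix <- function(n_clones, n_cpgs, p_meth, seed) {
  if (n_clones < 1 || n_cpgs < 1)
    stop("simulate_clone_matrix: need at least one clone and one CpG",
         call. = FALSE)
  if (p_meth < 0 || p_meth > 1)
    stop("simulate_clone_matrix: p_meth must lie in [0,1]", call. = FALSE)
  set.seed(as.integer(seed))
  m <- matrix(as.integer(stats::runif(n_clones * n_cpgs) < p_meth),
              n_clones, n_cpgs,
              dimnames = list(sprintf("clone%02d", seq_len(n_clones)),
                              sprintf("CpG%02d", seq_len(n_cpgs))))
  m
}

#' Simulate a qPCR cycle-threshold table
#'
#' Ct values follow the standard exponential-amplification model:
#' `Ct = ct_ref - log2(quantity) + N(0, noise_sd)`, so doubling the template
#' lowers Ct by exactly one cycle.
#'
#' @param samples sample sheet (data.frame with `sample_id`, `group`).
#' @param targets character vector of assay names (genes and normalizers).
#' @param true_rel_quantity matrix or data.frame samples x targets of positive
#'   relative quantities.
#' @param ct_ref baseline cycle number for quantity 1.
#' @param noise_sd technical noise (cycles).
#' @param seed integer seed.
#' @param n_replicates technical replicates per sample x target.
#' @return data.frame: sample_id, group, target, replicate, ct.
#' @export
simulate_ct_table <- function(samples, targets, true_rel_quantity,
                              ct_ref = 25, noise_sd = 0.1, seed,
                              n_replicates = 1) {
  q <- as.matrix(true_rel_quantity)
  if (any(!is.finite(q)) || any(q <= 0))
    stop("simulate_ct_table: quantities must be positive", call. = FALSE)
  stopifnot(nrow(q) == nrow(samples), ncol(q) == length(targets))
  set.seed(as.integer(seed))
  grid <- expand.grid(rep = seq_len(n_replicates),
                      target = seq_along(targets),
                      sample = seq_len(nrow(samples)))
  ct <- ct_ref - log2(q[cbind(grid$sample, grid$target)]) +
    stats::rnorm(nrow(grid), 0, noise_sd)
  data.frame(sample_id = samples$sample_id[grid$sample],
             group = samples$group[grid$sample],
             target = targets[grid$target],
             replicate = grid$rep,
             ct = ct,
             stringsAsFactors = FALSE)
}

#' Generate promoter-like FASTA sequences with embedded CpG islands
#'
#' Each sequence is an AT-rich, CpG-free background (bulk vertebrate genome is
#' CpG-depleted) with one embedded island segment engineered to meet the
#' configured length / GC / observed-expected CpG targets; the island starts
#' and ends on a CpG dinucleotide, as real islands delimited by island-search
#' tools do. The embedded coordinates are returned as ground truth for the
#' island caller.
#'
#' @param n_sequences number of sequences.
#' @param island_len embedded island length (>= 200 bp).
#' @param gc target GC fraction of the island.
#' @param obs_exp minimum observed/expected CpG ratio of the island.
#' @param flank_len length of each AT-rich flank.
#' @param flank_gc GC fraction of the flanks (kept well below island calling
#'   thresholds).
#' @param seed integer seed.
#' @return list with `sequences` (named character vector) and `islands`
#'   (data.frame: seq_id, start, end; 0-based half-open truth coordinates).
#' @export
generate_promoter_fasta <- function(n_sequences, island_len = 300, gc = 0.65,
                                    obs_exp = 0.8, flank_len = 400,
                                    flank_gc = 0.25, seed) {
  if (n_sequences == 0)
    return(list(sequences = setNames(character(0), character(0)),
                islands = data.frame(seq_id = character(0), start = integer(0),
                                     end = integer(0))))
  if (island_len < 200)
    stop("generate_promoter_fasta: island length must be >= 200", call. = FALSE)
  if (gc <= 0 || gc > 1 || obs_exp <= 0)
    stop("generate_promoter_fasta: invalid GC/obs-exp targets", call. = FALSE)
  # feasibility: need ~obs_exp * (gc/2)^2 * len CpG starts among gc*len G+C
  n_gc <- round(gc * island_len)
  n_cpg_needed <- ceiling(obs_exp * (n_gc / 2) * (n_gc / 2) / island_len) + 1L
  if (2L * n_cpg_needed > n_gc)
    stop("generate_promoter_fasta: unachievable GC/obs-exp combination",
         call. = FALSE)
  set.seed(as.integer(seed))
  seqs <- character(n_sequences)
  truth <- vector("list", n_sequences)
  for (i in seq_len(n_sequences)) {
    fl <- round(flank_len * stats::runif(1, 0.6, 1.4))
    fr <- round(flank_len * stats::runif(1, 0.6, 1.4))
    left <- random_seq(fl, flank_gc)
    right <- random_seq(fr, flank_gc)
    isl <- island_seq(island_len, n_gc, n_cpg_needed)
    seqs[i] <- paste0(left, isl, right)
    truth[[i]] <- data.frame(seq_id = sprintf("seq%04d", i),
                             start = fl, end = fl + island_len)
  }
  names(seqs) <- sprintf("seq%04d", seq_len(n_sequences))
  list(sequences = seqs, islands = do.call(rbind, truth))
}

# Random sequence with a given GC fraction (iid draws). With cpg_free, any
# C directly followed by G is broken by swapping the G to A, mimicking the
# CpG depletion of bulk genomic background.
random_seq <- function(len, gc, cpg_free = TRUE) {
  if (len == 0) return("")
  v <- sample(c("A", "T", "C", "G"), len, replace = TRUE,
              prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  if (cpg_free && len > 1) {
    repeat {
      hit <- which(v[-len] == "C" & v[-1] == "G")
      if (length(hit) == 0) break
      v[hit + 1L] <- "A"
    }
  }
  paste(v, collapse = "")
}

# Island segment: place CpG dinucleotides to hit the observed/expected
# target (first and last dinucleotide slots are always CpG so the island is
# CpG-delimited), distribute remaining G/C singletons, fill with A/T.
island_seq <- function(len, n_gc, n_cpg) {
  slots <- len %/% 2L
  cpg_slots <- sort(unique(c(1L, slots,
                             sample(2:(slots - 1L), max(n_cpg - 2L, 0L)))))
  chars <- rep(NA_character_, len)
  chars[2L * cpg_slots - 1L] <- "C"
  chars[2L * cpg_slots] <- "G"
  free <- which(is.na(chars))
  n_extra <- n_gc - 2L * length(cpg_slots)
  if (n_extra > 0) {
    pick <- sample(free, n_extra)
    chars[pick] <- sample(c("C", "G"), n_extra, replace = TRUE)
    free <- setdiff(free, pick)
  }
  if (length(free) > 0)
    chars[free] <- sample(c("A", "T"), length(free), replace = TRUE)
  paste(chars, collapse = "")
}
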