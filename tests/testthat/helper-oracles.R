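# Independent oracles used across the suite. Implementations are kept naive
# and textbook-style on purpose: string counting instead of prefix sums,
# explicit formulas instead of stats:: test functions, enumeration instead of
# closed forms.

# Pooled-variance two-sample t-test from the textbook formula.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Upper-tail hypergeometric probability by explicit enumeration.
hyper_tail_oracle <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Naive string-based CpG-island finder mirroring the documented caller
# semantics: qualifying min_len windows, merge, CpG snap, longest-qualifying
# fallback. Counting is done on substrings with gsub, not prefix sums.
oracle_islands <- function(s, min_len = 200, gc_min = 0.5, oe_min = 0.6) {
  s <- toupper(s)
  L <- nchar(s)
  none <- data.frame(start = integer(0), end = integer(0))
  if (L < min_len) return(none)
  count <- function(txt, pat) nchar(txt) - nchar(gsub(pat, "", txt, fixed = TRUE))
  win_stats <- function(st, en) {
    sub <- substring(s, st + 1, en)
    len <- en - st
    nC <- count(sub, "C"); nG <- count(sub, "G"); nN <- count(sub, "N")
    ncpg <- count(sub, "CG") / 2
    gc <- (nC + nG) / len
    oe <- ifelse(nC > 0 & nG > 0, ncpg * len / (nC * nG), 0)
    list(ok = nN == 0 & gc > gc_min & oe > oe_min, gc = gc, oe = oe)
  }
  st_all <- 0:(L - min_len)
  ok <- win_stats(st_all, st_all + min_len)$ok
  if (!any(ok)) return(none)
  qs <- st_all[ok]; qe <- qs + min_len
  brk <- which(qs[-1] > qe[-length(qe)])
  rs <- qs[c(1, brk + 1)]; re <- qe[c(brk, length(qe))]
  out <- vector("list", length(rs))
  for (r in seq_along(rs)) {
    reg <- substring(s, rs[r] + 1, re[r])
    cpg <- gregexpr("CG", reg, fixed = TRUE)[[1]]
    emit <- NULL
    if (cpg[1] != -1) {
      ss <- rs[r] + cpg[1] - 1
      se <- rs[r] + cpg[length(cpg)] + 1
      if (se - ss >= min_len) {
        w <- win_stats(ss, se)
        if (w$ok) emit <- data.frame(start = ss, end = se)
      }
    }
    if (is.null(emit)) {
      for (len in seq(re[r] - rs[r], min_len)) {
        starts <- rs[r]:(re[r] - len)
        okl <- win_stats(starts, starts + len)$ok
        if (any(okl)) {
          i <- which(okl)[1]
          emit <- data.frame(start = starts[i], end = starts[i] + len)
          break
        }
      }
    }
    out[[r]] <- emit
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# Varied island-caller test corpus: CpG-depleted AT-rich backgrounds with
# 0-2 embedded islands per sequence, plus occasional island-free sequences.
island_corpus <- function(n, seed) {
  set.seed(seed)
  specs <- data.frame(
    island_len = sample(c(200, 220, 250, 300, 400, 500), n, replace = TRUE),
    gc = runif(n, 0.55, 0.75),
    flank_len = sample(150:700, n, replace = TRUE),
    flank_gc = runif(n, 0.05, 0.35),
    with_island = runif(n) > 0.15,
    two = runif(n) < 0.25)
  lapply(seq_len(n), function(i) {
    sp <- specs[i, ]
    if (!sp$with_island)
      return(ucmeth:::random_seq(sample(250:1800, 1), sp$flank_gc))
    g <- generate_promoter_fasta(if (sp$two) 2 else 1,
                                 island_len = sp$island_len, gc = sp$gc,
                                 obs_exp = 0.7, flank_len = sp$flank_len,
                                 flank_gc = sp$flank_gc, seed = seed + i)
    paste(g$sequences, collapse = "")
  })
}

jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  inter / (max(e1, e2) - min(s1, s2))
}
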