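#' Call CpG islands in a DNA sequence
#'
#' Scans `min_len`-bp windows for CpG-island character: GC fraction strictly
#' above `gc_min` and observed/expected CpG ratio strictly above
#' `obs_exp_min`, where `obs/exp = (#CpG * len) / (#C * #G)`. Qualifying
#' windows that overlap or touch are merged, and each merged region is trimmed
#' to its maximal qualifying extent: the region is first snapped inward so it
#' starts and ends on a CpG dinucleotide (island boundaries are CpG-delimited,
#' as in classical island-search tools); if the snapped interval itself
#' satisfies all three criteria it is emitted, otherwise the longest
#' qualifying sub-interval of the merged region (leftmost on ties) is emitted.
#' Windows containing `N` are disqualified. Coordinates are 0-based half-open.
#'
#' The default thresholds (200 bp, GC > 50\%, obs/exp > 0.6) follow the
#' classical sequence-based island definition used by standard island-search
#' tools.
#'
#' @param sequence a single DNA string over `A,C,G,T,N` (case-insensitive).
#' @param min_len minimum island length (bp).
#' @param gc_min GC-fraction threshold (exclusive).
#' @param obs_exp_min observed/expected CpG threshold (exclusive).
#' @return data.frame with columns `start`, `end`, `length`, `gc_fraction`,
#'   `obs_exp`, sorted by `start`; zero rows if none found.
#' @export
find_cpg_islands <- function(sequence, min_len = 200, gc_min = 0.50,
                             obs_exp_min = 0.60) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  s <- toupper(sequence)
  L <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_fraction = numeric(0),
                      obs_exp = numeric(0))
  if (L < min_len) return(empty)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!all(v %in% c("A", "C", "G", "T", "N")))
    stop("find_cpg_islands: sequence contains characters outside A,C,G,T,N",
         call. = FALSE)
  isC <- v == "C"; isG <- v == "G"; isN <- v == "N"
  # cumulative counts; cpg[i] counts CpG dinucleotides starting before i
  cC <- cumsum(isC); cG <- cumsum(isG); cN <- cumsum(isN)
  cpg_at <- c(isC[-L] & isG[-1], FALSE)
  cCpG <- cumsum(cpg_at)

  stats_of <- function(st, en) {
    # st, en 0-based half-open
    len <- en - st
    nN <- cN[en] - if (st > 0) cN[st] else 0
    nc <- cC[en] - if (st > 0) cC[st] else 0
    ng <- cG[en] - if (st > 0) cG[st] else 0
    ncpg <- (if (en > 1) cCpG[en - 1] else 0) - if (st > 0) cCpG[st] else 0
    gc <- (nc + ng) / len
    oe <- if (nc > 0 && ng > 0) ncpg * len / (nc * ng) else 0
    c(ok = nN == 0 && gc > gc_min && oe > obs_exp_min, gc = gc, oe = oe)
  }

  # vectorized window scan
  starts <- 0:(L - min_len)
  ends <- starts + min_len
  wc <- cC[ends] - c(0, cC)[starts + 1L]
  wg <- cG[ends] - c(0, cG)[starts + 1L]
  wn <- cN[ends] - c(0, cN)[starts + 1L]
  wcpg <- cCpG[ends - 1L] - c(0, cCpG)[starts + 1L]
  gc_ok <- (wc + wg) / min_len > gc_min
  oe <- ifelse(wc > 0 & wg > 0, wcpg * min_len / (wc * wg), 0)
  ok <- gc_ok & oe > obs_exp_min & wn == 0
  if (!any(ok)) return(empty)

  # merge overlapping/adjacent qualifying windows
  qs <- starts[ok]
  qe <- ends[ok]
  brk <- which(qs[-1] > qe[-length(qe)])
  reg_start <- qs[c(1L, brk + 1L)]
  reg_end <- qe[c(brk, length(qe))]

  cpg_pos <- which(cpg_at) - 1L  # 0-based CpG start positions
  out <- vector("list", length(reg_start))
  for (r in seq_along(reg_start)) {
    rs <- reg_start[r]; re <- reg_end[r]
    # snap to terminal CpGs (a qualifying window guarantees one exists)
    inreg <- cpg_pos[cpg_pos >= rs & cpg_pos + 2L <= re]
    emit <- NULL
    if (length(inreg) > 0) {
      ss <- inreg[1]; se <- inreg[length(inreg)] + 2L
      if (se - ss >= min_len) {
        q <- stats_of(ss, se)
        if (q[["ok"]] == 1)
          emit <- data.frame(start = ss, end = se, length = se - ss,
                             gc_fraction = q[["gc"]], obs_exp = q[["oe"]])
      }
    }
    if (is.null(emit))
      emit <- longest_qualifying(rs, re, min_len, cC, cG, cN, cCpG,
                                 gc_min, obs_exp_min)
    out[[r]] <- emit
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Longest qualifying sub-interval of [rs, re); leftmost on ties. The region
# always contains at least one qualifying window, so a result exists.
# Vectorized over starts for each candidate length, longest first.
longest_qualifying <- function(rs, re, min_len, cC, cG, cN, cCpG,
                               gc_min, obs_exp_min) {
  p <- function(cum, i) ifelse(i > 0, cum[pmax(i, 1L)], 0)
  for (len in seq(re - rs, min_len)) {
    st <- rs:(re - len)
    en <- st + len
    nN <- p(cN, en) - p(cN, st)
    nc <- p(cC, en) - p(cC, st)
    ng <- p(cG, en) - p(cG, st)
    ncpg <- p(cCpG, en - 1L) - p(cCpG, st)
    gc <- (nc + ng) / len
    oe <- ifelse(nc > 0 & ng > 0, ncpg * len / (nc * ng), 0)
    ok <- nN == 0 & gc > gc_min & oe > obs_exp_min
    if (any(ok)) {
      i <- which(ok)[1]
      return(data.frame(start = st[i], end = en[i], length = len,
                        gc_fraction = gc[i], obs_exp = oe[i]))
    }
  }
  stop("internal error: merged region lost its qualifying window")  # nocov
}

#' Classify a probe position relative to CpG islands
#'
#' Standard island-neighborhood vocabulary: `island` inside an island,
#' `shore` within `shore` bp of an island edge, `shelf` within the next
#' `shelf` bp, otherwise `open_sea`.
#'
#' @param position 1-based probe coordinate.
#' @param islands data.frame with 0-based half-open `start`,`end` on the same
#'   sequence, sorted by start.
#' @param shore,shelf widths (bp) of the shore and shelf bands.
#' @return one of `"island"`, `"shore"`, `"shelf"`, `"open_sea"`.
#' @export
island_relation <- function(position, islands, shore = 2000, shelf = 2000) {
  p0 <- position - 1L  # 0-based
  if (nrow(islands) == 0L) return("open_sea")
  inside <- p0 >= islands$start & p0 < islands$end
  if (any(inside)) return("island")
  # distance to nearest island edge (bases beyond the terminal island base)
  d <- pmin(abs(p0 - islands$start), abs(p0 - (islands$end - 1L)))
  dmin <- min(d)
  if (dmin <= shore) "shore"
  else if (dmin <= shore + shelf) "shelf"
  else "open_sea"
}

#' Assign a genomic feature class to a probe position
#'
#' Precedence promoter > exon > intron > intergenic. The promoter window is
#' `[tss - promoter_up, tss + promoter_down]` on the plus strand and mirrored
#' on the minus strand.
#'
#' @param position 1-based probe coordinate.
#' @param gene_models data.frame as from [simulate_annotation()].
#' @param promoter_up,promoter_down promoter window extent upstream/downstream
#'   of the TSS (bp).
#' @return one of `"promoter"`, `"exon"`, `"intron"`, `"intergenic"`.
#' @export
assign_feature <- function(position, gene_models, promoter_up = 1500,
                           promoter_down = 500) {
  if (nrow(gene_models) == 0L) stop("no annotation", call. = FALSE)
  p0 <- position - 1L
  up <- ifelse(gene_models$strand == "+",
               gene_models$tss - promoter_up, gene_models$tss - promoter_down)
  dn <- ifelse(gene_models$strand == "+",
               gene_models$tss + promoter_down, gene_models$tss + promoter_up)
  if (any(p0 >= up & p0 <= dn)) return("promoter")
  hit_exon <- FALSE; hit_intron <- FALSE
  for (i in seq_len(nrow(gene_models))) {
    ex <- parse_exons(gene_models$exons[i])
    if (p0 < min(ex[, 1]) || p0 >= max(ex[, 2])) next
    if (any(p0 >= ex[, 1] & p0 < ex[, 2])) hit_exon <- TRUE else hit_intron <- TRUE
    if (hit_exon) break
  }
  if (hit_exon) "exon" else if (hit_intron) "intron" else "intergenic"
}

# Nearest gene symbol for a 1-based position (by distance to TSS).
nearest_gene <- function(position, gene_models) {
  gene_models$gene[which.min(abs((position - 1L) - gene_models$tss))]
}

#' Cross-tabulate probe annotation categories
#'
#' @param probes data.frame with `feature` and `island_relation` columns.
#' @return a feature x island_relation contingency table whose counts sum to
#'   `nrow(probes)`.
#' @export
feature_distribution <- function(probes) {
  stopifnot(all(c("feature", "island_relation") %in% names(probes)))
  table(feature = factor(probes$feature,
                         levels = c("promoter", "5'UTR", "exon", "intron",
                                    "3'UTR", "intergenic")),
        island_relation = factor(probes$island_relation,
                                 levels = c("island", "shore", "shelf",
                                            "open_sea")))
}

#' Select promoter CpG-island probes among hypermethylation survivors
#'
#' The final funnel stage: restrict fold-filtered hypermethylated probes to
#' those annotated as promoter-resident and island-resident.
#'
#' @param survivors character vector of probe ids (fold-filtered hyper set).
#' @param manifest annotated manifest data.frame.
#' @return character vector of probe ids (subset of `survivors`).
#' @export
select_promoter_island_probes <- function(survivors, manifest) {
  keep <- manifest$probe_id %in% survivors &
    manifest$feature == "promoter" & manifest$island_relation == "island"
  manifest$probe_id[keep]
}
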