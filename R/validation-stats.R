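#' Methylation-specific PCR call frequencies
#'
#' Per gene and group: number methylated, total, and percent methylated
#' (one decimal).
#'
#' @param table MSP call data.frame: sample_id, group, gene, call in
#'   {methylated, unmethylated}.
#' @return data.frame gene, group, n_meth, n_total, percent.
#' @export
msp_frequency <- function(table) {
  if (nrow(table) == 0) stop("msp_frequency: empty table", call. = FALSE)
  check_vocab(table$call, c("methylated", "unmethylated"), "call")
  if (anyDuplicated(table[, c("sample_id", "gene")]))
    stop("msp_frequency: duplicate (sample, gene) calls", call. = FALSE)
  agg <- stats::aggregate(call ~ gene + group, data = table,
                          FUN = function(x) c(n_meth = sum(x == "methylated"),
                                              n_total = length(x)))
  out <- data.frame(gene = agg$gene, group = agg$group,
                    n_meth = agg$call[, "n_meth"],
                    n_total = agg$call[, "n_total"],
                    stringsAsFactors = FALSE)
  out$percent <- round(100 * out$n_meth / out$n_total, 1)
  out[order(out$gene, out$group), , drop = FALSE]
}

#' Summarize a bisulfite clone matrix
#'
#' Per-CpG methylated fractions, the overall density, and a text lollipop
#' grid (`*` methylated, `o` unmethylated) matching the clone matrix.
#'
#' @param m binary clones x CpG matrix.
#' @return list with `per_cpg`, `density`, `grid` (character vector, one
#'   row per clone).
#' @export
clone_summary <- function(m) {
  if (length(m) == 0) stop("clone_summary: empty matrix", call. = FALSE)
  grid <- apply(m, 1, function(r) paste(ifelse(r == 1, "*", "o"),
                                        collapse = ""))
  list(per_cpg = colMeans(m), density = mean(m), grid = unname(grid))
}

# Mean Ct per sample x target with replicates averaged.
mean_ct <- function(ct, target) {
  sub <- ct[ct$target == target, , drop = FALSE]
  tapply(sub$ct, sub$sample_id, mean)
}

#' Relative methylation level by quantitative MSP
#'
#' Replicate Cts are averaged; `dCt = Ct_target - Ct_normalizer` per sample;
#' `level = 2^-(dCt_sample - dCt_calibrator)`, so the calibrator (typically
#' in-vitro methylated DNA) sits at level 1. Samples missing the normalizer
#' are skipped with a warning; no-template (H2O) rows are never quantified.
#'
#' @param ct Ct table (sample_id, target, replicate, ct).
#' @param target gene assay name.
#' @param normalizer repeat-element normalizer assay (default `"Alu"`).
#' @param calibrator sample id of the fully-methylated calibrator.
#' @param blank sample ids never to quantify (water controls).
#' @return data.frame sample_id, dct, rel_level.
#' @export
qmsp_relative <- function(ct, target, normalizer = "Alu", calibrator,
                          blank = c("H2O", "NTC")) {
  ct <- ct[!(ct$sample_id %in% blank), , drop = FALSE]
  ct_t <- mean_ct(ct, target)
  ct_n <- mean_ct(ct, normalizer)
  ids <- names(ct_t)
  missing_norm <- setdiff(ids, names(ct_n))
  if (length(missing_norm) > 0) {
    warning("qmsp_relative: no normalizer Ct for: ",
            paste(missing_norm, collapse = ", "), "; skipped")
    ids <- setdiff(ids, missing_norm)
  }
  if (!calibrator %in% ids)
    stop("qmsp_relative: calibrator has no usable Cts", call. = FALSE)
  dct <- ct_t[ids] - ct_n[ids]
  level <- 2^-(dct - dct[[calibrator]])
  data.frame(sample_id = ids, dct = unname(dct),
             rel_level = unname(level), stringsAsFactors = FALSE)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_housekeeping` per sample; `ddCt = dCt - mean dCt of
#' the reference group`; expression level `= 2^-ddCt`. Group means and SDs
#' of the levels are reported alongside.
#'
#' @param ct Ct table with a `group` column.
#' @param target gene assay name.
#' @param housekeeping housekeeping normalizer assay (e.g. `"ACTB"`,
#'   `"GAPDH"`).
#' @param reference_group group whose mean dCt anchors level 1.
#' @return list with `samples` (sample_id, group, dct, ddct, rel_expr) and
#'   `groups` (group, mean, sd, n).
#' @export
ddct_expression <- function(ct, target, housekeeping, reference_group = "NC") {
  ct_t <- mean_ct(ct, target)
  ct_h <- mean_ct(ct, housekeeping)
  ids <- intersect(names(ct_t), names(ct_h))
  skipped <- setdiff(names(ct_t), ids)
  if (length(skipped) > 0)
    warning("ddct_expression: no housekeeping Ct for: ",
            paste(skipped, collapse = ", "), "; skipped")
  grp <- ct$group[match(ids, ct$sample_id)]
  if (!any(grp == reference_group))
    stop("ddct_expression: reference group empty", call. = FALSE)
  dct <- ct_t[ids] - ct_h[ids]
  ddct <- dct - mean(dct[grp == reference_group])
  expr <- 2^-ddct
  samples <- data.frame(sample_id = ids, group = grp, dct = unname(dct),
                        ddct = unname(ddct), rel_expr = unname(expr),
                        stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(samples$rel_expr, samples$group),
                                  function(v) data.frame(mean = mean(v),
                                                         sd = stats::sd(v),
                                                         n = length(v))))
  groups <- data.frame(group = rownames(groups), groups, row.names = NULL,
                       stringsAsFactors = FALSE)
  list(samples = samples, groups = groups)
}

#' Three-gate candidate-gene filter
#'
#' Retains genes that are (i) expressed in normal colon, (ii) at most
#' `nc_max_pct` percent methylated in normal colon and (iii) at least
#' `uc_min_pct` percent methylated in UC samples, with per-gate diagnostics.
#'
#' @param msp_freq output of [msp_frequency()] covering NC and UC groups.
#' @param nc_expressed named logical vector: gene -> expressed in normal
#'   colon.
#' @param nc_max_pct,uc_min_pct methylation-percentage gates.
#' @return data.frame gene, gate_expression, gate_nc_meth, gate_uc_meth,
#'   pass; genes absent from a table are excluded with a warning.
#' @export
candidate_filter <- function(msp_freq, nc_expressed, nc_max_pct = 25,
                             uc_min_pct = 50) {
  genes <- sort(unique(msp_freq$gene))
  pick <- function(g, grp) {
    r <- msp_freq[msp_freq$gene == g & msp_freq$group == grp, , drop = FALSE]
    if (nrow(r) == 0) NA_real_ else r$percent[1]
  }
  nc <- vapply(genes, pick, numeric(1), grp = "NC")
  uc <- vapply(genes, pick, numeric(1), grp = "UC")
  expr <- nc_expressed[genes]
  incomplete <- is.na(nc) | is.na(uc) | is.na(expr)
  if (any(incomplete)) {
    warning("candidate_filter: excluded for missing data: ",
            paste(genes[incomplete], collapse = ", "))
    genes <- genes[!incomplete]
    nc <- nc[!incomplete]; uc <- uc[!incomplete]; expr <- expr[genes]
  }
  out <- data.frame(gene = genes,
                    gate_expression = unname(expr == TRUE),
                    gate_nc_meth = unname(nc <= nc_max_pct),
                    gate_uc_meth = unname(uc >= uc_min_pct),
                    stringsAsFactors = FALSE)
  out$pass <- out$gate_expression & out$gate_nc_meth & out$gate_uc_meth
  out
}

#' Two-group mean/SD summary with Student's t
#'
#' Mean and sample SD (n-1 denominator) per group plus a two-sided
#' pooled-variance t-test. If both groups are constant with unequal means the
#' p-value degenerates to 0 and is flagged.
#'
#' @param values numeric vector.
#' @param group two-level grouping vector aligned to `values`.
#' @return list with `summary` (group, mean, sd, n), `t`, `p_value`,
#'   `degenerate`.
#' @export
group_compare <- function(values, group) {
  sp <- split(values, group)
  if (length(sp) != 2) stop("group_compare: need exactly 2 groups", call. = FALSE)
  if (any(lengths(sp) < 2))
    stop("group_compare: need >= 2 values per group", call. = FALSE)
  summ <- data.frame(group = names(sp),
                     mean = vapply(sp, mean, numeric(1)),
                     sd = vapply(sp, stats::sd, numeric(1)),
                     n = lengths(sp), row.names = NULL,
                     stringsAsFactors = FALSE)
  res <- tryCatch({
    tt <- stats::t.test(sp[[1]], sp[[2]], var.equal = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  }, error = function(e) {
    eq <- isTRUE(all.equal(mean(sp[[1]]), mean(sp[[2]])))
    list(t = if (eq) 0 else sign(mean(sp[[1]]) - mean(sp[[2]])) * Inf,
         p = if (eq) 1 else 0, degenerate = TRUE)
  })
  list(summary = summ, t = res$t, p_value = res$p, degenerate = res$degenerate)
}

#' Cohort summary table
#'
#' Counts and percentages (one decimal) for every categorical clinical field
#' in the sample sheet plus mean, median and range of age. Unknown category
#' values are counted under `"other"` with a warning.
#'
#' @param sheet sample-sheet data.frame.
#' @param fields categorical fields to tabulate (defaults to the clinical
#'   fields present).
#' @param vocab optional named list of allowed values per field.
#' @return list with `table` (field, category, n, percent) and `age`
#'   (mean, median, min, max).
#' @export
summarize_cohort <- function(sheet,
                             fields = intersect(c("sex", "duration_class",
                                                  "lesion_location",
                                                  "mayo_class",
                                                  "clinical_type"),
                                                names(sheet)),
                             vocab = NULL) {
  if (nrow(sheet) == 0) stop("summarize_cohort: empty sheet", call. = FALSE)
  n_total <- nrow(sheet)
  rows <- list()
  for (f in fields) {
    x <- sheet[[f]]
    x <- x[!is.na(x)]
    if (!is.null(vocab[[f]])) {
      bad <- !(x %in% vocab[[f]])
      if (any(bad)) {
        warning("summarize_cohort: unknown ", f, " value(s) counted as 'other'")
        x[bad] <- "other"
      }
    }
    tab <- table(x)
    rows[[f]] <- data.frame(field = f, category = names(tab),
                            n = as.integer(tab),
                            percent = round(100 * as.integer(tab) / n_total, 1),
                            stringsAsFactors = FALSE)
  }
  age <- if ("age" %in% names(sheet)) {
    a <- sheet$age[!is.na(sheet$age)]
    list(mean = mean(a), median = stats::median(a), min = min(a), max = max(a))
  } else NULL
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       age = age, n_total = n_total)
}
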