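#' Per-probe two-group differential methylation tests
#'
#' For every probe, a two-sided Student's independent-samples t-test (pooled
#' variance) of UC versus NC beta values, plus the difference of group means.
#' A probe passes the DMC gate when `p < p_cut` AND `|delta_beta| >
#' delta_cut`; direction is hyper/hypo by the sign of `delta_beta` among
#' passers, else null. Positive-control (POS) samples must be excluded by the
#' caller (see [funnel()], which does).
#'
#' @param betas probes x samples beta matrix.
#' @param groups sample sheet (data.frame with `sample_id`, `group`; only
#'   NC/UC rows are used).
#' @param p_cut,delta_cut the two DMC gates.
#' @param welch use Welch's unequal-variance t instead of the pooled t.
#' @return data.frame of DmcRecords: probe_id, mean_nc, mean_uc, delta_beta,
#'   p_value, direction, pass_dmc.
#' @export
test_probes <- function(betas, groups, p_cut = 0.05, delta_cut = 0.2,
                        welch = FALSE) {
  groups <- groups[groups$group %in% c("NC", "UC"), , drop = FALSE]
  nc_ids <- intersect(groups$sample_id[groups$group == "NC"], colnames(betas))
  uc_ids <- intersect(groups$sample_id[groups$group == "UC"], colnames(betas))
  if (length(nc_ids) < 2 || length(uc_ids) < 2)
    stop("test_probes: need >= 2 samples per group", call. = FALSE)
  X <- betas[, nc_ids, drop = FALSE]
  Y <- betas[, uc_ids, drop = FALSE]
  mean_nc <- rowMeans(X)
  mean_uc <- rowMeans(Y)
  delta <- mean_uc - mean_nc
  p <- vapply(seq_len(nrow(betas)), function(i) {
    x <- X[i, ]; y <- Y[i, ]
    tryCatch(stats::t.test(y, x, var.equal = !welch)$p.value,
             error = function(e) {
               # constant data: equal means -> no evidence; unequal -> extreme
               if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
             })
  }, numeric(1))
  pass <- (p < p_cut) & (abs(delta) > delta_cut)
  direction <- ifelse(!pass, "null", ifelse(delta > 0, "hyper", "hypo"))
  data.frame(probe_id = rownames(betas), mean_nc = mean_nc, mean_uc = mean_uc,
             delta_beta = delta, p_value = p, direction = direction,
             pass_dmc = pass, row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold-change filter on hypermethylated DMCs
#'
#' `fold_change = (mean_uc + eps) / (mean_nc + eps)`; the pseudocount guards
#' near-zero normal-colon means. A record passes when it is a hyper DMC and
#' its fold change exceeds `fold_cut`.
#'
#' @param records DmcRecord data.frame from [test_probes()].
#' @param fold_cut fold-change threshold.
#' @param eps pseudocount added to both means.
#' @return list with `records` (augmented with `fold_change`, `pass_fold`)
#'   and `survivors` (probe ids of fold-passing hyper DMCs).
#' @export
fold_filter <- function(records, fold_cut = 1.7, eps = 0.01) {
  fold <- (records$mean_uc + eps) / (records$mean_nc + eps)
  pass <- records$direction == "hyper" & fold > fold_cut
  records$fold_change <- fold
  records$pass_fold <- pass
  list(records = records, survivors = records$probe_id[pass])
}

#' Mann-Whitney comparison of group-level beta distributions
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum, normal approximation with
#' tie correction) comparing per-probe NC means against per-probe UC means,
#' computed separately for the hyper- and hypo-classified probe sets — the
#' global hyper/hypo shift display.
#'
#' @param records DmcRecord data.frame (carries the group means and
#'   directions).
#' @return data.frame with one row per direction: n_probes, U statistic, p
#'   (NA with `undefined = TRUE` for an empty probe set).
#' @export
global_compare <- function(records) {
  one <- function(dir) {
    r <- records[records$direction == dir, , drop = FALSE]
    if (nrow(r) == 0)
      return(data.frame(direction = dir, n_probes = 0L, U = NA_real_,
                        p_value = NA_real_, undefined = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(r$mean_uc, r$mean_nc,
                                              exact = FALSE, correct = TRUE))
    data.frame(direction = dir, n_probes = nrow(r),
               U = unname(wt$statistic), p_value = wt$p.value,
               undefined = FALSE)
  }
  rbind(one("hyper"), one("hypo"))
}

#' Mann-Whitney U test between two value vectors
#'
#' Thin wrapper used for group-level comparisons; normal approximation with
#' tie correction for larger samples, exact for small untied samples.
#'
#' @param x,y numeric vectors.
#' @param exact force/forbid the exact null distribution (default: let
#'   `stats::wilcox.test` decide).
#' @return list with `U` and `p_value`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  if (stats::sd(c(x, y)) == 0)
    return(list(U = length(x) * length(y) / 2, p_value = 1))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' The staged differential-methylation filter funnel
#'
#' Composes (optional) detection QC, per-probe DMC testing, the fold-change
#' filter and promoter CpG-island selection, and reports the survivor count
#' of every stage. Positive-control samples are excluded from testing.
#'
#' @param betas probes x samples beta matrix (post-QC if `detection` is
#'   NULL).
#' @param groups sample sheet.
#' @param manifest annotated manifest (for promoter-island selection; NULL
#'   skips that stage and marks its count unavailable).
#' @param detection optional detection p-value matrix; when given, QC runs
#'   first.
#' @param p_cut,delta_cut,fold_cut,eps,qc_p_cut,call_rate_min stage
#'   thresholds.
#' @param welch use Welch's t test.
#' @return list with `report` (FunnelReport: n_total, n_qc, n_dmc, n_hyper,
#'   n_hypo, n_hyper_fold, n_hyper_promoter_island), `records`, and staged
#'   probe-id lists (`hyper`, `hypo`, `fold_survivors`, `promoter_island`).
#' @export
funnel <- function(betas, groups, manifest = NULL, detection = NULL,
                   p_cut = 0.05, delta_cut = 0.2, fold_cut = 1.7, eps = 0.01,
                   qc_p_cut = 0.05, call_rate_min = 0.99, welch = FALSE) {
  n_total <- nrow(betas)
  if (!is.null(detection)) {
    qc <- qc_samples_and_probes(detection, qc_p_cut, call_rate_min)
    betas <- betas[intersect(rownames(betas), qc$kept_probes),
                   intersect(colnames(betas), qc$kept_samples), drop = FALSE]
  }
  n_qc <- nrow(betas)
  records <- test_probes(betas, groups, p_cut, delta_cut, welch)
  hyper <- records$probe_id[records$direction == "hyper"]
  hypo <- records$probe_id[records$direction == "hypo"]
  ff <- fold_filter(records, fold_cut, eps)
  records <- ff$records
  promoter_island <- if (is.null(manifest)) NA else
    select_promoter_island_probes(ff$survivors, manifest)
  report <- data.frame(
    n_total = n_total, n_qc = n_qc,
    n_dmc = length(hyper) + length(hypo),
    n_hyper = length(hyper), n_hypo = length(hypo),
    n_hyper_fold = length(ff$survivors),
    n_hyper_promoter_island = if (is.null(manifest)) NA_integer_ else
      length(promoter_island))
  list(report = report, records = records, hyper = hyper, hypo = hypo,
       fold_survivors = ff$survivors, promoter_island = promoter_island)
}
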