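# Vectorized annotation of many probe positions against gene models and
# islands. Semantics identical to assign_feature()/island_relation(); the
# agreement is property-tested. positions are 1-based.
annotate_positions <- function(positions, gene_models, islands,
                               promoter_up = 1500, promoter_down = 500,
                               shore = 2000, shelf = 2000) {
  if (nrow(gene_models) == 0L) stop("no annotation", call. = FALSE)
  p0 <- positions - 1L
  n <- length(p0)

  # --- island relation via sorted disjoint island intervals
  relation <- rep("open_sea", n)
  if (nrow(islands) > 0L) {
    ist <- islands$start; ien <- islands$end
    idx <- findInterval(p0, ist)
    inside <- idx >= 1L & p0 < ien[pmax(idx, 1L)]
    # distance to nearest edge among flanking islands
    d_left <- ifelse(idx >= 1L, p0 - (ien[pmax(idx, 1L)] - 1L), Inf)
    d_right <- ifelse(idx < length(ist), ist[pmin(idx + 1L, length(ist))] - p0, Inf)
    dmin <- pmin(abs(d_left), abs(d_right))
    relation[dmin <= shore + shelf] <- "shelf"
    relation[dmin <= shore] <- "shore"
    relation[inside] <- "island"
  }

  # --- feature: promoter > exon > intron > intergenic
  up <- ifelse(gene_models$strand == "+",
               gene_models$tss - promoter_up, gene_models$tss - promoter_down)
  dn <- ifelse(gene_models$strand == "+",
               gene_models$tss + promoter_down, gene_models$tss + promoter_up)
  prom <- IRanges::IRanges(start = up + 1L, end = dn + 1L)  # 1-based inclusive
  ex_list <- lapply(gene_models$exons, parse_exons)
  n_ex <- vapply(ex_list, nrow, integer(1))
  ex_all <- do.call(rbind, ex_list)
  exons <- IRanges::IRanges(start = ex_all[, 1] + 1L, end = ex_all[, 2])
  body <- IRanges::IRanges(
    start = vapply(ex_list, function(m) min(m[, 1]), numeric(1)) + 1L,
    end = vapply(ex_list, function(m) max(m[, 2]), numeric(1)))
  pts <- IRanges::IRanges(start = p0 + 1L, width = 1L)
  in_prom <- IRanges::overlapsAny(pts, prom)
  in_exon <- IRanges::overlapsAny(pts, exons)
  in_body <- IRanges::overlapsAny(pts, body)
  feature <- ifelse(in_prom, "promoter",
                    ifelse(in_exon, "exon",
                           ifelse(in_body, "intron", "intergenic")))

  # --- nearest gene by TSS distance (tie -> earlier row, models TSS-sorted)
  o <- order(gene_models$tss)
  tss_s <- gene_models$tss[o]
  gidx <- findInterval(p0, tss_s)
  left <- pmax(gidx, 1L); right <- pmin(gidx + 1L, length(tss_s))
  dl <- abs(p0 - tss_s[left]); dr <- abs(p0 - tss_s[right])
  pick <- ifelse(gidx < 1L, right, ifelse(dl <= dr, left, right))
  gene <- gene_models$gene[o][pick]

  data.frame(feature = feature, island_relation = relation, gene = gene,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic array manifest
#'
#' Places `n_probes` CpG probes on the simulated genome and annotates each
#' with design type (I/II), nearest gene, feature class and island relation.
#' A configurable share of probes is placed inside CpG islands (the 450K
#' design is island/promoter-heavy); the rest are uniform over the chromosome.
#'
#' @param config a [sim_config()].
#' @param gene_models,islands annotation as from [simulate_annotation()].
#' @param frac_island_targeted fraction of probes placed inside islands.
#' @return manifest data.frame: probe_id, seq_id, position (1-based), strand,
#'   design_type, gene, feature, island_relation; ordered by position.
#' @export
generate_manifest <- function(config, gene_models, islands,
                              frac_island_targeted = 0.35) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(gene_models) || nrow(gene_models) == 0L)
    stop("no annotation", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_probes
  genome_len <- max(gene_models$tss) + 20000L
  n_isl <- round(frac_island_targeted * n)
  pos_isl <- integer(0)
  if (n_isl > 0 && nrow(islands) > 0) {
    pick <- sample.int(nrow(islands), n_isl, replace = TRUE)
    w <- islands$end[pick] - islands$start[pick]
    pos_isl <- islands$start[pick] + floor(stats::runif(n_isl) * w)
  }
  pos_uni <- floor(stats::runif(n - length(pos_isl)) * genome_len)
  position <- sort(as.integer(c(pos_isl, pos_uni))) + 1L  # 1-based
  design_type <- ifelse(stats::runif(n) < config$frac_type2, "II", "I")
  ann <- annotate_positions(position, gene_models, islands)
  data.frame(probe_id = sprintf("cg%07d", seq_len(n)),
             seq_id = gene_models$seq_id[1],
             position = position,
             strand = sample(c("+", "-"), n, replace = TRUE),
             design_type = design_type,
             gene = ann$gene,
             feature = ann$feature,
             island_relation = ann$island_relation,
             stringsAsFactors = FALSE)
}

#' Simulate M/U fluorescence intensities, sample sheet and ground truth
#'
#' Draws a baseline methylation state per probe (low/intermediate/high beta
#' states; promoter-island probes are predominantly unmethylated, open-sea
#' probes predominantly methylated, mirroring real array biology), plants
#' hyper-/hypomethylation effects of size `delta_planted` in the UC group,
#' and converts per-sample true betas into methylated/unmethylated channel
#' intensities: total intensity T per probe is lognormal, each channel gains
#' an additive normal background (floored at 0), type-II probes are
#' compressed toward 0.5 by the declared factor, and every intensity of a
#' sample is multiplied by that sample's lognormal dye factor. The
#' positive-control sample is near-fully methylated at all planted hyper
#' probes.
#'
#' @param config a [sim_config()].
#' @param manifest manifest from [generate_manifest()].
#' @param internals also return the latent intensity layer (total intensity
#'   `T`, background `b`, dye factors) for invariant checking.
#' @return list with `signals` (class `signal_set`: matrices `M`, `U`
#'   probes x samples, `negatives` controls x samples), `sample_sheet`,
#'   `truth` (probe_id, true_delta_beta, planted, direction) and
#'   `beta_true` (the per-sample true betas before the intensity layer).
#' @export
simulate_signals <- function(config, manifest, internals = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(manifest) != config$n_probes)
    stop("manifest length must equal config$n_probes", call. = FALSE)
  set.seed(config$seed + 1L)
  n <- config$n_probes
  sheet <- make_sample_sheet(config)
  n_samp <- nrow(sheet)

  # baseline state probabilities by annotation compartment
  bp <- config$baseline_beta_params
  prom_isl <- manifest$feature == "promoter" & manifest$island_relation == "island"
  isl <- manifest$island_relation == "island" & !prom_isl
  shore <- manifest$island_relation == "shore"
  pmat <- matrix(rep(c(0.20, 0.25, 0.55), each = n), n)  # open sea default
  pmat[shore, ] <- rep(c(0.40, 0.30, 0.30), each = sum(shore))
  pmat[isl, ] <- rep(c(0.70, 0.15, 0.15), each = sum(isl))
  pmat[prom_isl, ] <- rep(c(0.85, 0.10, 0.05), each = sum(prom_isl))
  u <- stats::runif(n)
  state <- 1L + (u > pmat[, 1]) + (u > pmat[, 1] + pmat[, 2])
  shapes <- do.call(rbind, bp)[state, , drop = FALSE]
  beta0 <- stats::rbeta(n, shapes[, 1], shapes[, 2])
  beta0 <- pmin(pmax(beta0, 0.08), 0.92)  # headroom for effects and noise

  # plant effects: hypermethylation among low-baseline probes (promoter-island
  # biology), hypomethylation among high-baseline probes
  truth <- data.frame(probe_id = manifest$probe_id, true_delta_beta = 0,
                      planted = FALSE,
                      direction = "null", stringsAsFactors = FALSE)
  low_pool <- which(beta0 <= 0.5)
  high_pool <- which(beta0 >= 0.5)
  if (config$n_planted_hyper > length(low_pool) ||
      config$n_planted_hypo > length(high_pool))
    stop("not enough probes with baseline headroom for planted effects",
         call. = FALSE)
  hyper_idx <- sort(sample(low_pool, config$n_planted_hyper))
  high_pool <- setdiff(high_pool, hyper_idx)
  hypo_idx <- sort(sample(high_pool, config$n_planted_hypo))
  truth$true_delta_beta[hyper_idx] <- config$delta_planted
  truth$true_delta_beta[hypo_idx] <- -config$delta_planted
  truth$planted[c(hyper_idx, hypo_idx)] <- TRUE
  truth$direction[hyper_idx] <- "hyper"
  truth$direction[hypo_idx] <- "hypo"

  # per-sample true betas
  clamp <- function(x) pmin(pmax(x, 0.02), 0.98)
  beta_true <- matrix(0, n, n_samp, dimnames = list(manifest$probe_id,
                                                    sheet$sample_id))
  for (j in seq_len(n_samp)) {
    m <- beta0
    if (sheet$group[j] == "UC") {
      m[hyper_idx] <- m[hyper_idx] + config$delta_planted
      m[hypo_idx] <- m[hypo_idx] - config$delta_planted
    } else if (sheet$group[j] == "POS") {
      m[hyper_idx] <- 0.93
    }
    beta_true[, j] <- rbeta_meansd(n, clamp(m), config$beta_sample_sd)
    if (sheet$group[j] == "POS")  # cell-line analog: fully methylated panel
      beta_true[hyper_idx, j] <- pmax(beta_true[hyper_idx, j], 0.85)
  }

  # intensity layer
  type2 <- manifest$design_type == "II"
  s <- config$type2_compression
  dye <- stats::rlnorm(n_samp, 0, config$dye_log_sd)
  M <- U <- matrix(0L, n, n_samp, dimnames = dimnames(beta_true))
  negatives <- matrix(0L, config$n_negative_controls, n_samp,
                      dimnames = list(sprintf("neg%04d",
                                              seq_len(config$n_negative_controls)),
                                      sheet$sample_id))
  T_mat <- b_mat <- if (internals) matrix(0, n, n_samp) else NULL
  for (j in seq_len(n_samp)) {
    bc <- beta_true[, j]
    bc[type2] <- 0.5 + s * (bc[type2] - 0.5)
    tt <- stats::rlnorm(n, config$total_intensity_log_mean,
                        config$total_intensity_log_sd)
    b <- pmax(stats::rnorm(n, config$background_mean, config$background_sd), 0)
    M[, j] <- as.integer(round(dye[j] * (bc * tt + b)))
    U[, j] <- as.integer(round(dye[j] * ((1 - bc) * tt + b)))
    negatives[, j] <- as.integer(round(dye[j] * pmax(
      stats::rnorm(config$n_negative_controls, config$background_mean,
                   config$background_sd), 0)))
    if (internals) { T_mat[, j] <- tt; b_mat[, j] <- b }
  }
  signals <- structure(list(M = M, U = U, negatives = negatives,
                            sample_ids = sheet$sample_id),
                       class = "signal_set")
  out <- list(signals = signals, sample_sheet = sheet, truth = truth,
              beta_true = beta_true)
  if (internals)
    out$internals <- list(total = T_mat, background = b_mat, dye = dye)
  out
}

# Sample sheet for the simulated cohort. Inflammation status mirrors the
# study's split (UC 1, 3, 5 inactive; UC 6, 8 active) and extends it to the
# remaining UC samples.
make_sample_sheet <- function(config) {
  ids <- c(sprintf("NC%d", seq_len(config$n_nc)),
           sprintf("UC%d", seq_len(config$n_uc)))
  group <- c(rep("NC", config$n_nc), rep("UC", config$n_uc))
  if (config$include_positive_control) {
    ids <- c(ids, "POS1"); group <- c(group, "POS")
  }
  inactive <- c(1, 3, 5)
  inflammation <- rep(NA_character_, length(ids))
  is_uc <- group == "UC"
  inflammation[is_uc] <- ifelse(as.integer(sub("^UC", "", ids[is_uc])) %in%
                                  inactive, "inactive", "active")
  set.seed(config$seed + 2L)
  n <- length(ids)
  data.frame(sample_id = ids, group = group, inflammation = inflammation,
             age = sample(25:70, n, replace = TRUE),
             sex = sample(c("male", "female"), n, replace = TRUE),
             duration_class = sample(c("<=1y", "1-8y", ">9y"), n, replace = TRUE),
             lesion_location = ifelse(group == "UC",
                                      sample(c("proctitis", "left_sided",
                                               "pancolitis"), n, replace = TRUE),
                                      NA),
             mayo_class = ifelse(group == "UC",
                                 sample(c("inactive", "mild", "moderate",
                                          "severe"), n, replace = TRUE), NA),
             clinical_type = ifelse(group == "UC",
                                    sample(c("one_episode", "chronic_relapsing",
                                             "chronic_continuous"), n,
                                           replace = TRUE), NA),
             stringsAsFactors = FALSE)
}
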