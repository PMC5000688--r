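#' Run the full synthetic-to-report analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> differential-methylation funnel ->
#' annotation-based promoter-island selection -> clustering -> enrichment
#' from a single configuration, writing every stage artifact under `out_dir`
#' and a run log with versions, seed, thresholds and stage counts. Stages can
#' be toggled; a disabled annotate stage marks the promoter-island count
#' unavailable (NA) rather than zero.
#'
#' @param config named list: `seed` (required when simulating), optional
#'   `sim` (arguments to [sim_config()]), `cuts` (p_cut, delta_cut, fold_cut,
#'   call_rate_min, enrich_p), `stages` (logical toggles: preprocess, dmc,
#'   annotate, cluster, enrich), `bmiq` (logical).
#' @param out_dir output directory (created if missing).
#' @return list with `funnel` (report + staged lists), `paths` of written
#'   artifacts, and the stage objects.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- utils::modifyList(list(preprocess = TRUE, dmc = TRUE,
                                   annotate = TRUE, cluster = TRUE,
                                   enrich = FALSE), config$stages %||% list())
  cuts <- utils::modifyList(list(p_cut = 0.05, delta_cut = 0.2,
                                 fold_cut = 1.7, call_rate_min = 0.99,
                                 enrich_p = 1e-3), config$cuts %||% list())
  if (is.null(config$seed)) stop("run_pipeline: seed required", call. = FALSE)
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("ucmeth pipeline | R ", R.version.string)
  logline("seed=", config$seed)
  logline("cuts: ", paste(names(cuts), unlist(cuts), sep = "=", collapse = " "))

  paths <- list()
  wr <- function(obj, name, writer) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    paths[[name]] <<- p
    p
  }

  cfg <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                               config$sim %||% list()))
  ann <- simulate_annotation(seed = cfg$seed)
  manifest <- generate_manifest(cfg, ann$gene_models, ann$islands)
  sim <- simulate_signals(cfg, manifest)
  wr(manifest, "manifest.tsv", write_manifest)
  wr(sim$sample_sheet, "sample_sheet.tsv", write_sample_sheet)
  wr(sim$truth, "truth.tsv", function(x, p) write_tsv(x, p))
  write_signal_set(sim$signals, file.path(out_dir, "signals"))
  logline("simulated ", cfg$n_probes, " probes x ",
          nrow(sim$sample_sheet), " samples")

  if (!stages$preprocess)
    return(invisible(list(paths = paths, funnel = NULL)))
  prep <- preprocess_signals(sim$signals, manifest,
                             call_rate_min = cuts$call_rate_min,
                             bmiq = isTRUE(config$bmiq %||% TRUE),
                             bmiq_seed = config$seed)
  wr(prep$betas, "betas.tsv", write_beta_matrix)
  logline("preprocess: kept ", nrow(prep$betas), "/", cfg$n_probes,
          " probes, ", ncol(prep$betas), " samples")

  out <- list(paths = paths, manifest = manifest, sim = sim, prep = prep)
  if (!stages$dmc) return(invisible(out))
  fun <- funnel(prep$betas, sim$sample_sheet,
                manifest = if (stages$annotate) manifest else NULL,
                p_cut = cuts$p_cut, delta_cut = cuts$delta_cut,
                fold_cut = cuts$fold_cut)
  wr(fun$records, "dmc_records.tsv", function(x, p) write_tsv(x, p))
  wr(fun$report, "funnel_report.tsv", function(x, p) write_tsv(x, p))
  writeLines(fun$hyper, file.path(out_dir, "hyper_probes.txt"))
  writeLines(fun$fold_survivors, file.path(out_dir, "fold_survivors.txt"))
  if (stages$annotate)
    writeLines(fun$promoter_island,
               file.path(out_dir, "promoter_island_probes.txt"))
  logline("funnel: ", paste(names(fun$report), unlist(fun$report),
                            sep = "=", collapse = " "))
  out$funnel <- fun

  if (stages$cluster && length(fun$hyper) + length(fun$hypo) >= 2) {
    dmc_ids <- c(fun$hyper, fun$hypo)
    hc <- hier_cluster(prep$betas[dmc_ids, , drop = FALSE])
    mds <- classical_mds(prep$betas[dmc_ids, , drop = FALSE])
    wr(data.frame(sample_id = colnames(prep$betas)[hc$order]),
       "leaf_order.tsv", function(x, p) write_tsv(x, p))
    wr(data.frame(sample_id = rownames(mds), mds), "mds_coords.tsv",
       function(x, p) write_tsv(x, p))
    out$cluster <- list(hclust = hc, mds = mds)
    logline("cluster: ", ncol(prep$betas), " samples on ", length(dmc_ids),
            " DMC probes")
  }

  if (stages$enrich && !is.null(config$gene_sets)) {
    hyper_genes <- unique(manifest$gene[manifest$probe_id %in%
                                          (fun$promoter_island %||%
                                             fun$fold_survivors)])
    er <- enrich(hyper_genes, config$gene_sets,
                 universe = unique(manifest$gene),
                 p_threshold = cuts$enrich_p)
    wr(er, "enrichment.tsv", function(x, p) write_tsv(x, p))
    out$enrichment <- er
    logline("enrich: ", sum(er$significant), " significant terms")
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
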