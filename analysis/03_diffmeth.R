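#!/usr/bin/env Rscript
# Differential methylation funnel: per-CpG pooled-t tests with the
# p < 0.05 and |delta-beta| > 0.2 gates, the > 1.7-fold filter on
# hypermethylated survivors, and promoter CpG-island selection; plus the
# global hyper/hypo Mann-Whitney comparison and recovery scoring against
# the planted truth.
source("analysis/00_common.R")

manifest <- read_manifest(file.path(DATA_DIR, "manifest.tsv"))
sheet <- read_sample_sheet(file.path(DATA_DIR, "sample_sheet.tsv"))
betas <- read_beta_matrix(file.path(OUT_DIR, "betas.tsv"))
truth <- ucmeth:::read_tsv(file.path(DATA_DIR, "truth.tsv"))

fun <- funnel(betas, sheet, manifest = manifest)
ucmeth:::write_tsv(fun$records, file.path(OUT_DIR, "dmc_records.tsv"))
ucmeth:::write_tsv(fun$report, file.path(OUT_DIR, "funnel_report.tsv"))
writeLines(fun$promoter_island,
           file.path(OUT_DIR, "promoter_island_probes.txt"))

gc <- global_compare(fun$records)
ucmeth:::write_tsv(gc, file.path(OUT_DIR, "global_compare.tsv"))

hyper_true <- truth$probe_id[truth$direction == "hyper"]
null_ids <- truth$probe_id[truth$direction == "null"]
say("funnel: %d tested -> %d DMC (%d hyper / %d hypo) -> %d fold -> %d promoter-island",
    fun$report$n_qc, fun$report$n_dmc, fun$report$n_hyper,
    fun$report$n_hypo, fun$report$n_hyper_fold,
    fun$report$n_hyper_promoter_island)
say("sensitivity for planted hyper CpGs: %.3f; false hyper calls: %d of %d null probes",
    mean(hyper_true %in% fun$hyper),
    length(intersect(fun$hyper, null_ids)), length(null_ids))
say("Mann-Whitney p (hyper set): %.3g", gc$p_value[gc$direction == "hyper"])
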