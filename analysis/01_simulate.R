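#!/usr/bin/env Rscript
# Generate the synthetic study dataset: an Infinium-450K-style array of
# 20,000 CpG probes over 3 normal-colon and 8 UC samples plus one
# fully-methylated positive-control sample, with 250 planted
# hypermethylated and 20 hypomethylated CpGs at delta-beta 0.3.
source("analysis/00_common.R")

cfg <- sim_config(n_probes = 20000, n_nc = 3, n_uc = 8,
                  n_planted_hyper = 250, n_planted_hypo = 20,
                  delta_planted = 0.3, seed = SEED)
ann <- simulate_annotation(seed = SEED)
manifest <- generate_manifest(cfg, ann$gene_models, ann$islands)
sim <- simulate_signals(cfg, manifest)

write_manifest(manifest, file.path(DATA_DIR, "manifest.tsv"))
write_gene_models(ann$gene_models, file.path(DATA_DIR, "gene_models.tsv"))
write_bed(ann$islands, file.path(DATA_DIR, "islands.bed"))
write_sample_sheet(sim$sample_sheet, file.path(DATA_DIR, "sample_sheet.tsv"))
ucmeth:::write_tsv(sim$truth, file.path(DATA_DIR, "truth.tsv"))
write_signal_set(sim$signals, file.path(DATA_DIR, "signals"))

say("wrote %d probes x %d samples to %s", nrow(manifest),
    nrow(sim$sample_sheet), DATA_DIR)
say("planted: %d hyper, %d hypo at delta-beta %.2f",
    sum(sim$truth$direction == "hyper"), sum(sim$truth$direction == "hypo"),
    cfg$delta_planted)
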