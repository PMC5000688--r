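#!/usr/bin/env Rscript
# Annotation layer: the feature x island-relation distribution of the DMC
# panel (the display that shows UC-associated CpGs concentrate in promoter
# islands), and a sequence-level demonstration of the CpG-island caller on
# generated promoter sequences with known embedded islands.
source("analysis/00_common.R")

manifest <- read_manifest(file.path(DATA_DIR, "manifest.tsv"))
records <- ucmeth:::read_tsv(file.path(OUT_DIR, "dmc_records.tsv"))

dmc <- manifest[manifest$probe_id %in%
                  records$probe_id[records$pass_dmc], , drop = FALSE]
tab <- feature_distribution(dmc)
ucmeth:::write_tsv(as.data.frame(tab), file.path(OUT_DIR,
                                                 "dmc_distribution.tsv"))
say("DMC panel: %d probes; promoter-island share %.1f%%", nrow(dmc),
    100 * tab["promoter", "island"] / nrow(dmc))

g <- generate_promoter_fasta(25, island_len = 300, gc = 0.65, obs_exp = 0.8,
                             seed = SEED)
write_fasta(g$sequences, file.path(DATA_DIR, "promoters.fa"))
called <- do.call(rbind, lapply(names(g$sequences), function(id) {
  isl <- find_cpg_islands(g$sequences[[id]])
  if (nrow(isl) > 0) cbind(seq_id = id, isl)
}))
write_bed(called, file.path(OUT_DIR, "called_islands.bed"))
hits <- merge(called, g$islands, by = "seq_id", suffixes = c("", "_true"))
jac <- pmax(0, pmin(hits$end, hits$end_true) - pmax(hits$start, hits$start_true)) /
  (pmax(hits$end, hits$end_true) - pmin(hits$start, hits$start_true))
say("island caller on %d promoter sequences: %d called, median Jaccard %.2f",
    length(g$sequences), nrow(called), median(jac))
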