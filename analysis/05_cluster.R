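#!/usr/bin/env Rscript
# Unsupervised structure of the methylation profiles: hierarchical
# clustering of samples on the DMC panel (the positive-control cell-line
# analog is shown but excluded from purity scoring) and classical MDS on
# 1 - Pearson correlation distances.
source("analysis/00_common.R")

sheet <- read_sample_sheet(file.path(DATA_DIR, "sample_sheet.tsv"))
betas <- read_beta_matrix(file.path(OUT_DIR, "betas.tsv"))
records <- ucmeth:::read_tsv(file.path(OUT_DIR, "dmc_records.tsv"))

dmc_ids <- records$probe_id[records$pass_dmc]
b <- betas[dmc_ids, , drop = FALSE]

hc <- hier_cluster(b)
ucmeth:::write_tsv(data.frame(order = seq_along(hc$order),
                              sample_id = colnames(b)[hc$order]),
                   file.path(OUT_DIR, "leaf_order.tsv"))

keep <- sheet$group != "POS"
hc2 <- hier_cluster(b[, sheet$sample_id[keep], drop = FALSE])
purity <- cluster_purity(hc2, 2, sheet$group[keep])

mds <- classical_mds(b)
ucmeth:::write_tsv(data.frame(sample_id = rownames(mds), mds),
                   file.path(OUT_DIR, "mds_coords.tsv"))

say("clustered %d samples on %d DMC probes; leaf order: %s",
    ncol(b), nrow(b), paste(colnames(b)[hc$order], collapse = " "))
say("NC/UC purity at k = 2 (positive control excluded): %.2f", purity)
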