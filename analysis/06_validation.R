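#!/usr/bin/env Rscript
# The wet-lab validation layer on synthetic inputs mirroring the published
# design: MSP call frequencies for the three-gene panel across 79 UC and
# 8 NC samples, bisulfite clone summaries, Alu-normalized qMSP,
# delta-delta-Ct expression with group testing, the three-gate candidate
# filter, and the cohort characteristics table.
source("analysis/00_common.R")

## MSP frequencies (published-marginal reconstruction)
msp <- uc_msp_template()
freq <- msp_frequency(msp)
ucmeth:::write_tsv(freq, file.path(OUT_DIR, "msp_frequencies.tsv"))
uc <- freq[freq$group == "UC", ]
say("MSP, UC n=79: %s", paste(sprintf("%s %.1f%%", uc$gene, uc$percent),
                              collapse = ", "))

## candidate filter over the panel
cand <- candidate_filter(freq, c(KIAA1614 = TRUE, RIBC2 = TRUE,
                                 FAM217B = TRUE))
ucmeth:::write_tsv(cand, file.path(OUT_DIR, "candidate_filter.tsv"))
say("candidate filter passes: %s", paste(cand$gene[cand$pass], collapse = ", "))

## bisulfite clone matrices: dense methylation in UC, sparse in NC
uc_clones <- simulate_clone_matrix(10, 24, 0.85, seed = SEED)
nc_clones <- simulate_clone_matrix(10, 24, 0.08, seed = SEED + 1)
write_clone_matrix(uc_clones, file.path(DATA_DIR, "clones_uc.tsv"))
write_clone_matrix(nc_clones, file.path(DATA_DIR, "clones_nc.tsv"))
su <- clone_summary(uc_clones); sn <- clone_summary(nc_clones)
say("bisulfite clones: UC density %.2f vs NC %.2f", su$density, sn$density)
writeLines(c("UC:", su$grid, "NC:", sn$grid),
           file.path(OUT_DIR, "clone_lollipops.txt"))

## Alu-normalized qMSP on 8 UC vs 8 NC with IVD calibrator
set.seed(SEED)
sheet <- data.frame(sample_id = c("IVD", sprintf("UC%d", 1:8),
                                  sprintf("NC%d", 1:8)),
                    group = c("POS", rep("UC", 8), rep("NC", 8)))
q <- cbind(target = c(1, runif(8, 0.3, 0.9), runif(8, 0.005, 0.05)),
           Alu = 1)
ct <- simulate_ct_table(sheet, c("GENE", "Alu"), q, noise_sd = 0.1,
                        seed = SEED, n_replicates = 3)
write_ct_table(ct, file.path(DATA_DIR, "qmsp_ct.tsv"))
qm <- qmsp_relative(ct, "GENE", calibrator = "IVD")
qm$group <- sheet$group[match(qm$sample_id, sheet$sample_id)]
ucmeth:::write_tsv(qm, file.path(OUT_DIR, "qmsp_levels.tsv"))
gcq <- group_compare(qm$rel_level[qm$group != "POS"],
                     qm$group[qm$group != "POS"])
say("qMSP relative methylation: UC mean %.2f vs NC %.2f, pooled-t p = %.2g",
    gcq$summary$mean[gcq$summary$group == "UC"],
    gcq$summary$mean[gcq$summary$group == "NC"], gcq$p_value)

## expression: planted 4-fold silencing in UC, ACTB housekeeping
sheet_e <- data.frame(sample_id = c(sprintf("NC%d", 1:10),
                                    sprintf("UC%d", 1:15)),
                      group = rep(c("NC", "UC"), c(10, 15)))
qe <- cbind(g = ifelse(sheet_e$group == "UC", 0.25, 1), hk = 1)
cte <- simulate_ct_table(sheet_e, c("GENE", "ACTB"), qe, noise_sd = 0.1,
                         seed = SEED + 2, n_replicates = 3)
ex <- ddct_expression(cte, "GENE", "ACTB", "NC")
ucmeth:::write_tsv(ex$groups, file.path(OUT_DIR, "expression_groups.tsv"))
gce <- group_compare(ex$samples$rel_expr, ex$samples$group)
say("expression: UC fold %.2f (planted 0.25), mean +/- SD %.2f +/- %.2f, p = %.2g",
    ex$groups$mean[ex$groups$group == "UC"],
    ex$groups$mean[ex$groups$group == "UC"],
    ex$groups$sd[ex$groups$group == "UC"], gce$p_value)

## cohort characteristics
cs <- summarize_cohort(uc_cohort_template())
ucmeth:::write_tsv(cs$table, file.path(OUT_DIR, "cohort_summary.tsv"))
say("cohort: n=%d, male %.1f%%, proctitis %.1f%%, age mean %.1f (range %d-%d)",
    cs$n_total, cs$table$percent[cs$table$category == "male"],
    cs$table$percent[cs$table$category == "proctitis"],
    cs$age$mean, cs$age$min, cs$age$max)
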