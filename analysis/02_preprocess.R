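#!/usr/bin/env Rscript
# Preprocess raw channel intensities to a QC'd, normalized beta matrix:
# detection p-values against negative controls, median dye scaling,
# background subtraction, call-rate QC, beta computation and BMIQ-style
# normalization of type-II probes onto the type-I scale.
source("analysis/00_common.R")

manifest <- read_manifest(file.path(DATA_DIR, "manifest.tsv"))
signals <- read_signal_set(file.path(DATA_DIR, "signals"))

prep <- preprocess_signals(signals, manifest, bmiq = TRUE, bmiq_seed = SEED)
write_beta_matrix(prep$betas, file.path(OUT_DIR, "betas.tsv"))
qc <- data.frame(sample_id = names(prep$qc$sample_call_rates),
                 call_rate = unname(prep$qc$sample_call_rates),
                 scale_factor = unname(prep$scale_factors))
ucmeth:::write_tsv(qc, file.path(OUT_DIR, "qc_report.tsv"))

say("kept %d/%d probes and %d/%d samples (call-rate floor %.2f)",
    prep$qc$n_probes_kept, prep$qc$n_probes_in,
    prep$qc$n_samples_kept, prep$qc$n_samples_in, prep$qc$call_rate_min)
say("per-sample call rates: %.4f - %.4f",
    min(qc$call_rate), max(qc$call_rate))
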