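#!/usr/bin/env Rscript
# Hypergeometric over-representation of the promoter-island
# hypermethylated gene panel against synthetic gene sets. One set is
# enriched by construction (built around the panel), the rest are random
# draws from the manifest universe.
source("analysis/00_common.R")

manifest <- read_manifest(file.path(DATA_DIR, "manifest.tsv"))
panel_probes <- readLines(file.path(OUT_DIR, "promoter_island_probes.txt"))
panel <- unique(manifest$gene[manifest$probe_id %in% panel_probes])
universe <- unique(manifest$gene)

set.seed(SEED)
sets <- c(
  list(planted_pathway = unique(c(sample(panel, min(10, length(panel))),
                                  sample(universe, 10)))),
  setNames(lapply(1:15, function(i) sample(universe, sample(8:25, 1))),
           sprintf("random_set_%02d", 1:15)))
write_gmt(sets, file.path(DATA_DIR, "gene_sets.gmt"))

res <- enrich(panel, read_gmt(file.path(DATA_DIR, "gene_sets.gmt")),
              universe = universe, p_threshold = 1e-3)
ucmeth:::write_tsv(res, file.path(OUT_DIR, "enrichment.tsv"))

say("panel: %d genes of %d in universe", length(panel), length(universe))
say("top term: %s (overlap %d/%d, p = %.3g, significant at 1e-3: %s)",
    res$term[1], res$overlap[1], res$set_size[1], res$p_value[1],
    res$significant[1])
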