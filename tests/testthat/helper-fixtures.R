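# Small shared fixtures, built in code.

small_cfg <- function(seed = 7, ...) {
  args <- utils::modifyList(list(n_probes = 2000, n_planted_hyper = 40,
                                 n_planted_hypo = 10, seed = seed), list(...))
  do.call(sim_config, args)
}

small_sim <- function(seed = 7, ...) {
  cfg <- small_cfg(seed = seed, ...)
  ann <- simulate_annotation(n_genes = 60, seed = seed)
  mf <- generate_manifest(cfg, ann$gene_models, ann$islands)
  c(list(cfg = cfg, ann = ann, manifest = mf),
    simulate_signals(cfg, mf, internals = TRUE))
}

# Minimal signal_set built by hand.
tiny_signals <- function(M, U, negatives) {
  structure(list(M = M, U = U, negatives = negatives,
                 sample_ids = colnames(M)),
            class = "signal_set")
}
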