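test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_probes = 100), "seed")
  expect_error(sim_config(n_probes = -1, seed = 1), "nonnegative")
  expect_error(sim_config(delta_planted = 1.2, seed = 1), "delta_planted")
  expect_error(sim_config(frac_type2 = 1.5, seed = 1), "frac_type2")
  expect_error(sim_config(n_probes = 10, n_planted_hyper = 8,
                          n_planted_hypo = 8, seed = 1), "exceed")
  expect_error(sim_config(total_intensity_log_sd = 0, seed = 1), "positive")
  expect_s3_class(sim_config(seed = 1), "sim_config")
})

test_that("manifest generation honors design mix and determinism", {
  ann <- simulate_annotation(n_genes = 40, seed = 3)
  cfg <- sim_config(n_probes = 1000, frac_type2 = 0.7, seed = 1)
  mf <- generate_manifest(cfg, ann$gene_models, ann$islands)
  expect_equal(nrow(mf), 1000)
  expect_false(anyDuplicated(mf$probe_id) > 0)
  expect_gt(mean(mf$design_type == "II"), 0.6)
  expect_lt(mean(mf$design_type == "II"), 0.8)

  cfg1 <- sim_config(n_probes = 500, frac_type2 = 0, seed = 2)
  mf1 <- generate_manifest(cfg1, ann$gene_models, ann$islands)
  expect_true(all(mf1$design_type == "I"))

  mf_a <- generate_manifest(cfg, ann$gene_models, ann$islands)
  expect_identical(mf, mf_a)

  expect_error(generate_manifest(cfg, ann$gene_models[0, ], ann$islands),
               "no annotation")
})

test_that("planted effects are realized at the configured delta", {
  sim <- small_sim(seed = 7, n_probes = 20000, n_planted_hyper = 250,
                   n_planted_hypo = 20)
  sheet <- sim$sample_sheet
  uc <- sheet$sample_id[sheet$group == "UC"]
  nc <- sheet$sample_id[sheet$group == "NC"]
  hy <- sim$truth$direction == "hyper"
  d <- rowMeans(sim$beta_true[hy, uc]) - rowMeans(sim$beta_true[hy, nc])
  expect_lt(abs(mean(d) - 0.3), 0.03)
  ho <- sim$truth$direction == "hypo"
  d2 <- rowMeans(sim$beta_true[ho, uc]) - rowMeans(sim$beta_true[ho, nc])
  expect_lt(abs(mean(d2) + 0.3), 0.04)
  # truth table consistency
  expect_true(all(sim$truth$planted == (sim$truth$direction != "null")))
  expect_true(all((abs(sim$truth$true_delta_beta) > 0) == sim$truth$planted))
  # positive control is near-fully methylated at planted hyper probes
  expect_true(all(sim$beta_true[hy, "POS1"] >= 0.8))
})

test_that("no planted effects yields an all-null truth table", {
  sim <- small_sim(seed = 5, n_planted_hyper = 0, n_planted_hypo = 0)
  expect_equal(sum(sim$truth$planted), 0)
  expect_true(all(sim$truth$direction == "null"))
})

test_that("intensity layer conserves M + U = dye * (T + 2b) within rounding", {
  sim <- small_sim(seed = 9, n_probes = 500, dye_log_sd = 0.1)
  tot <- sim$signals$M + sim$signals$U
  expected <- sweep(sim$internals$total + 2 * sim$internals$background, 2,
                    sim$internals$dye, "*")
  expect_lt(max(abs(tot - expected)), 1.0001)
})

test_that("generator output is deterministic under a fixed config", {
  a <- small_sim(seed = 11, n_probes = 400)
  b <- small_sim(seed = 11, n_probes = 400)
  expect_identical(a$signals$M, b$signals$M)
  expect_identical(a$signals$negatives, b$signals$negatives)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sample_sheet, b$sample_sheet)
})

test_that("clone matrix simulation matches its Bernoulli definition", {
  expect_error(simulate_clone_matrix(0, 5, 0.5, 1), "at least one")
  expect_error(simulate_clone_matrix(5, 5, 1.5, 1), "p_meth")
  ones <- simulate_clone_matrix(4, 6, 1, 1)
  expect_true(all(ones == 1))
  zeros <- simulate_clone_matrix(4, 6, 0, 1)
  expect_true(all(zeros == 0))
  m <- simulate_clone_matrix(10, 20, 0.8, 3)
  expect_lt(abs(mean(m) - 0.8), 0.1)
})

test_that("Ct simulation follows the log2 amplification model", {
  sheet <- data.frame(sample_id = c("a", "b"), group = "UC")
  q <- rbind(c(1, 0.25), c(2, 0.25))
  ct <- simulate_ct_table(sheet, c("g1", "g2"), q, ct_ref = 25, noise_sd = 0,
                          seed = 1)
  expect_equal(ct$ct[ct$sample_id == "a" & ct$target == "g1"], 25)
  expect_equal(ct$ct[ct$sample_id == "a" & ct$target == "g2"], 27)
  expect_equal(ct$ct[ct$sample_id == "b" & ct$target == "g1"], 24)
  expect_error(simulate_ct_table(sheet, "g1", cbind(c(1, -1)), seed = 1),
               "positive")
})

test_that("promoter FASTA generator embeds recoverable islands", {
  g <- generate_promoter_fasta(5, island_len = 300, gc = 0.65, obs_exp = 0.8,
                               seed = 21)
  expect_length(g$sequences, 5)
  for (i in 1:5) {
    called <- find_cpg_islands(g$sequences[[i]])
    expect_equal(nrow(called), 1)
    tr <- g$islands[i, ]
    expect_gte(jaccard(called$start, called$end, tr$start, tr$end), 0.8)
  }
  # pure A/T flanks carry nothing callable outside the embedded segment
  g2 <- generate_promoter_fasta(3, island_len = 250, gc = 0.7, flank_gc = 0,
                                seed = 22)
  for (i in 1:3) {
    called <- find_cpg_islands(g2$sequences[[i]])
    tr <- g2$islands[i, ]
    expect_true(all(called$start >= tr$start & called$end <= tr$end))
  }
  empty <- generate_promoter_fasta(0, seed = 1)
  expect_length(empty$sequences, 0)
  expect_error(generate_promoter_fasta(1, island_len = 100, seed = 1), ">= 200")
  expect_error(generate_promoter_fasta(1, island_len = 300, gc = 1,
                                       obs_exp = 3, seed = 1), "unachievable")
})
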