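make_betas <- function(nc, uc, probe = "cg1") {
  b <- rbind(c(nc, uc))
  rownames(b) <- probe
  colnames(b) <- c(paste0("NC", seq_along(nc)), paste0("UC", seq_along(uc)))
  b
}
two_group_sheet <- function(n_nc, n_uc) {
  data.frame(sample_id = c(paste0("NC", seq_len(n_nc)),
                           paste0("UC", seq_len(n_uc))),
             group = rep(c("NC", "UC"), c(n_nc, n_uc)))
}

test_that("per-probe t-tests apply both DMC gates", {
  nc <- c(0.10, 0.12, 0.11)
  uc <- c(0.45, 0.50, 0.48, 0.46, 0.47, 0.49, 0.44, 0.51)
  rec <- test_probes(make_betas(nc, uc), two_group_sheet(3, 8))
  orc <- pooled_t_oracle(uc, nc)
  expect_equal(rec$p_value, orc$p, tolerance = 1e-12)
  expect_equal(rec$delta_beta, mean(uc) - mean(nc))
  expect_gt(rec$delta_beta, 0.2)
  expect_lt(rec$p_value, 0.05)
  expect_equal(rec$direction, "hyper")
  expect_true(rec$pass_dmc)

  # equal means, nonzero variance -> p = 1, null
  rec2 <- test_probes(make_betas(c(0.3, 0.4, 0.5), c(0.3, 0.4, 0.5)),
                      two_group_sheet(3, 3))
  expect_equal(rec2$p_value, 1)
  expect_equal(rec2$direction, "null")

  # a large delta with an insignificant p fails the gate
  nc3 <- c(0.05, 0.6, 0.2)
  uc3 <- c(0.6, 0.95, 0.1)
  rec3 <- test_probes(make_betas(nc3, uc3), two_group_sheet(3, 3))
  expect_gt(abs(rec3$delta_beta), 0.2)
  expect_gt(rec3$p_value, 0.05)
  expect_false(rec3$pass_dmc)

  expect_error(test_probes(make_betas(0.1, c(0.2, 0.3)),
                           two_group_sheet(1, 2)), ">= 2 samples")
})

test_that("pooled-t p-values match the brute-force formula on random cases", {
  set.seed(99)
  for (i in 1:1000) {
    n1 <- sample(2:6, 1); n2 <- sample(2:9, 1)
    x <- runif(n1); y <- runif(n2)
    rec <- test_probes(make_betas(x, y), two_group_sheet(n1, n2))
    expect_equal(rec$p_value, pooled_t_oracle(y, x)$p, tolerance = 1e-10)
  }
})

test_that("fold filter uses the pseudocount-guarded mean ratio", {
  rec <- data.frame(probe_id = c("a", "b", "c"),
                    mean_nc = c(0.2, 0.0, 0.3),
                    mean_uc = c(0.36, 0.5, 0.45),
                    direction = c("hyper", "hyper", "hyper"))
  ff0 <- fold_filter(rec, fold_cut = 1.7, eps = 0)
  expect_true("a" %in% ff0$survivors)        # 1.8 > 1.7
  expect_false("c" %in% ff0$survivors)       # 1.5
  ff <- fold_filter(rec, fold_cut = 1.7, eps = 0.01)
  expect_equal(ff$records$fold_change[2], 51)
  expect_true(all(is.finite(ff$records$fold_change)))
  # non-hyper records never pass
  rec$direction <- "hypo"
  expect_length(fold_filter(rec)$survivors, 0)
})

test_that("label swap negates deltas and swaps directions", {
  sim <- small_sim(seed = 17, n_probes = 1500)
  sheet <- sim$sample_sheet
  b <- compute_beta(sim$signals$M, sim$signals$U)
  rec <- test_probes(b, sheet)
  swapped <- sheet
  swapped$group[sheet$group == "NC"] <- "UC"
  swapped$group[sheet$group == "UC"] <- "NC"
  rec2 <- test_probes(b, swapped)
  expect_equal(rec2$delta_beta, -rec$delta_beta)
  expect_equal(rec2$p_value, rec$p_value, tolerance = 1e-12)
  expect_equal(sum(rec2$direction == "hyper"), sum(rec$direction == "hypo"))
  expect_equal(sum(rec2$direction == "hypo"), sum(rec$direction == "hyper"))
})

test_that("Mann-Whitney wrapper handles extremes, ties and the null", {
  # complete separation at n = 8 vs 3: U maximal, exact p = 2 / C(11,3)
  x <- 10 + 1:8; y <- 1:3
  mw <- mann_whitney(x, y)
  expect_equal(mw$U, 24)
  expect_equal(mw$p_value, 2 / choose(11, 3), tolerance = 1e-12)
  # a single shared constant -> p = 1
  expect_equal(mann_whitney(rep(1, 5), rep(1, 4))$p_value, 1)
  # null calibration: rejection rate near nominal
  set.seed(71)
  rej <- mean(replicate(200, mann_whitney(rnorm(30), rnorm(30),
                                          exact = FALSE)$p_value < 0.05))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("global_compare reports per-direction shifts and empty sets", {
  rec <- data.frame(probe_id = paste0("cg", 1:6),
                    mean_nc = c(0.1, 0.15, 0.2, 0.1, 0.1, 0.1),
                    mean_uc = c(0.5, 0.55, 0.6, 0.12, 0.11, 0.09),
                    direction = c("hyper", "hyper", "hyper",
                                  "null", "null", "null"))
  gc <- global_compare(rec)
  expect_equal(gc$n_probes, c(3L, 0L))
  expect_false(gc$undefined[1])
  expect_true(gc$undefined[2])
  expect_true(is.na(gc$p_value[2]))
})

test_that("the funnel composes stages with consistent monotone counts", {
  sim <- small_sim(seed = 7, n_probes = 4000, n_planted_hyper = 60,
                   n_planted_hypo = 10)
  det <- detection_pvalues(sim$signals)
  prep <- preprocess_signals(sim$signals, sim$manifest, bmiq = TRUE,
                             bmiq_seed = 7)
  fun <- funnel(prep$betas, sim$sample_sheet, manifest = sim$manifest,
                detection = det)
  rep <- fun$report
  expect_gte(rep$n_total, rep$n_qc)
  expect_gte(rep$n_qc, rep$n_dmc)
  expect_equal(rep$n_dmc, rep$n_hyper + rep$n_hypo)
  expect_gte(rep$n_hyper, rep$n_hyper_fold)
  expect_gte(rep$n_hyper_fold, rep$n_hyper_promoter_island)
  expect_equal(rep$n_hyper, length(fun$hyper))
  expect_equal(rep$n_hyper_fold, length(fun$fold_survivors))
  expect_true(all(fun$promoter_island %in% fun$fold_survivors))
  expect_true(all(fun$fold_survivors %in% fun$hyper))
  sens <- mean(sim$truth$probe_id[sim$truth$direction == "hyper"] %in%
                 fun$hyper)
  expect_gte(sens, 0.9)
})
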