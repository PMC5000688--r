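test_that("MSP frequencies are exact percentages, order-invariant", {
  msp <- uc_msp_template()
  fr <- msp_frequency(msp)
  uc <- fr[fr$group == "UC", ]
  expect_equal(uc$percent[uc$gene == "KIAA1614"], 91.1)  # 72 of 79
  expect_equal(uc$percent[uc$gene == "RIBC2"], 64.6)     # 51 of 79
  expect_equal(uc$percent[uc$gene == "FAM217B"], 62.0)   # 49 of 79
  fr2 <- msp_frequency(msp[sample(nrow(msp)), ])
  expect_equal(fr, fr2, ignore_attr = TRUE)
  # methylated + unmethylated shares always total 100
  expect_true(all(abs(fr$percent + 100 * (fr$n_total - fr$n_meth) /
                        fr$n_total - 100) < 0.051))
  zero <- data.frame(sample_id = paste0("s", 1:8), group = "NC",
                     gene = "g", call = "unmethylated")
  expect_equal(msp_frequency(zero)$percent, 0)
  expect_error(msp_frequency(zero[0, ]), "empty")
  dup <- rbind(zero, zero[1, ])
  expect_error(msp_frequency(dup), "duplicate")
})

test_that("clone summaries match their matrix definitions", {
  ones <- matrix(1, 5, 10)
  cs <- clone_summary(ones)
  expect_equal(cs$density, 1)
  expect_true(all(cs$per_cpg == 1))
  expect_equal(cs$grid, rep(strrep("*", 10), 5))

  checker <- rbind(c(1, 0), c(0, 1))
  expect_equal(clone_summary(checker)$density, 0.5)
  expect_equal(clone_summary(checker)$grid, c("*o", "o*"))

  m <- simulate_clone_matrix(8, 12, 0.6, 4)
  cs2 <- clone_summary(m)
  expect_equal(cs2$density, mean(cs2$per_cpg))
})

test_that("qMSP inverts the Ct generator exactly at zero noise", {
  sheet <- data.frame(sample_id = c("IVD", "u1", "u2", "n1"),
                      group = c("POS", "UC", "UC", "NC"))
  q <- cbind(target = c(1, 0.6, 0.15, 0.02), Alu = c(1, 1, 1, 1))
  ct <- simulate_ct_table(sheet, c("GENE", "Alu"), q, noise_sd = 0, seed = 2)
  res <- qmsp_relative(ct, "GENE", normalizer = "Alu", calibrator = "IVD")
  expect_equal(res$rel_level[match(sheet$sample_id, res$sample_id)],
               q[, "target"], tolerance = 1e-12, ignore_attr = TRUE)
  # dCt two cycles above the calibrator -> level 0.25
  ct2 <- data.frame(sample_id = rep(c("IVD", "s"), each = 2),
                    target = rep(c("GENE", "Alu"), 2),
                    replicate = 1, ct = c(24, 24, 26, 24))
  res2 <- qmsp_relative(ct2, "GENE", calibrator = "IVD")
  expect_equal(res2$rel_level[res2$sample_id == "IVD"], 1)
  expect_equal(res2$rel_level[res2$sample_id == "s"], 0.25)
  # missing normalizer -> sample skipped with a warning; H2O never quantified
  ct3 <- rbind(ct2, data.frame(sample_id = c("x", "H2O", "H2O"),
                               target = c("GENE", "GENE", "Alu"),
                               replicate = 1, ct = c(30, 38, 38)))
  expect_warning(res3 <- qmsp_relative(ct3, "GENE", calibrator = "IVD"),
                 "skipped")
  expect_false("x" %in% res3$sample_id)
  expect_false("H2O" %in% res3$sample_id)
})

test_that("delta-delta-Ct expression recovers planted fold changes", {
  # all identical -> every level 1
  ct0 <- data.frame(sample_id = rep(c("a", "b"), each = 2),
                    group = rep(c("NC", "NC"), each = 2),
                    target = rep(c("GENE", "ACTB"), 2),
                    replicate = 1, ct = c(25, 20, 25, 20))
  r0 <- ddct_expression(ct0, "GENE", "ACTB", "NC")
  expect_true(all(r0$samples$rel_expr == 1))

  # 2 cycles higher target in UC with equal housekeeping -> 0.25x
  sheet <- data.frame(sample_id = c("n1", "n2", "u1", "u2"),
                      group = c("NC", "NC", "UC", "UC"))
  q <- cbind(g = c(1, 1, 0.25, 0.25), hk = 1)
  ct <- simulate_ct_table(sheet, c("GENE", "ACTB"), q, noise_sd = 0, seed = 3)
  r <- ddct_expression(ct, "GENE", "ACTB", "NC")
  expect_equal(r$groups$mean[r$groups$group == "UC"], 0.25, tolerance = 1e-12)
  expect_equal(r$groups$mean[r$groups$group == "NC"], 1, tolerance = 1e-12)

  # planted 4-fold silencing recovered within the noise band
  set.seed(9)
  n <- 20
  sheet2 <- data.frame(sample_id = sprintf("s%02d", 1:n),
                       group = rep(c("NC", "UC"), each = n / 2))
  q2 <- cbind(g = ifelse(sheet2$group == "UC", 0.25, 1), hk = 1)
  ct2 <- simulate_ct_table(sheet2, c("GENE", "ACTB"), q2, noise_sd = 0.1,
                           seed = 9)
  r2 <- ddct_expression(ct2, "GENE", "ACTB", "NC")
  expect_lt(abs(r2$groups$mean[r2$groups$group == "UC"] - 0.25), 0.05)
})

test_that("candidate filter applies all three gates with diagnostics", {
  msp <- rbind(
    data.frame(gene = "GOOD", group = c("NC", "UC"), n_meth = c(0, 72),
               n_total = c(8, 79), percent = c(0, 91.1)),
    data.frame(gene = "NCMETH", group = c("NC", "UC"), n_meth = c(6, 60),
               n_total = c(8, 79), percent = c(75, 75.9)),
    data.frame(gene = "SILENT", group = c("NC", "UC"), n_meth = c(0, 60),
               n_total = c(8, 79), percent = c(0, 75.9)))
  expr <- c(GOOD = TRUE, NCMETH = TRUE, SILENT = FALSE)
  out <- candidate_filter(msp, expr)
  expect_true(out$pass[out$gene == "GOOD"])
  expect_false(out$pass[out$gene == "NCMETH"])
  expect_false(out$gate_nc_meth[out$gene == "NCMETH"])   # gate (ii) named
  expect_false(out$pass[out$gene == "SILENT"])
  expect_false(out$gate_expression[out$gene == "SILENT"])  # gate (i) named
  expect_true(out$gate_nc_meth[out$gene == "SILENT"])
  # tightening a threshold never adds a gene
  tighter <- candidate_filter(msp, expr, uc_min_pct = 80)
  expect_true(all(tighter$pass <= out$pass))
  # absent gene -> excluded with warning
  expect_warning(out2 <- candidate_filter(msp, expr[c("GOOD", "NCMETH")]),
                 "SILENT")
  expect_false("SILENT" %in% out2$gene)
})

test_that("group comparison reports mean/SD and the pooled t", {
  gc <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(gc$p_value, 1)
  expect_equal(gc$summary$sd, c(1, 1))
  expect_false(gc$degenerate)

  gd <- group_compare(c(0, 0, 0, 0, 1, 1, 1, 1), rep(c("a", "b"), each = 4))
  expect_true(gd$degenerate)
  expect_lt(gd$p_value, 1e-12)

  set.seed(77)
  for (i in 1:200) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- c(rnorm(n1), rnorm(n2, 1))
    g <- rep(c("a", "b"), c(n1, n2))
    got <- group_compare(v, g)
    orc <- pooled_t_oracle(v[g == "a"], v[g == "b"])
    expect_equal(got$p_value, orc$p, tolerance = 1e-10)
  }
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b")), ">= 2 values")
})

test_that("cohort summary reproduces published-style percentages", {
  sheet <- uc_cohort_template()
  cs <- summarize_cohort(sheet)
  tab <- cs$table
  pick <- function(f, c) tab$percent[tab$field == f & tab$category == c]
  expect_equal(pick("sex", "male"), 60.8)
  expect_equal(pick("lesion_location", "left_sided"), 31.6)
  expect_equal(pick("lesion_location", "proctitis"), 55.7)
  expect_equal(pick("clinical_type", "chronic_relapsing"), 44.3)
  expect_equal(pick("mayo_class", "moderate"), 55.7)
  expect_equal(cs$n_total, 79)
  expect_equal(round(cs$age$mean, 1), 42.4)
  expect_equal(c(cs$age$min, cs$age$max), c(16, 68))

  single <- summarize_cohort(sheet[1, ])
  expect_true(all(single$table$percent == 100))

  odd <- sheet
  odd$sex[1] <- "unknown"
  expect_warning(cs2 <- summarize_cohort(odd, vocab = list(
    sex = c("male", "female"))), "other")
  expect_true("other" %in% cs2$table$category[cs2$table$field == "sex"])
})
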