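test_that("island caller handles closed-form and degenerate sequences", {
  cg <- paste(rep("CG", 100), collapse = "")
  isl <- find_cpg_islands(cg)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 0)
  expect_equal(isl$end, 200)
  expect_equal(isl$gc_fraction, 1)
  expect_equal(isl$obs_exp, 2)  # (100 CpG * 200) / (100 C * 100 G)

  expect_equal(nrow(find_cpg_islands(paste(rep("AT", 250), collapse = ""))), 0)
  expect_equal(nrow(find_cpg_islands("ACGT")), 0)  # shorter than min_len
  # N disqualifies windows
  withN <- paste0(substr(cg, 1, 100), "N", substr(cg, 102, 200))
  expect_equal(nrow(find_cpg_islands(withN)), 0)
  expect_error(find_cpg_islands(paste0(strrep("A", 300), "X")), "outside")
})

test_that("island caller equals the brute-force oracle on a random corpus", {
  corpus <- island_corpus(150, seed = 314)
  for (s in corpus) {
    a <- find_cpg_islands(s)[, c("start", "end")]
    b <- oracle_islands(s)
    expect_equal(unname(as.matrix(a)), unname(as.matrix(b)))
  }
})

test_that("island relation follows the shore/shelf distance bands", {
  islands <- data.frame(seq_id = "chr1", start = 1000L, end = 1400L)
  mid <- 1200
  expect_equal(island_relation(mid + 1, islands), "island")   # 1-based
  expect_equal(island_relation(1400 + 1, islands), "shore")   # end + 1
  expect_equal(island_relation(1400 + 2000, islands), "shore")
  expect_equal(island_relation(1400 + 2001, islands), "shelf")
  expect_equal(island_relation(1400 + 4000, islands), "shelf")
  expect_equal(island_relation(1400 + 4001, islands), "open_sea")
  expect_equal(island_relation(1000, islands), "shore")       # start - 1
  expect_equal(island_relation(50000, islands[0, ]), "open_sea")
})

test_that("feature assignment applies promoter > exon > intron precedence", {
  gm <- data.frame(gene = "G1", seq_id = "chr1", strand = "+", tss = 10000L,
                   exons = "10000-10200,10800-11000,11500-11800")
  expect_equal(assign_feature(10001, gm), "promoter")  # at the TSS
  expect_equal(assign_feature(10000 - 1500 + 1, gm), "promoter")
  expect_equal(assign_feature(10000 - 1501, gm), "intergenic")
  expect_equal(assign_feature(10901, gm), "exon")      # exon 2, window passed
  expect_equal(assign_feature(11201, gm), "intron")
  expect_equal(assign_feature(50000, gm), "intergenic")
  # minus strand mirrors the promoter window
  gm2 <- data.frame(gene = "G2", seq_id = "chr1", strand = "-", tss = 10000L,
                    exons = "9000-10001")
  expect_equal(assign_feature(10000 + 1500, gm2), "promoter")
  expect_equal(assign_feature(10000 - 499, gm2), "promoter")
  expect_equal(assign_feature(10000 - 502, gm2), "exon")
  expect_error(assign_feature(1, gm[0, ]), "no annotation")
})

test_that("vectorized manifest annotation agrees with the scalar rules", {
  ann <- simulate_annotation(n_genes = 30, seed = 41)
  cfg <- sim_config(n_probes = 400, seed = 41)
  mf <- generate_manifest(cfg, ann$gene_models, ann$islands)
  idx <- seq(1, 400, by = 7)
  for (i in idx) {
    expect_equal(mf$feature[i], assign_feature(mf$position[i],
                                               ann$gene_models))
    expect_equal(mf$island_relation[i], island_relation(mf$position[i],
                                                        ann$islands))
  }
})

test_that("feature distribution conserves counts and ignores order", {
  probes <- data.frame(feature = rep("promoter", 10),
                       island_relation = rep("island", 10))
  tab <- feature_distribution(probes)
  expect_equal(sum(tab), 10)
  expect_equal(tab["promoter", "island"], 10)

  sim <- small_sim(seed = 23, n_probes = 500)
  t1 <- feature_distribution(sim$manifest)
  t2 <- feature_distribution(sim$manifest[sample(500), ])
  expect_equal(sum(t1), 500)
  expect_identical(t1, t2)
})

test_that("promoter-island selection is a pure annotation subset", {
  mf <- data.frame(probe_id = c("a", "b", "c", "d"),
                   feature = c("promoter", "promoter", "exon", "promoter"),
                   island_relation = c("island", "shore", "island", "island"))
  got <- select_promoter_island_probes(c("a", "b", "c"), mf)
  expect_equal(got, "a")
  expect_length(select_promoter_island_probes(character(0), mf), 0)
})
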