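test_that("background correction subtracts the negative-control mean, floored", {
  M <- matrix(c(500, 50), 2, 1, dimnames = list(c("a", "b"), "S1"))
  U <- matrix(c(300, 10), 2, 1, dimnames = list(c("a", "b"), "S1"))
  neg <- matrix(c(90, 100, 110), 3, 1, dimnames = list(NULL, "S1"))
  sig <- tiny_signals(M, U, neg)
  out <- background_correct(sig)
  expect_equal(out$M[, 1], c(a = 400, b = 0))
  expect_equal(out$U[, 1], c(a = 200, b = 0))
  expect_equal(out$negatives, neg)  # retained for detection

  zero <- tiny_signals(M, U, matrix(0, 3, 1, dimnames = list(NULL, "S1")))
  expect_equal(background_correct(zero)$M, M)
})

test_that("detection p-values follow the doubled-negative Gaussian model", {
  # negatives mean 100 sd 10 -> doubled: mu 200 sd 20
  neg <- matrix(c(90, 100, 110), 3, 1, dimnames = list(NULL, "S1"))
  M <- matrix(c(100, 120, 1e6), 3, 1,
              dimnames = list(c("a", "b", "c"), "S1"))
  U <- matrix(c(100, 120, 1e6), 3, 1,
              dimnames = list(c("a", "b", "c"), "S1"))
  sig <- tiny_signals(M, U, neg)
  p <- detection_pvalues(sig)
  expect_equal(p["a", 1], 0.5)                  # at the background mean
  expect_equal(p["b", 1], 1 - pnorm(2), tolerance = 1e-12)
  expect_lt(p["c", 1], 1e-12)                   # far above background
  # monotone decreasing in total signal
  tot <- seq(0, 1000, by = 50)
  sig2 <- tiny_signals(matrix(tot, dimnames = list(NULL, "S1")),
                       matrix(0 * tot, dimnames = list(NULL, "S1")), neg)
  expect_true(all(diff(detection_pvalues(sig2)[, 1]) <= 0))

  degen <- tiny_signals(M, U, matrix(100, 3, 1, dimnames = list(NULL, "S1")))
  expect_error(detection_pvalues(degen), "degenerate controls")
  one <- tiny_signals(M, U, matrix(100, 1, 1, dimnames = list(NULL, "S1")))
  expect_error(detection_pvalues(one), ">= 2")
})

test_that("QC drops failing probes and low-call-rate samples", {
  d <- matrix(0, 4, 3, dimnames = list(paste0("cg", 1:4), paste0("S", 1:3)))
  qc <- qc_samples_and_probes(d)
  expect_equal(qc$kept_samples, paste0("S", 1:3))
  expect_equal(qc$kept_probes, paste0("cg", 1:4))

  d2 <- d
  d2["cg2", "S3"] <- 0.2
  qc2 <- qc_samples_and_probes(d2, call_rate_min = 0)
  expect_false("cg2" %in% qc2$kept_probes)
  expect_equal(length(qc2$kept_probes), 3)

  # one sample below the call-rate floor is dropped, rescuing its probes
  d3 <- matrix(0, 100, 3, dimnames = list(sprintf("cg%03d", 1:100),
                                          paste0("S", 1:3)))
  d3[1:50, "S2"] <- 0.5
  qc3 <- qc_samples_and_probes(d3, call_rate_min = 0.99)
  expect_equal(qc3$kept_samples, c("S1", "S3"))
  expect_equal(length(qc3$kept_probes), 100)
  expect_error(qc_samples_and_probes(d3 * 0 + 1), "all samples dropped")
})

test_that("synthetic default retains nearly all probes through QC", {
  sim <- small_sim(seed = 7, n_probes = 20000, n_planted_hyper = 250,
                   n_planted_hypo = 20)
  det <- detection_pvalues(sim$signals)
  qc <- qc_samples_and_probes(det)
  expect_gte(length(qc$kept_probes) / 20000, 0.98)
  expect_equal(length(qc$kept_samples), ncol(sim$signals$M))
})

test_that("dye equalization matches medians and is order-invariant", {
  M <- matrix(c(100, 200, 300, 200, 400, 600), 3, 2,
              dimnames = list(letters[1:3], c("S1", "S2")))
  U <- M
  neg <- matrix(10, 2, 2, dimnames = list(NULL, c("S1", "S2")))
  de <- dye_equalize(tiny_signals(M, U, neg))
  expect_equal(unname(de$scale_factors), c(1.5, 0.75))
  med <- apply(de$signals$M + de$signals$U, 2, median)
  expect_equal(unname(med[1]), unname(med[2]))

  same <- dye_equalize(tiny_signals(M[, c(1, 1)], U[, c(1, 1)], neg))
  expect_equal(unname(same$scale_factors), c(1, 1))

  perm <- dye_equalize(tiny_signals(M[3:1, ], U[3:1, ], neg))
  expect_equal(unname(perm$scale_factors), unname(de$scale_factors))
})

test_that("beta computation uses the offset-stabilized ratio", {
  expect_equal(compute_beta(0, 0), 0)
  expect_equal(compute_beta(900, 0, offset = 100), 0.9)
  expect_equal(compute_beta(300, 100, offset = 100), 0.6)
  expect_error(compute_beta(-1, 5), "negative")
})
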