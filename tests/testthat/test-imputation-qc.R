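test_that("per-variant accuracy matches Pearson identities", {
  truth <- cbind(c(0, 1, 2, 1, 0), c(2, 2, 2, 2, 2), c(0, 2, 1, 0, 2))
  imputed <- cbind(truth[, 1], truth[, 2], 2 - truth[, 3])
  tr <- per_variant_accuracy(imputed, truth)
  expect_equal(tr$r[1], 1)
  expect_true(is.na(tr$r[2]))  # monomorphic called site
  expect_equal(tr$r[3], -1)
  expect_equal(tr$n, rep(5L, 3))
  expect_error(per_variant_accuracy(imputed[, 1:2], truth), "dimensions")
  # affine rescaling of imputed dosages leaves accuracy unchanged
  tr2 <- per_variant_accuracy(0.25 * imputed + 0.7, truth)
  expect_equal(tr2$r, tr$r)
})

test_that("MAF filtering is strictly greater-than", {
  track <- data.frame(contig = "c", position = 1:3,
                      maf = c(0.05, 0.051, 0.3), r = 0.9, n = 10)
  out <- maf_filter(track, 0.05)
  expect_equal(out$position, c(2L, 3L))
  pan <- simulate_genotype_panel(n = 20, m = 10,
                                 maf_dist = c(rep(0.05, 4), rep(0.2, 6)),
                                 seed = 701)
  pf <- maf_filter(pan, 0.05)
  expect_equal(pf$m, 6)
  expect_equal(ncol(pf$true), 6)
})

test_that("MAF bins report means with empty bins left empty", {
  track <- data.frame(contig = "c", position = 1:6,
                      maf = c(0.06, 0.07, 0.3, 0.3, 0.45, 0.45),
                      r = c(0.5, 0.7, 0.8, NA, 0.9, 1.0), n = 10)
  b <- bin_by_maf(track, edges = c(0.05, 0.1, 0.2, 0.4, 0.5))
  expect_equal(b$n, c(2L, 0L, 1L, 2L))
  expect_equal(b$mean_r[1], 0.6)
  expect_true(is.na(b$mean_r[2]))     # empty, not zero
  expect_equal(b$mean_r[3], 0.8)      # NA accuracy excluded
  expect_equal(b$mean_r[4], 0.95)
  # single bin over everything equals the overall mean of defined r
  all1 <- bin_by_maf(track, edges = c(0, 0.5))
  expect_equal(all1$mean_r, mean(track$r, na.rm = TRUE))
})

test_that("imputation accuracy rises with MAF on the synthetic generator", {
  pan <- simulate_genotype_panel(n = 250, m = 600, seed = 702)
  imp <- corrupt_to_imputed(pan, base_error = 0.08, maf_error_slope = 3,
                            seed = 703)
  tr <- per_variant_accuracy(imp, pan)
  b <- bin_by_maf(tr, edges = c(0.05, 0.14, 0.23, 0.32, 0.41, 0.5))
  expect_true(all(diff(b$mean_r) > 0))
})

test_that("gap detection equals the successive-difference oracle", {
  set.seed(704)
  pos <- sort(sample.int(5e6, 400))
  track <- data.frame(contig = "c1", position = pos)
  for (mg in c(2e4, 5e4, 2e5)) {
    got <- detect_gaps(track, min_gap = mg)
    want <- oracle_gaps(pos, mg)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$span_bp, want$span)
  }
  # min_gap beyond the span -> nothing
  expect_equal(nrow(detect_gaps(track, min_gap = 6e6)), 0)
  expect_error(detect_gaps(data.frame(contig = "c", position = c(5, 1)),
                           min_gap = 2), "sorted")
})

test_that("low-accuracy windows are flagged and merged", {
  # uniformly accurate track: no flags
  good <- data.frame(contig = "c", position = seq(1e4, 2e6, by = 1e4),
                     maf = 0.3, r = 0.95, n = 50)
  expect_equal(nrow(flag_low_accuracy_runs(good)), 0)
  # two adjacent bad windows merge into one region
  bad <- good
  bad$r[bad$position >= 8e5 & bad$position < 1.3e6] <- 0.05
  fl <- flag_low_accuracy_runs(bad)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$kind, "low_accuracy_run")
  expect_lte(fl$start, 8e5)
  expect_gte(fl$end, 1.3e6)
  expect_lt(fl$mean_r, 0.3)
})
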