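test_that("the GRM is symmetric, unit-diagonal on average, and flags twins", {
  pan <- simulate_genotype_panel(n = 150, m = 600, seed = 801)
  X <- pan$true
  X[2, ] <- X[1, ]  # duplicate individuals
  G <- build_grm(X)
  expect_equal(G, t(G))
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
  expect_equal(G[1, 2], (G[1, 1] + G[2, 2]) / 2, tolerance = 1e-12)
  expect_error(build_grm(matrix(2, 10, 5)), "monomorphic")
})

test_that("null REML recovers heritability and detects pure noise", {
  h2hat <- nulls <- numeric(5)
  for (r in 1:5) {
    s <- child_seed(802, r)
    pan <- simulate_genotype_panel(n = 300, m = 800, seed = s)
    G <- build_grm(pan)
    y <- simulate_phenotypes(pan, h2 = 0.5, seed = child_seed(s, "y"))
    h2hat[r] <- fit_null(y, G)$h2
    y0 <- herdqc:::with_seed(child_seed(s, "n"), rnorm(300))
    nulls[r] <- fit_null(y0, G)$h2
  }
  expect_lt(abs(median(h2hat) - 0.5), 0.15)
  expect_lt(median(nulls), 0.1)
})

test_that("missing phenotypes are dropped listwise", {
  pan <- simulate_genotype_panel(n = 100, m = 300, seed = 803)
  G <- build_grm(pan)
  y <- simulate_phenotypes(pan, h2 = 0.5, seed = 804)
  y2 <- as.numeric(y); y2[c(3, 50)] <- NA
  nf <- fit_null(y2, G)
  expect_equal(nf$n, 98)
  expect_equal(nf$kept, setdiff(1:100, c(3, 50)))
  sc <- gwas_scan(y2, pan, nf)
  expect_equal(nrow(sc), 300)
})

test_that("with an identity GRM the scan reduces to simple regression", {
  set.seed(805)
  n <- 120
  x <- rbinom(n, 2, 0.35)
  y <- 0.4 * x + rnorm(n)
  nf <- fit_null(y, diag(n))
  sc <- gwas_scan(y, matrix(x, ncol = 1), nf)
  ols <- summary(lm(y ~ x))$coefficients
  expect_equal(sc$effect, ols[2, 1], tolerance = 1e-8)
  # monomorphic marker yields an NA row
  sc2 <- gwas_scan(y, cbind(x, rep(2, n)), nf)
  expect_true(is.na(sc2$effect[2]))
  expect_false(is.na(sc2$effect[1]))
})

test_that("spectral-cached GLS agrees with the dense oracle", {
  pan <- simulate_genotype_panel(n = 150, m = 400, seed = 806)
  G <- build_grm(pan)
  y <- simulate_phenotypes(pan, h2 = 0.6, seed = 807)
  nf <- fit_null(y, G)
  sc <- gwas_scan(y, pan, nf)
  for (j in c(1, 57, 200, 400)) {
    o <- oracle_gls(as.numeric(y), pan$true[, j], G, nf$sigma_g2,
                    nf$sigma_e2)
    expect_equal(sc$effect[j], o$effect, tolerance = 1e-8)
    expect_equal(sc$se[j], o$se, tolerance = 1e-8)
  }
})

test_that("the scan is equivariant under phenotype shift and scale", {
  pan <- simulate_genotype_panel(n = 120, m = 200, seed = 808)
  G <- build_grm(pan)
  y <- as.numeric(simulate_phenotypes(pan, h2 = 0.5, seed = 809))
  sc1 <- gwas_scan(y, pan, fit_null(y, G))
  y2 <- 3 * y + 10
  sc2 <- gwas_scan(y2, pan, fit_null(y2, G))
  expect_equal(sc2$logp, sc1$logp, tolerance = 1e-6)
  expect_equal(sc2$effect, 3 * sc1$effect, tolerance = 1e-6)
})

test_that("region report finds peaks and planted discontinuities", {
  res <- data.frame(contig = "c", position = seq(1e5, 5e6, by = 1e5),
                    logp = 1 + seq(0.02, 1, by = 0.02))
  class(res) <- c("gwas_result", "data.frame")
  rr <- region_report(res, window = 2e6, drop_threshold = 2)
  expect_equal(rr$peaks$position, 5e6)  # argmax of -log10 p
  expect_equal(nrow(rr$discontinuities), 0)  # monotone: no discontinuity
  # a signal cliff beside the peak is reported and cross-referenced
  res2 <- res
  res2$logp <- c(rep(1, 20), 6, 7, 8, rep(0.5, 27))
  rr2 <- region_report(res2, window = 2e6, drop_threshold = 2,
                       flags = data.frame(contig = "c", start = 2.25e6,
                                          end = 2.6e6))
  expect_equal(nrow(rr2$discontinuities), 1)
  expect_equal(rr2$discontinuities$start, 2.3e6)
  expect_equal(rr2$discontinuities$end, 2.4e6)
  expect_true(rr2$discontinuities$overlaps_flag)
})
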