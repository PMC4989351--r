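test_that("reference generation renders half-open gaps as N runs", {
  gaps <- data.frame(contig = "chr1", start = 4000, end = 5000)
  ref <- make_reference(1, 20000, gap_spec = gaps, seed = 3)
  chars <- strsplit(ref$contigs[["chr1"]], "")[[1]]
  expect_equal(sum(chars == "N"), 1000)
  expect_true(all(chars[4001:5000] == "N"))
  expect_false(chars[4000] == "N")
  expect_false(chars[5001] == "N")
  # byte-identical regeneration
  expect_identical(ref$contigs,
                   make_reference(1, 20000, gap_spec = gaps, seed = 3)$contigs)
})

test_that("planted variants are consistent with the edited haplotypes", {
  ref <- make_reference(1, 50000, seed = 21)
  don <- plant_variants(ref, n_snp = 40, n_indel = 10, seed = 22)
  tr <- don$truth
  expect_equal(nrow(tr), 50)
  expect_setequal(unique(tr$CLASS), c("SNP", "indel"))
  expect_equal(sum(tr$CLASS == "SNP"), 40)
  # hom variants must be on both haplotypes, het on exactly one
  expect_true(all(tr$HAP[tr$GT == "hom"] == 0))
  expect_true(all(tr$HAP[tr$GT == "het"] %in% 1:2))
  # net length change of each haplotype equals the sum of its indel deltas
  delta <- nchar(tr$ALT) - nchar(tr$REF)
  on_h1 <- tr$GT == "hom" | tr$HAP == 1
  on_h2 <- tr$GT == "hom" | tr$HAP == 2
  expect_equal(nchar(don$hap1[["chr1"]]) - 50000, sum(delta[on_h1]))
  expect_equal(nchar(don$hap2[["chr1"]]) - 50000, sum(delta[on_h2]))
  # REF alleles match the reference sequence at their positions
  for (i in seq_len(nrow(tr)))
    expect_equal(substr(ref$contigs[["chr1"]], tr$POS[i],
                        tr$POS[i] + nchar(tr$REF[i]) - 1), tr$REF[i])
})

test_that("simulated read pairs have the documented geometry", {
  ref <- make_reference(1, 30000, seed = 31)
  cfg <- read_sim_config(depth = 5, seed = 32)
  rds <- simulate_reads(ref, cfg)
  # pair count gives depth * L / (2 * read_length)
  expect_equal(length(rds), round(5 * 30000 / 200))
  expect_true(all(nchar(rds$seq1) == 100))
  expect_true(all(nchar(rds$seq2) == 100))
  # names are an audit trail: mate1 is the fragment prefix, mate2 the
  # reverse complement of the fragment suffix
  meta <- regmatches(rds$id,
                     regexec("src=(.+)\\|start=(\\d+)\\|flen=(\\d+)", rds$id))
  start <- as.integer(vapply(meta, `[`, "", 3))
  flen <- as.integer(vapply(meta, `[`, "", 4))
  expect_true(all(flen >= 200 & flen <= 500))
  expect_equal(mean(flen), 350, tolerance = 0.02)
  i <- which.max(start)
  frag <- substr(ref$contigs[["chr1"]], start[i], start[i] + flen[i] - 1)
  expect_equal(rds$seq1[i], substr(frag, 1, 100))
  expect_equal(revcomp(rds$seq2[i]), substr(frag, flen[i] - 99, flen[i]))
})

test_that("clustered coverage bias leaves more genome uncovered than Poisson", {
  ref <- make_reference(1, 100000, seed = 41)
  rp <- simulate_reads(ref, read_sim_config(depth = 4, bias = "poisson",
                                            seed = 42))
  rc <- simulate_reads(ref, read_sim_config(depth = 4, bias = "clustered",
                                            seed = 42))
  unc <- function(rds) {
    1 - breadth_of_coverage(align_reads(rds, ref), ref)$breadth
  }
  u_pois <- unc(rp); u_clus <- unc(rc)
  expect_gt(u_clus, u_pois)
  # Poisson uncovered fraction tracks exp(-depth) within a 3-sigma band
  # whose effective sample size accounts for read-length correlation
  n_eff <- 100000 / 200
  p0 <- poisson_uncovered(4)
  expect_lt(abs(u_pois - p0), 3 * sqrt(p0 * (1 - p0) / n_eff))
})

test_that("genotype panel matches drawn MAFs and decaying LD", {
  pan <- simulate_genotype_panel(n = 10000, m = 60, maf_dist = rep(0.5, 60),
                                 seed = 51)
  # MAF fixed at 0.5: mean dosage 1.0 within binomial s.e.
  expect_lt(abs(mean(pan$true) - 1), 0.015)
  pan2 <- simulate_genotype_panel(n = 400, m = 200, ld_decay = 50000,
                                  chrom_length = 2e6, seed = 52)
  d <- diff(pan2$map$pos)
  r <- vapply(seq_len(199), function(j) {
    if (sd(pan2$true[, j]) == 0 || sd(pan2$true[, j + 1]) == 0) NA_real_
    else cor(pan2$true[, j], pan2$true[, j + 1])
  }, 0)
  # with ~10 kb mean spacing both bins are populated with high probability
  near <- d < 5000; far <- d > 30000
  expect_gt(sum(near), 0)
  expect_gt(sum(far), 0)
  expect_gt(mean(r[near], na.rm = TRUE), mean(r[far], na.rm = TRUE))
})

test_that("corrupting with zero error reproduces the truth exactly", {
  pan <- simulate_genotype_panel(n = 50, m = 80, seed = 61)
  imp <- corrupt_to_imputed(pan, base_error = 0, seed = 62)
  expect_identical(imp$imputed, pan$true)
})

test_that("raw-effect phenotypes at full heritability are exactly linear", {
  pan <- simulate_genotype_panel(n = 40, m = 30, seed = 71)
  y <- simulate_phenotypes(pan, qtl_index = c(5, 12),
                           qtl_effect = c(1.5, -0.5), h2 = 1, seed = 72)
  expect_equal(as.numeric(y),
               as.vector(pan$true[, c(5, 12)] %*% c(1.5, -0.5)))
})

test_that("misassembly modes edit the recorded region", {
  ref <- make_reference(1, 40000, seed = 81)
  del <- make_misassembled_reference(ref, "chr1", 10000, 15000, "delete")
  expect_equal(nchar(del$contigs[["chr1"]]), 35000)
  expect_equal(del$misassembly$mode, "delete")
  inv <- make_misassembled_reference(ref, "chr1", 10000, 15000, "invert")
  expect_equal(substr(inv$contigs[["chr1"]], 10001, 15000),
               revcomp(substr(ref$contigs[["chr1"]], 10001, 15000)))
  shf <- make_misassembled_reference(ref, "chr1", 10000, 15000,
                                     "shuffle_blocks", block_size = 1000,
                                     seed = 82)
  expect_equal(nchar(shf$contigs[["chr1"]]), 40000)
  expect_false(shf$contigs[["chr1"]] == ref$contigs[["chr1"]])
  # outside the region the sequence is untouched
  expect_equal(substr(shf$contigs[["chr1"]], 1, 10000),
               substr(ref$contigs[["chr1"]], 1, 10000))
  expect_equal(substr(shf$contigs[["chr1"]], 15001, 40000),
               substr(ref$contigs[["chr1"]], 15001, 40000))
  # gap overlap is refused
  gr <- make_reference(1, 40000,
                       gap_spec = data.frame(contig = "chr1", start = 12000,
                                             end = 12500), seed = 83)
  expect_error(make_misassembled_reference(gr, "chr1", 10000, 15000,
                                           "delete"), "gap")
})

test_that("contaminant mixing is lossless and labelled", {
  host <- make_reference(1, 20000, seed = 91)
  hreads <- simulate_reads(host, read_sim_config(depth = 2, seed = 92))
  cont <- list(bug = setNames(herdqc:::with_seed(93, random_dna(5000)),
                              "bug1"))
  mx <- mix_contaminants(hreads, cont, c(bug = 0.1),
                         read_sim_config(depth = 1, seed = 94))
  expect_equal(length(mx$reads), nrow(mx$labels))
  expect_setequal(unique(mx$labels$source), c("host", "bug"))
  expect_equal(sum(mx$labels$source == "host"), length(hreads))
  frac <- mean(mx$labels$source == "bug")
  expect_gt(frac, 0.05); expect_lt(frac, 0.15)
})
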