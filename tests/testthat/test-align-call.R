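test_that("perfect, mismatched and over-mismatched reads place correctly", {
  set.seed(301)
  ref <- reference_genome(setNames(random_dna(5000), "c1"))
  s <- 1201
  rd <- substr(ref$contigs[["c1"]], s, s + 99)
  mm2 <- rd; substr(mm2, 10, 10) <- "N"; substr(mm2, 60, 60) <- "N"
  mm3 <- mm2; substr(mm3, 80, 80) <- "N"
  rp <- read_pairs(id = c("perfect", "mm"),
                   seq1 = c(rd, mm2), seq2 = c(revcomp(rd), mm3))
  aln <- align_reads(rp, ref)
  a <- aln$alignments
  p1 <- a[a$qname == "perfect" & a$mate == 1, ]
  expect_equal(p1$status, "mapped")
  expect_equal(p1$start, s)
  expect_equal(p1$strand, "+")
  expect_equal(p1$nm, 0L)
  expect_true(p1$perfect)
  # the same sequence given reverse-complemented maps at s on the - strand
  p2 <- a[a$qname == "perfect" & a$mate == 2, ]
  expect_equal(p2$start, s)
  expect_equal(p2$strand, "-")
  # two mismatches pass, three fail
  m1 <- a[a$qname == "mm" & a$mate == 1, ]
  expect_equal(m1$status, "mapped")
  expect_equal(m1$nm, 2L)
  m2 <- a[a$qname == "mm" & a$mate == 2, ]
  expect_equal(m2$status, "unmapped")
})

test_that("repeat placements are counted and capped at 100", {
  set.seed(302)
  unit <- random_dna(100)
  few <- reference_genome(setNames(paste(rep(unit, 7), collapse = ""), "r"))
  many <- reference_genome(setNames(paste(rep(unit, 120), collapse = ""),
                                    "r"))
  rp <- read_pairs(id = "u", seq1 = unit, seq2 = revcomp(unit))
  a1 <- align_reads(rp, few)$alignments
  expect_equal(a1$status[1], "mapped")
  expect_equal(a1$multiplicity[1], 7L)
  expect_equal(a1$start[1], 1L)  # tie broken leftmost
  a2 <- align_reads(rp, many)$alignments
  expect_equal(a2$status[1], "multi")
})

test_that("reads spanning short indels place with a single gap", {
  set.seed(303)
  ref <- reference_genome(setNames(random_dna(4000), "c1"))
  sq <- ref$contigs[["c1"]]
  s <- 2001
  del_read <- paste0(substr(sq, s, s + 49), substr(sq, s + 53, s + 102))
  ins_read <- paste0(substr(sq, s, s + 49), "ACG", substr(sq, s + 50, s + 96))
  rp <- read_pairs(id = c("del", "ins"), seq1 = c(del_read, ins_read),
                   seq2 = c(revcomp(del_read), revcomp(ins_read)))
  a <- align_reads(rp, ref)$alignments
  d <- a[a$qname == "del" & a$mate == 1, ]
  expect_equal(d$status, "mapped")
  expect_equal(d$start, s)
  expect_equal(d$gap_len, -3L)
  expect_equal(d$nm, 3L)  # SAM NM: gap bases count, no mismatches here
  i <- a[a$qname == "ins" & a$mate == 1, ]
  expect_equal(i$status, "mapped")
  expect_equal(i$start, s)
  expect_equal(i$gap_len, 3L)
})

test_that("breadth of coverage equals the per-base counting oracle", {
  ref <- make_reference(1, 20000,
                        gap_spec = data.frame(contig = "chr1", start = 9000,
                                              end = 9800), seed = 311)
  rds <- simulate_reads(ref, read_sim_config(depth = 3, seed = 312))
  aln <- align_reads(rds, ref)
  b <- breadth_of_coverage(aln, ref)
  expect_equal(b$breadth, oracle_breadth(aln, ref))
  expect_equal(b$per_contig$denominator, 20000 - 800)
})

test_that("variant normalization left-aligns and trims anchored alleles", {
  sq <- "TTTTACACACGG"
  nv <- herdqc:::normalize_variant(sq, 8, "CAC", "C")
  expect_equal(nv$pos, 4)
  expect_equal(nv$ref, "TAC")
  expect_equal(nv$alt, "T")
  # SNPs are untouched
  nv2 <- herdqc:::normalize_variant(sq, 5, "A", "G")
  expect_equal(list(nv2$pos, nv2$ref, nv2$alt), list(5, "A", "G"))
})

test_that("caller genotypes and filters behave at designed sites", {
  set.seed(321)
  ref <- reference_genome(setNames(random_dna(1000), "c1"))
  sq <- ref$contigs[["c1"]]
  site <- 500
  altb <- setdiff(c("A", "C", "G", "T"), substr(sq, site, site))[1]
  alt_sq <- sq; substr(alt_sq, site, site) <- altb
  mk_pair <- function(src, fs, id) {
    frag <- substr(src, fs, fs + 149)
    read_pairs(id = id, seq1 = substr(frag, 1, 100),
               seq2 = revcomp(substr(frag, 51, 150)))
  }
  # 5 ref pairs + 5 alt pairs, fragments all covering the site from both
  # mates (fragment 150, site central) -> het with alt on both strands
  prs <- do.call(c, c(
    lapply(1:5, function(i) mk_pair(sq, site - 75 + i, paste0("r", i))),
    lapply(1:5, function(i) mk_pair(alt_sq, site - 75 - i, paste0("a", i)))))
  calls <- call_variants(align_reads(prs, ref), ref)
  hit <- calls[calls$POS == site, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$ALT, altb)
  expect_equal(hit$GT, "het")
  expect_equal(hit$FILTER, "PASS")
  # all-alt pairs -> hom call
  prs2 <- do.call(c, lapply(1:8, function(i)
    mk_pair(alt_sq, site - 75 - i, paste0("h", i))))
  calls2 <- call_variants(align_reads(prs2, ref), ref)
  hit2 <- calls2[calls2$POS == site, ]
  expect_equal(hit2$GT, "hom")
  # depth below the minimum is flagged low_depth regardless of balance
  # fragments whose site offset is below mate2's span, so each pair
  # contributes a single covering mate: total depth 3 < 4
  prs3 <- do.call(c, lapply(1:3, function(i)
    mk_pair(alt_sq, site - 10 * i, paste0("l", i))))
  calls3 <- call_variants(align_reads(prs3, ref), ref)
  hit3 <- calls3[calls3$POS == site, ]
  expect_equal(hit3$FILTER, "low_depth")
})

test_that("final call set enforces cross-sample support and bi-allelism", {
  t1 <- data.frame(CHROM = "c", POS = c(10, 20, 30), REF = c("A", "C", "G"),
                   ALT = c("T", "G", "A"), GT = "het", CLASS = "SNP",
                   FILTER = c("PASS", "PASS", "low_depth"))
  t2 <- data.frame(CHROM = "c", POS = c(10, 20, 40), REF = c("A", "C", "T"),
                   ALT = c("T", "A", "C"), GT = "het", CLASS = "SNP",
                   FILTER = "PASS")
  fin <- finalize_call_set(list(s1 = t1, s2 = t2), min_samples = 2)
  # POS 20 is multi-allelic across samples (G vs A) -> excluded entirely;
  # POS 30 is filtered; POS 40 is single-sample
  expect_equal(fin$POS, 10)
  expect_equal(fin$n_samples, 2L)
})

test_that("subsampling is deterministic, seeded and depth-proportional", {
  ref <- make_reference(1, 20000, seed = 331)
  rds <- simulate_reads(ref, read_sim_config(depth = 10, seed = 332))
  s1 <- subsample_reads(rds, 10, 2, replicate = 1, seed = 7)
  s1b <- subsample_reads(rds, 10, 2, replicate = 1, seed = 7)
  s2 <- subsample_reads(rds, 10, 2, replicate = 2, seed = 7)
  expect_identical(s1$id, s1b$id)
  expect_false(identical(s1$id, s2$id))
  expect_equal(length(s1) / length(rds), 0.2, tolerance = 0.1)
  expect_identical(subsample_reads(rds, 10, 10)$id, rds$id)
  expect_error(subsample_reads(rds, 10, 12), "exceeds")
})

test_that("recovery arithmetic counts intersections per class", {
  full <- data.frame(CHROM = "c", POS = c(1, 2, 3, 4),
                     REF = "A", ALT = "T",
                     GT = c("het", "het", "hom", "hom"),
                     CLASS = c("SNP", "indel", "SNP", "SNP"),
                     FILTER = "PASS")
  sub <- list(list(depth = 2, replicate = 1,
                   calls = data.frame(CHROM = "c", POS = c(1, 3, 4),
                                      REF = "A", ALT = "T",
                                      GT = c("het", "hom", "hom"),
                                      CLASS = "SNP", FILTER = "PASS")))
  rt <- recovery_curve(full, sub)
  expect_equal(rt$recovery[rt$class == "het_SNP"], 1)
  expect_equal(rt$recovery[rt$class == "het_indel"], 0)
  expect_equal(rt$recovery[rt$class == "hom_SNP"], 1)
})
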