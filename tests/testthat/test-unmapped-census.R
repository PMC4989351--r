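test_that("unmapped pool keeps whole pairs for half-mapped reads", {
  set.seed(501)
  ref <- reference_genome(setNames(random_dna(5000), "c1"))
  sq <- ref$contigs[["c1"]]
  foreign <- random_dna(100)
  rp <- read_pairs(
    id = c("both_ok", "half", "both_bad"),
    seq1 = c(substr(sq, 101, 200), substr(sq, 301, 400), foreign),
    seq2 = c(revcomp(substr(sq, 151, 250)), random_dna(100),
             random_dna(100)))
  aln <- align_reads(rp, ref)
  pool <- collect_unmapped(aln, rp)
  expect_setequal(pool$pool$id, c("half", "both_bad"))
  expect_equal(pool$n_both_unmapped, 1)
  expect_equal(pool$n_half_mapped, 1)
})

test_that("greedy assembly reconstructs a tiled sequence and keeps disjoint reads apart", {
  set.seed(502)
  plant <- random_dna(1500)
  starts <- seq(1, 1401, by = 25)
  reads <- substr(rep(plant, length(starts)), starts, starts + 99)
  ctg <- greedy_assemble(reads, min_overlap = 30)
  expect_length(ctg, 1)
  expect_true(ctg[[1]] == plant || revcomp(ctg[[1]]) == plant)
  # disjoint reads assemble into one contig each
  disj <- vapply(1:4, function(i) random_dna(80), "")
  ctg2 <- greedy_assemble(disj, min_overlap = 30, both_strands = FALSE)
  expect_length(ctg2, 4)
  expect_setequal(unname(ctg2), disj)
  # a read set given in reverse-complement orientation still assembles
  half_rc <- reads
  half_rc[seq(1, length(reads), 2)] <-
    revcomp(reads[seq(1, length(reads), 2)])
  ctg3 <- greedy_assemble(half_rc, min_overlap = 30)
  expect_length(ctg3, 1)
  expect_true(ctg3[[1]] == plant || revcomp(ctg3[[1]]) == plant)
})

test_that("contig length filter is strict for DNA and absent for RNA", {
  ctgs <- setNames(c(strrep("A", 501), strrep("C", 500), strrep("G", 120)),
                   c("a", "b", "c"))
  expect_equal(names(filter_contigs(ctgs, "DNA")), "a")
  expect_equal(names(filter_contigs(ctgs, "RNA")), c("a", "b", "c"))
})

test_that("best-hit parsing keeps one most-significant row per query", {
  hits <- data.frame(
    query = c("q1", "q1", "q1", "q2"),
    subject = c("s1", "s2", "s3", "s1"),
    identity = c(99, 98, 97, 90), length = c(300, 300, 300, 60),
    mismatches = 0, gaps = 0, qstart = 1, qend = 300, sstart = 1,
    send = 300, evalue = c(1e-50, 1e-80, 1e-80, 1e-10),
    bitscore = c(200, 500, 400, 90),
    species = c("cow", "worm", "worm", "microbe"), gi = c(1, 2, 3, 4))
  best <- parse_best_hits(hits)
  expect_equal(nrow(best), 2)
  # q1: lowest evalue is shared by s2/s3, higher bitscore wins
  expect_equal(best$subject[best$query == "q1"], "s2")
  # significance thresholds are strict
  sig_dna <- apply_significance(best, "DNA")
  expect_equal(sig_dna$query, "q1")
  hits201 <- data.frame(query = "q", subject = "s", identity = 99,
                        length = c(200, 201), mismatches = 0, gaps = 0,
                        qstart = 1, qend = 200, sstart = 1, send = 200,
                        evalue = c(1e-5, 1e-4), bitscore = c(100, 90),
                        species = "x", gi = 9)
  expect_equal(nrow(apply_significance(hits201, "DNA")), 1)
  expect_equal(nrow(apply_significance(hits201[hits201$length == 200, ],
                                       "RNA")), 1)
})

test_that("species summary orders by alignment count", {
  hits <- data.frame(query = paste0("q", 1:5),
                     subject = "s", identity = c(99, 98, 97, 96, 95),
                     length = 300, mismatches = 0, gaps = 0, qstart = 1,
                     qend = 300, sstart = 1, send = 300,
                     evalue = c(1e-30, 1e-20, 1e-10, 1e-40, 1e-5),
                     bitscore = 100,
                     species = c("worm", "worm", "worm", "cow", "cow"),
                     gi = 1:5)
  sm <- summarize_species(hits)
  expect_equal(sm$species, c("worm", "cow"))
  expect_equal(sm$n, c(3L, 2L))
  expect_equal(sm$max_identity, c(99, 96))
})

test_that("gene mapping buckets unresolved GIs and overlaps intersect", {
  hits <- data.frame(query = paste0("q", 1:4), gi = c(11, 12, 11, 99),
                     species = "x", length = 300, identity = 99,
                     evalue = 1e-20)
  lookup <- data.frame(gi = c(11, 12), symbol = c("ND5", "COX1"))
  gm <- map_genes(hits, lookup)
  expect_equal(gm$per_gene$symbol, c("ND5", "COX1"))
  expect_equal(gm$per_gene$n, c(2L, 1L))
  expect_equal(gm$unresolved, 1)
  ov <- gene_set_overlap(c("ND5", "COX1"), c("COX1", "CYTB"))
  expect_equal(ov$n_common, 1)
  expect_equal(ov$common, "COX1")
})

test_that("cross-overlap finds shared contigs by local alignment", {
  set.seed(503)
  shared <- random_dna(400)
  q <- c(q1 = shared, q2 = random_dna(400))
  s <- c(s1 = paste0(random_dna(100), shared, random_dna(100)))
  co <- cross_overlap(q, s, min_identity = 98, min_length = 100)
  expect_equal(co$n_overlapping, 1)
  expect_equal(co$fraction, 0.5)
  expect_equal(co$spanned_bases, 400)
})

test_that("N50 is base-weighted with a count-based alternative", {
  lens <- c(5, 4, 3, 2, 1)
  st <- contig_stats(lens)
  expect_equal(st$n50, 4)
  expect_equal(st$total_bp, 15)
  expect_equal(contig_stats(lens, count_based = TRUE)$n50, 3)
  expect_error(contig_stats(numeric()), "no contigs")
})
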