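test_that("reference genomes validate their interval annotations", {
  ctg <- setNames(c(strrep("A", 100), strrep("C", 50)), c("c1", "c2"))
  ref <- reference_genome(ctg)
  expect_equal(unname(contig_lengths(ref)), c(100, 50))
  expect_error(reference_genome(ctg, gaps = data.frame(contig = "c1",
                                                       start = 10, end = 10)),
               "half-open")
})

test_that("FASTA and paired FASTQ round-trip losslessly", {
  dir <- withr::local_tempdir()
  seqs <- herdqc:::with_seed(901, setNames(c(random_dna(300), random_dna(200)),
                                           c("a", "b")))
  fa <- file.path(dir, "x.fa")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)
  rp <- read_pairs(id = c("r1", "r2"),
                   seq1 = herdqc:::with_seed(902, c(random_dna(100),
                                                    random_dna(100))),
                   seq2 = herdqc:::with_seed(903, c(random_dna(100),
                                                    random_dna(100))))
  write_fastq_pair(rp, file.path(dir, "rp"))
  back <- read_fastq_pair(file.path(dir, "rp"))
  expect_identical(back$id, rp$id)
  expect_identical(back$seq1, rp$seq1)
  expect_identical(back$seq2, rp$seq2)
})

test_that("emitted VCF is parseable by an independent reader", {
  dir <- withr::local_tempdir()
  v <- data.frame(CHROM = "chr1", POS = c(101L, 205L),
                  REF = c("A", "TAC"), ALT = c("G", "T"),
                  GT = c("het", "hom"), CLASS = c("SNP", "indel"),
                  DP = c(12L, 9L), AF = c(0.5, 1), ADF = c(3L, 4L),
                  ADR = c(3L, 5L), FILTER = c("PASS", "low_depth"))
  path <- file.path(dir, "v.vcf")
  write_variant_vcf(v, path, contigs = c(chr1 = 1000L))
  parsed <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(parsed))
  expect_equal(as.integer(fix$POS), v$POS)
  expect_equal(fix$REF, v$REF)
  expect_equal(fix$ALT, v$ALT)
  expect_equal(fix$FILTER, v$FILTER)
  expect_match(vcfR::extract.info(parsed, "ZY"), "het|hom")
})

test_that("SAM output encodes strand, CIGAR gaps and the NM tag", {
  dir <- withr::local_tempdir()
  aln <- data.frame(qname = c("m", "g", "u"), mate = 1L,
                    status = c("mapped", "mapped", "unmapped"),
                    contig = c("c1", "c1", NA), start = c(10L, 30L, NA),
                    strand = c("-", "+", "*"), nm = c(1L, 0L, NA),
                    gap_pos = c(0L, 45L, 0L), gap_len = c(0L, -2L, 0L),
                    perfect = FALSE, multiplicity = 1L,
                    seq = c(strrep("A", 50), strrep("C", 50),
                            strrep("G", 50)))
  path <- file.path(dir, "x.sam")
  write_sam(aln, path, contigs = c(c1 = 500L))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  f <- strsplit(body, "\t")
  expect_equal(f[[1]][2], "16")              # minus strand flag
  expect_equal(f[[2]][6], "15M2D35M")        # deletion CIGAR
  expect_equal(f[[1]][12], "NM:i:1")
  expect_equal(f[[3]][2], "4")               # unmapped flag
})

test_that("BED and TSV writers round-trip coordinates", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "r.bed")
  write_bed(data.frame(contig = "c1", start = 0, end = 100, kind = "gap"),
            bed)
  got <- read.table(bed, sep = "\t")
  expect_equal(unname(unlist(got)), c("c1", "0", "100", "gap"),
               ignore_attr = TRUE)
  tsv <- file.path(dir, "t.tsv")
  df <- data.frame(a = 1:3, b = c("x", "y", "z"))
  write_tsv(df, tsv)
  expect_equal(read_tsv(tsv), df)
})
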