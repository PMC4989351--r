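# Core containers: reference genomes, donor genomes, paired reads, and the
# plain-text interchange formats (FASTA, gzipped FASTQ, TSV, VCF, SAM, BED).
#
# Interval tables (gaps, misassembly regions, bad regions, flagged regions)
# use 0-based half-open coordinates, the BED convention; single positions
# (variants, accuracy tracks) are 1-based, the VCF convention.

#' Construct a reference genome
#'
#' @param contigs named character vector of uppercase A/C/G/T/N sequences.
#' @param gaps optional data.frame (`contig`, `start`, `end`), half-open
#'   0-based intervals already rendered as `N` runs in `contigs`.
#' @param misassembly optional data.frame (`contig`, `start`, `end`, `mode`)
#'   recording planted assembly errors (ground truth for scans).
#' @return an object of class `reference_genome`.
#' @export
reference_genome <- function(contigs, gaps = NULL, misassembly = NULL) {
  stopifnot(is.character(contigs), length(contigs) >= 1, !is.null(names(contigs)))
  if (any(nchar(contigs) == 0)) stop("contig sequences must be non-empty")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) stop("contig alphabet must be A/C/G/T/N: ", names(contigs)[bad][1])
  check_regions(gaps, "gap")
  if (!is.null(gaps) && nrow(gaps)) {
    for (ct in unique(gaps$contig)) {
      g <- gaps[gaps$contig == ct, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
        stop("overlapping gap intervals on contig ", ct)
      if (any(g$end > nchar(contigs[[ct]])))
        stop("gap interval beyond contig end on ", ct)
    }
  }
  check_regions(misassembly, "misassembly")
  structure(list(contigs = contigs, gaps = gaps, misassembly = misassembly),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome:", length(x$contigs), "contig(s),",
      format(sum(nchar(x$contigs)), big.mark = ","), "bp total\n")
  ng <- if (is.null(x$gaps)) 0L else nrow(x$gaps)
  cat("  gaps:", ng, " misassembly records:",
      if (is.null(x$misassembly)) 0L else nrow(x$misassembly), "\n")
  invisible(x)
}

#' Total contig lengths of a reference genome
#' @param ref a `reference_genome`.
#' @return named integer vector of contig lengths.
#' @export
contig_lengths <- function(ref) {
  setNames(nchar(ref$contigs), names(ref$contigs))
}

#' Construct a container of paired-end reads
#'
#' Reads are held in memory as parallel character vectors; `write_fastq_pair()`
#' and `read_fastq_pair()` move them to/from gzipped `_1`/`_2` FASTQ files.
#'
#' @param id read-pair names (no `/1`, `/2` suffix).
#' @param seq1,seq2 mate sequences.
#' @return an object of class `read_pairs`.
#' @export
read_pairs <- function(id = character(), seq1 = character(), seq2 = character()) {
  stopifnot(length(id) == length(seq1), length(id) == length(seq2))
  structure(list(id = unname(as.character(id)),
                 seq1 = unname(toupper(as.character(seq1))),
                 seq2 = unname(toupper(as.character(seq2)))),
            class = "read_pairs")
}

#' @export
length.read_pairs <- function(x) length(x$id)

#' @export
`[.read_pairs` <- function(x, i) {
  read_pairs(x$id[i], x$seq1[i], x$seq2[i])
}

#' @export
c.read_pairs <- function(...) {
  parts <- list(...)
  read_pairs(unlist(lapply(parts, `[[`, "id")),
             unlist(lapply(parts, `[[`, "seq1")),
             unlist(lapply(parts, `[[`, "seq2")))
}

#' @export
print.read_pairs <- function(x, ...) {
  cat("read_pairs:", length(x), "pairs\n")
  if (length(x)) cat("  first:", x$id[1], nchar(x$seq1[1]), "+",
                     nchar(x$seq2[1]), "bp\n")
  invisible(x)
}

#' Write a reference genome (or named sequences) to FASTA
#' @param x `reference_genome` or named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "reference_genome")) x$contigs else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write paired reads to gzipped FASTQ mate files
#'
#' @param rp a `read_pairs` object.
#' @param prefix output prefix; files `<prefix>_1.fastq.gz` and
#'   `<prefix>_2.fastq.gz` are written with uniform placeholder qualities
#'   (base-quality modelling is out of scope).
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(rp, prefix) {
  paths <- paste0(prefix, c("_1.fastq.gz", "_2.fastq.gz"))
  for (m in 1:2) {
    seqs <- Biostrings::DNAStringSet(rp[[paste0("seq", m)]])
    names(seqs) <- rp$id
    qual <- Biostrings::BStringSet(strrep("I", nchar(rp[[paste0("seq", m)]])))
    x <- Biostrings::QualityScaledDNAStringSet(seqs,
                                               Biostrings::PhredQuality(qual))
    Biostrings::writeQualityScaledXStringSet(x, paths[m], compress = TRUE)
  }
  invisible(paths)
}

#' Read gzipped FASTQ mate files into a `read_pairs` object
#' @param prefix prefix used by [write_fastq_pair()], or `files` directly.
#' @param files optional explicit character vector of the two mate files.
#' @return a `read_pairs` object.
#' @export
read_fastq_pair <- function(prefix, files = NULL) {
  if (is.null(files)) files <- paste0(prefix, c("_1.fastq.gz", "_2.fastq.gz"))
  r1 <- Biostrings::readDNAStringSet(files[1], format = "fastq")
  r2 <- Biostrings::readDNAStringSet(files[2], format = "fastq")
  id1 <- sub("\\s.*", "", names(r1))
  id2 <- sub("\\s.*", "", names(r2))
  if (!identical(id1, id2)) stop("mate files disagree on read names")
  read_pairs(id1, as.character(r1), as.character(r2))
}

#' Write a variant table as VCF 4.2
#'
#' Emits the package's call records (anchored, left-aligned alleles) with
#' zygosity, class, depth, allele fraction and strand counts in INFO, and the
#' filter status in FILTER.
#'
#' @param variants data.frame with columns `CHROM`, `POS`, `REF`, `ALT` and
#'   optionally `GT`, `CLASS`, `DP`, `AF`, `ADF`, `ADR`, `FILTER`.
#' @param path output path.
#' @param contigs optional named lengths for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=herdqc",
               "##INFO=<ID=ZY,Number=1,Type=String,Description=\"Zygosity (het/hom)\">",
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class (SNP/indel)\">",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
               "##INFO=<ID=ADF,Number=1,Type=Integer,Description=\"Alt reads, forward strand\">",
               "##INFO=<ID=ADR,Number=1,Type=Integer,Description=\"Alt reads, reverse strand\">"),
             con)
  if (!is.null(contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(variants)) {
    g <- function(col, def) if (col %in% names(variants)) variants[[col]] else def
    info <- sprintf("ZY=%s;CLASS=%s;DP=%d;AF=%.4f;ADF=%d;ADR=%d",
                    g("GT", "."), g("CLASS", "."),
                    as.integer(g("DP", 0L)), as.numeric(g("AF", 0)),
                    as.integer(g("ADF", 0L)), as.integer(g("ADR", 0L)))
    filt <- g("FILTER", "PASS")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s", variants$CHROM,
                       as.integer(variants$POS), variants$REF, variants$ALT,
                       filt, info), con)
  }
  invisible(path)
}

#' Write alignments as minimal SAM
#'
#' Mandatory columns plus the `NM` tag; one record per mapped read, unmapped
#' reads emitted with flag 4.
#'
#' @param aln alignment table from [align_reads()] (`$alignments`).
#' @param path output path.
#' @param contigs named contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, contigs) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)),
             con)
  for (i in seq_len(nrow(aln))) {
    a <- aln[i, ]
    if (is.na(a$start)) {
      writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", a$qname, a$seq),
                 con)
      next
    }
    len <- nchar(a$seq)
    cigar <- if (a$gap_len == 0) sprintf("%dM", len)
    else if (a$gap_len < 0) {
      b <- a$gap_pos - a$start
      sprintf("%dM%dD%dM", b, -a$gap_len, len - b)
    } else {
      b <- a$gap_pos - a$start
      sprintf("%dM%dI%dM", b, a$gap_len, len - b - a$gap_len)
    }
    flag <- if (a$strand == "-") 16L else 0L
    # aln$seq is already oriented to the forward reference strand, as SAM wants
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                       a$qname, flag, a$contig, a$start, cigar, a$seq, a$nm),
               con)
  }
  invisible(path)
}

#' Write half-open regions as BED
#' @param regions data.frame with `contig`, `start`, `end` (0-based half-open)
#'   and optionally `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  nm <- if ("name" %in% names(regions)) regions$name
  else if ("kind" %in% names(regions)) regions$kind else "."
  df <- data.frame(regions$contig, as.integer(regions$start),
                   as.integer(regions$end), nm)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write/read a TSV table (column headers kept, no quoting)
#' @param x data.frame.
#' @param path file path.
#' @return `path` (write) or data.frame (read), invisibly for write.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
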