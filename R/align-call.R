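# Minimal paired-end matcher and pileup variant caller.
#
# Acceptance rules for a placement: at most 2 mismatched bases, more than
# 95 % overall identity over aligned bases, at least 35 contiguous exactly
# matching bases, and at most 100 equally acceptable placements genome-wide
# (reads over the cap are reported unmapped-by-multiplicity and excluded
# from coverage and calling). A single short gap (<= 9 bases) is allowed so
# reads spanning small indels still place. The primary placement has the
# lowest edit distance (mismatches + gap bases), ties broken by leftmost
# coordinate. Candidate placements are enumerated from non-overlapping exact
# k-mer seeds, which is exhaustive for these thresholds; the heavy lifting
# is compiled code.

ref_contigs <- function(ref) {
  if (inherits(ref, "reference_genome")) ref$contigs
  else if (is.character(ref) && !is.null(names(ref))) ref
  else stop("reference must be a reference_genome or named character vector")
}

#' Align read pairs to a reference
#'
#' @param reads a [read_pairs] object.
#' @param ref a [reference_genome] or named character vector.
#' @param k seed k-mer size (must be <= read_length / 4 for exhaustive
#'   candidate enumeration with the default thresholds).
#' @param max_mm maximum mismatched bases per placement.
#' @param min_ident minimum percent identity over aligned bases (strict).
#' @param min_exact minimum contiguous exactly matching stretch (bases).
#' @param max_hits maximum number of placements before a read is reported
#'   unmapped-by-multiplicity.
#' @param max_gap maximum single-gap (indel) length considered.
#' @return an object of class `alignment_result`: `alignments` (one row per
#'   mate: `qname`, `mate`, `status` in mapped/unmapped/multi, `contig`,
#'   `start` (1-based), `strand`, `nm` (edit distance: mismatches plus gap
#'   bases, the SAM `NM` convention), `gap_pos`, `gap_len`, `perfect`,
#'   `multiplicity`, `seq` oriented to the forward reference strand) and
#'   `counts`. The three statuses always sum to the input mate count.
#' @export
align_reads <- function(reads, ref, k = 16, max_mm = 2, min_ident = 95.0,
                        min_exact = 35, max_hits = 100, max_gap = 9) {
  stopifnot(inherits(reads, "read_pairs"))
  contigs <- ref_contigs(ref)
  n <- length(reads)
  allseq <- c(reads$seq1, reads$seq2)
  res <- cpp_align(unname(contigs), names(contigs), allseq, k = k,
                   max_mm = max_mm, min_ident = min_ident,
                   min_exact = min_exact, max_hits = max_hits,
                   max_gap = max_gap)
  status <- c("unmapped", "mapped", "multi")[res$status + 1L]
  mapped <- res$status == 1L
  seq_out <- allseq
  neg <- which(mapped & res$strand == "-")
  if (length(neg)) seq_out[neg] <- revcomp(allseq[neg])
  aln <- data.frame(
    qname = rep(reads$id, 2), mate = rep(1:2, each = n), status = status,
    contig = ifelse(mapped, names(contigs)[res$contig], NA_character_),
    start = res$start, strand = res$strand, nm = res$nm,
    gap_pos = res$gap_pos, gap_len = res$gap_len, perfect = res$perfect,
    multiplicity = res$multiplicity, seq = seq_out,
    stringsAsFactors = FALSE)
  counts <- c(mapped = sum(status == "mapped"),
              unmapped = sum(status == "unmapped"),
              multi = sum(status == "multi"), input = 2L * n)
  structure(list(alignments = aln, counts = counts,
                 contig_lengths = setNames(nchar(contigs), names(contigs))),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("alignment_result:\n")
  print(x$counts)
  invisible(x)
}

#' Breadth of coverage
#'
#' Fraction of non-gap (non-N) reference bases covered by at least one
#' mapped read.
#'
#' @param aln an `alignment_result`.
#' @param ref the reference used for alignment.
#' @return list with `breadth` (overall fraction) and `per_contig`
#'   data.frame (`contig`, `covered`, `denominator`, `breadth`).
#' @export
breadth_of_coverage <- function(aln, ref) {
  contigs <- ref_contigs(ref)
  a <- aln$alignments[aln$alignments$status == "mapped", , drop = FALSE]
  per <- lapply(names(contigs), function(ct) {
    L <- nchar(contigs[[ct]])
    nN <- sum(strsplit(contigs[[ct]], "")[[1]] == "N")
    ai <- a[a$contig == ct, , drop = FALSE]
    covered <- 0L
    if (nrow(ai)) {
      span <- nchar(ai$seq) + pmax(0L, -ai$gap_len) - pmax(0L, ai$gap_len)
      ir <- IRanges::IRanges(start = ai$start, width = span)
      ir <- IRanges::restrict(ir, 1L, L)
      cov <- IRanges::reduce(ir)
      # exclude N bases from the covered count
      if (nN > 0) {
        npos <- which(strsplit(contigs[[ct]], "")[[1]] == "N")
        nir <- IRanges::reduce(IRanges::IRanges(npos, npos))
        cov <- IRanges::setdiff(cov, nir)
      }
      covered <- sum(IRanges::width(cov))
    }
    data.frame(contig = ct, covered = covered, denominator = L - nN,
               breadth = if (L - nN > 0) covered / (L - nN) else NA_real_)
  })
  per <- do.call(rbind, per)
  list(breadth = sum(per$covered) / sum(per$denominator), per_contig = per)
}

#' Variant-caller filter settings
#'
#' The filter families are coverage depth, allelic balance and
#' forward/reverse strand balance; the default thresholds are conventional
#' pileup heuristics and all are exposed here.
#'
#' @param min_depth minimum read depth at the site.
#' @param het_band alt-allele-fraction interval called heterozygous.
#' @param hom_min_fraction alt fraction above which the site is called
#'   homozygous-alt.
#' @param strand_min_each minimum alt reads required on each strand.
#' @param strand_min_alt alt-read count from which the strand-balance rule
#'   applies.
#' @return a list of class `call_filters`.
#' @export
call_filters <- function(min_depth = 4, het_band = c(0.2, 0.8),
                         hom_min_fraction = 0.8, strand_min_each = 1,
                         strand_min_alt = 4) {
  stopifnot(length(het_band) == 2, het_band[1] > 0, het_band[2] < 1 ||
              het_band[2] == hom_min_fraction, het_band[1] < het_band[2])
  structure(list(min_depth = min_depth, het_band = het_band,
                 hom_min_fraction = hom_min_fraction,
                 strand_min_each = strand_min_each,
                 strand_min_alt = strand_min_alt), class = "call_filters")
}

# left-align and trim an anchored variant representation (VCF convention)
normalize_variant <- function(seqc, pos, refa, alta) {
  repeat {
    changed <- FALSE
    while (nchar(refa) > 1 && nchar(alta) > 1 &&
           substr(refa, nchar(refa), nchar(refa)) ==
           substr(alta, nchar(alta), nchar(alta))) {
      refa <- substr(refa, 1, nchar(refa) - 1)
      alta <- substr(alta, 1, nchar(alta) - 1)
      changed <- TRUE
    }
    if ((nchar(refa) == 1 || nchar(alta) == 1) && pos > 1 &&
        nchar(refa) != nchar(alta) &&
        substr(refa, nchar(refa), nchar(refa)) ==
        substr(alta, nchar(alta), nchar(alta))) {
      b <- substr(seqc, pos - 1, pos - 1)
      refa <- paste0(b, substr(refa, 1, nchar(refa) - 1))
      alta <- paste0(b, substr(alta, 1, nchar(alta) - 1))
      pos <- pos - 1
      changed <- TRUE
    }
    if (!changed) break
  }
  list(pos = pos, ref = refa, alt = alta)
}

# normalize all indel rows of a variant table against the reference
normalize_calls <- function(calls, contigs) {
  if (!nrow(calls)) return(calls)
  idx <- which(calls$CLASS == "indel")
  for (i in idx) {
    nv <- normalize_variant(contigs[[calls$CHROM[i]]], calls$POS[i],
                            calls$REF[i], calls$ALT[i])
    calls$POS[i] <- nv$pos; calls$REF[i] <- nv$ref; calls$ALT[i] <- nv$alt
  }
  calls[order(calls$CHROM, calls$POS), , drop = FALSE]
}

#' Call variants from a pileup of accepted alignments
#'
#' Any position where a read differs from the reference is a putative
#' variant; the genotype is assigned from the alt-allele fraction and the
#' filter column records the first failed criterion (depth, allelic balance,
#' strand balance). Indels are reported in anchored, left-aligned VCF style.
#'
#' @param aln an `alignment_result`.
#' @param ref the reference used for alignment.
#' @param filters a [call_filters] object.
#' @return data.frame with `CHROM`, `POS`, `REF`, `ALT`, `GT`, `CLASS`,
#'   `DP`, `AF`, `ADF`, `ADR`, `FILTER`.
#' @export
call_variants <- function(aln, ref, filters = call_filters()) {
  contigs <- ref_contigs(ref)
  a <- aln$alignments[aln$alignments$status == "mapped", , drop = FALSE]
  if (any(!a$contig %in% names(contigs)))
    stop("alignments refer to contigs absent from the reference")
  out <- list()
  for (ct in names(contigs)) {
    ai <- a[a$contig == ct, , drop = FALSE]
    if (!nrow(ai)) next
    seqc <- contigs[[ct]]
    L <- nchar(seqc)
    pl <- cpp_pileup(seqc, ai$seq, ai$start, ai$strand, ai$gap_pos,
                     ai$gap_len)
    cnt <- pl$counts # 8 x L: A,C,G,T fwd then rev
    basei <- match(strsplit(seqc, "")[[1]], c("A", "C", "G", "T"))
    tot <- cnt[1:4, , drop = FALSE] + cnt[5:8, , drop = FALSE]
    depth <- colSums(tot) + pl$del_depth
    # mask the reference base, then take the best remaining allele
    alt_tot <- tot
    ok <- !is.na(basei)
    alt_tot[cbind(basei[ok], which(ok))] <- -1L
    best <- max.col(t(alt_tot), ties.method = "first")
    altn <- alt_tot[cbind(best, seq_len(L))]
    snp_pos <- which(ok & altn > 0)
    snp <- NULL
    if (length(snp_pos)) {
      bases <- c("A", "C", "G", "T")
      adf <- cnt[1:4, , drop = FALSE][cbind(best[snp_pos], snp_pos)]
      adr <- cnt[5:8, , drop = FALSE][cbind(best[snp_pos], snp_pos)]
      snp <- data.frame(CHROM = ct, POS = snp_pos,
                        REF = bases[basei[snp_pos]],
                        ALT = bases[best[snp_pos]],
                        CLASS = "SNP", DP = depth[snp_pos],
                        ADF = adf, ADR = adr, stringsAsFactors = FALSE)
    }
    idl <- NULL
    dels <- pl$del; inss <- pl$ins
    if (nrow(dels)) {
      anchor <- dels$pos - 1L
      keep <- anchor >= 1
      dels <- dels[keep, , drop = FALSE]; anchor <- anchor[keep]
      if (nrow(dels))
        idl <- rbind(idl, data.frame(
          CHROM = ct, POS = anchor,
          REF = substring(seqc, anchor, anchor + dels$len),
          ALT = substring(seqc, anchor, anchor),
          CLASS = "indel", DP = depth[anchor] ,
          ADF = dels$fwd, ADR = dels$rev, stringsAsFactors = FALSE))
    }
    if (nrow(inss)) {
      anchor <- inss$pos - 1L
      keep <- anchor >= 1
      inss <- inss[keep, , drop = FALSE]; anchor <- anchor[keep]
      if (nrow(inss))
        idl <- rbind(idl, data.frame(
          CHROM = ct, POS = anchor,
          REF = substring(seqc, anchor, anchor),
          ALT = paste0(substring(seqc, anchor, anchor), inss$seq),
          CLASS = "indel", DP = depth[anchor],
          ADF = inss$fwd, ADR = inss$rev, stringsAsFactors = FALSE))
    }
    out[[ct]] <- rbind(snp, idl)
  }
  calls <- do.call(rbind, out)
  if (is.null(calls) || !nrow(calls))
    return(data.frame(CHROM = character(), POS = integer(),
                      REF = character(), ALT = character(), GT = character(),
                      CLASS = character(), DP = integer(), AF = numeric(),
                      ADF = integer(), ADR = integer(), FILTER = character(),
                      stringsAsFactors = FALSE))
  altc <- calls$ADF + calls$ADR
  calls$DP <- pmax(calls$DP, altc)
  calls$AF <- altc / calls$DP
  calls$GT <- ifelse(calls$AF > filters$hom_min_fraction, "hom",
                     ifelse(calls$AF >= filters$het_band[1], "het", "."))
  filt <- rep("PASS", nrow(calls))
  filt[calls$AF < filters$het_band[1]] <- "allelic_balance"
  strand_fail <- altc >= filters$strand_min_alt &
    (calls$ADF < filters$strand_min_each |
       calls$ADR < filters$strand_min_each)
  filt[strand_fail] <- "strand_balance"
  filt[calls$DP < filters$min_depth] <- "low_depth"
  calls$FILTER <- filt
  calls <- calls[, c("CHROM", "POS", "REF", "ALT", "GT", "CLASS", "DP", "AF",
                     "ADF", "ADR", "FILTER")]
  rownames(calls) <- NULL
  normalize_calls(calls, contigs)
}

#' Combine per-sample variant tables into a final call set
#'
#' A variant is retained only if it passes its per-sample filters, is
#' bi-allelic across samples (one ALT allele per site), and is observed in
#' at least two individuals.
#'
#' @param tables named list (>= 2) of per-sample call tables from
#'   [call_variants()].
#' @param min_samples minimum number of individuals carrying the variant.
#' @return data.frame of retained variants with an `n_samples` column.
#' @export
finalize_call_set <- function(tables, min_samples = 2) {
  stopifnot(is.list(tables), length(tables) >= 2)
  pass <- lapply(tables, function(t) t[t$FILTER == "PASS", , drop = FALSE])
  all <- do.call(rbind, lapply(seq_along(pass), function(i) {
    t <- pass[[i]]
    if (nrow(t)) t$sample <- i
    t
  }))
  if (is.null(all) || !nrow(all)) return(all)
  site <- paste(all$CHROM, all$POS, all$REF)
  allele <- paste(site, all$ALT)
  multi <- names(which(tapply(all$ALT, site, function(x) length(unique(x))) > 1))
  all <- all[!site %in% multi, , drop = FALSE]
  allele <- paste(all$CHROM, all$POS, all$REF, all$ALT)
  n_by <- table(allele)
  keep <- allele %in% names(n_by)[n_by >= min_samples]
  kept <- all[keep, , drop = FALSE]
  if (!nrow(kept)) return(kept[, c("CHROM", "POS", "REF", "ALT", "CLASS")])
  key <- paste(kept$CHROM, kept$POS, kept$REF, kept$ALT)
  first <- !duplicated(key)
  outv <- kept[first, c("CHROM", "POS", "REF", "ALT", "CLASS"), drop = FALSE]
  outv$n_samples <- as.integer(n_by[key[first]])
  rownames(outv) <- NULL
  outv[order(outv$CHROM, outv$POS), , drop = FALSE]
}

#' Randomly subsample read pairs to a target depth
#'
#' Pairs are kept i.i.d. with probability `target_depth / full_depth`
#' (subsampling by pairs preserves pairing and fold-coverage arithmetic);
#' replicates use distinct child seeds.
#'
#' @param reads a [read_pairs] object.
#' @param full_depth depth of the complete data.
#' @param target_depth desired depth (<= `full_depth`).
#' @param replicate replicate index (>= 1).
#' @param seed master seed.
#' @return a [read_pairs] subset.
#' @export
subsample_reads <- function(reads, full_depth, target_depth, replicate = 1,
                            seed = 1) {
  if (target_depth > full_depth) stop("target depth exceeds full depth")
  if (target_depth == full_depth) return(reads)
  p <- target_depth / full_depth
  with_seed(child_seed(seed, paste0("sub", target_depth, "_", replicate)),
            reads[runif(length(reads)) < p])
}

#' Variant recovery relative to the full-depth call set
#'
#' Recovery = |variants called at depth, intersected with the full set| /
#' |full set|, computed per variant class (zygosity x SNP/indel taken from
#' the full-depth calls). An optional saturation fraction adds a rescaled
#' column estimating recovery relative to the genome rather than the
#' full-depth calls.
#'
#' @param full_calls PASS-filtered call table at full depth.
#' @param subsampled list of entries `list(depth=, replicate=, calls=)`.
#' @param saturation_scale optional fraction of genomic variants the full
#'   data discovers (e.g. 0.956); adds `recovery_scaled = recovery * scale`.
#' @return data.frame of class `recovery_table`: `depth`, `replicate`,
#'   `class`, `n_called`, `n_full`, `recovery` (and `recovery_scaled`).
#' @export
recovery_curve <- function(full_calls, subsampled, saturation_scale = NULL) {
  full <- full_calls[full_calls$FILTER == "PASS", , drop = FALSE]
  if (!nrow(full)) stop("full-depth call set is empty")
  full$key <- paste(full$CHROM, full$POS, full$REF, full$ALT)
  full$vclass <- paste(full$GT, full$CLASS, sep = "_")
  classes <- sort(unique(full$vclass))
  n_full <- table(factor(full$vclass, classes))
  rows <- lapply(subsampled, function(e) {
    calls <- e$calls
    key <- if (nrow(calls))
      paste(calls$CHROM, calls$POS, calls$REF, calls$ALT)[calls$FILTER == "PASS"]
    else character()
    hit <- full$key %in% key
    n_called <- table(factor(full$vclass[hit], classes))
    data.frame(depth = e$depth, replicate = e$replicate, class = classes,
               n_called = as.integer(n_called), n_full = as.integer(n_full),
               recovery = as.numeric(n_called / n_full))
  })
  out <- do.call(rbind, rows)
  if (!is.null(saturation_scale))
    out$recovery_scaled <- out$recovery * saturation_scale
  class(out) <- c("recovery_table", class(out))
  rownames(out) <- NULL
  out
}

#' Mean recovery per depth and class across replicates
#' @param rt a `recovery_table`.
#' @return data.frame `depth`, `class`, `recovery` (replicate mean).
#' @export
recovery_summary <- function(rt) {
  agg <- aggregate(recovery ~ depth + class, data = rt, FUN = mean)
  agg[order(agg$class, agg$depth), ]
}
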