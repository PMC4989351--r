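# Unmapped-read census: pool reads that failed to align, assemble them with
# a toy greedy assembler, filter contigs by length, parse tabular best-hit
# alignments with significance thresholds, and summarize by species and
# gene. The assembler is a deliberate stand-in for a real de novo
# assembler: it only needs to reconstruct planted sequences at desk scale.

#' Collect the unmapped read pool from an alignment result
#'
#' Pairs where both mates failed to map, and pairs where exactly one mate
#' failed, are pooled (both mates emitted) so paired file structure is
#' preserved. Reads unmapped by multiplicity are included in the pool.
#'
#' @param aln an `alignment_result` from [align_reads()].
#' @param reads the [read_pairs] that were aligned.
#' @return list with `pool` ([read_pairs]), `n_both_unmapped`,
#'   `n_half_mapped`.
#' @export
collect_unmapped <- function(aln, reads) {
  a <- aln$alignments
  m1 <- a[a$mate == 1, ]; m2 <- a[a$mate == 2, ]
  if (!identical(m1$qname, reads$id) || !identical(m2$qname, reads$id)) {
    off <- setdiff(union(m1$qname, m2$qname), reads$id)
    stop("read names in alignments and reads disagree; first offender: ",
         if (length(off)) off[1] else "(ordering mismatch)")
  }
  un1 <- m1$status != "mapped"
  un2 <- m2$status != "mapped"
  keep <- un1 | un2
  list(pool = reads[keep],
       n_both_unmapped = sum(un1 & un2),
       n_half_mapped = sum(xor(un1, un2)))
}

#' Toy greedy overlap assembler
#'
#' Seeds a contig with the first unused read and repeatedly extends it right
#' and left by the read with the longest exact-anchored suffix/prefix
#' overlap of at least `min_overlap` bases and at least `min_identity`
#' percent identity over the overlap, consuming reads as it goes;
#' deterministic given input order. With `both_strands`, reverse complements
#' of the input reads participate and contigs that are reverse complements
#' of an earlier contig are collapsed.
#'
#' @param reads character vector of read sequences.
#' @param min_overlap minimum overlap in bases.
#' @param min_identity minimum percent identity over the overlap.
#' @param both_strands also consider reverse-complemented reads.
#' @return named character vector of contigs (`contig1`, `contig2`, ...),
#'   each at least one read long.
#' @export
greedy_assemble <- function(reads, min_overlap = 30, min_identity = 100,
                            both_strands = TRUE) {
  stopifnot(length(reads) >= 1, min_overlap >= 1)
  reads <- toupper(reads)
  reads <- reads[nchar(reads) >= min_overlap]
  reads <- unique(reads)
  if (both_strands) reads <- unique(c(reads, revcomp(reads)))
  n <- length(reads)
  if (n == 0) return(character())
  k <- min_overlap
  max_mm <- function(L) floor((1 - min_identity / 100) * L)
  # prefix index: first k bases -> read ids; suffix index: last k bases
  pref <- split(seq_len(n), substr(reads, 1, k))
  suff <- split(seq_len(n), substr(reads, nchar(reads) - k + 1, nchar(reads)))
  used <- logical(n)
  overlap_ok <- function(a, b, L) { # suffix of a vs prefix of b, length L
    sa <- substr(a, nchar(a) - L + 1, nchar(a))
    sb <- substr(b, 1, L)
    if (min_identity >= 100) sa == sb
    else sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]]) <= max_mm(L)
  }
  contigs <- character()
  for (s in seq_len(n)) {
    if (used[s]) next
    used[s] <- TRUE
    if (both_strands) {
      rcs <- match(revcomp(reads[s]), reads)
      if (!is.na(rcs)) used[rcs] <- TRUE
    }
    ctg <- reads[s]
    # extend right
    repeat {
      found <- FALSE
      for (L in seq(min(nchar(ctg), max(nchar(reads))), k)) {
        key <- substr(ctg, nchar(ctg) - L + 1, nchar(ctg) - L + k)
        cand <- pref[[key]]
        cand <- cand[!used[cand] & nchar(reads)[cand] > L]
        for (b in cand) {
          if (overlap_ok(ctg, reads[b], L)) {
            used[b] <- TRUE
            if (both_strands) {
              rcb <- match(revcomp(reads[b]), reads)
              if (!is.na(rcb)) used[rcb] <- TRUE
            }
            ctg <- paste0(ctg, substr(reads[b], L + 1, nchar(reads[b])))
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (!found) break
    }
    # extend left
    repeat {
      found <- FALSE
      for (L in seq(min(nchar(ctg), max(nchar(reads))), k)) {
        key <- substr(ctg, L - k + 1, L)
        cand <- suff[[key]]
        cand <- cand[!used[cand] & nchar(reads)[cand] > L]
        for (b in cand) {
          if (overlap_ok(reads[b], ctg, L)) {
            used[b] <- TRUE
            if (both_strands) {
              rcb <- match(revcomp(reads[b]), reads)
              if (!is.na(rcb)) used[rcb] <- TRUE
            }
            ctg <- paste0(substr(reads[b], 1, nchar(reads[b]) - L), ctg)
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (!found) break
    }
    contigs <- c(contigs, ctg)
  }
  if (both_strands && length(contigs) > 1) {
    drop <- logical(length(contigs))
    rc <- revcomp(contigs)
    for (i in seq_along(contigs))
      if (!drop[i]) drop[which(contigs == rc[i] & seq_along(contigs) > i)] <- TRUE
    contigs <- contigs[!drop]
  }
  setNames(contigs, paste0("contig", seq_along(contigs)))
}

#' Length-filter assembled contigs before database search
#'
#' DNA contigs must be strictly longer than `min_len` bases; RNA contigs are
#' not filtered by size.
#'
#' @param contigs named character vector.
#' @param molecule `"DNA"` or `"RNA"`.
#' @param min_len DNA length threshold (strict).
#' @return filtered named character vector.
#' @export
filter_contigs <- function(contigs, molecule = c("DNA", "RNA"),
                           min_len = 500) {
  molecule <- match.arg(molecule)
  if (molecule == "RNA") contigs else contigs[nchar(contigs) > min_len]
}

hit_columns <- c("query", "subject", "identity", "length", "mismatches",
                 "gaps", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore", "species", "gi")

#' Parse a tabular best-hit file to one record per query
#'
#' Input is the 12-column tabular alignment dialect plus subject species and
#' GI columns. For each query the most significant alignment is retained:
#' lowest E-value, ties broken by higher bit score, then first occurrence.
#'
#' @param path TSV file (no header) or a data.frame already in that layout.
#' @return data.frame of best hits, one row per query.
#' @export
parse_best_hits <- function(path) {
  df <- if (is.data.frame(path)) {
    x <- path
    if (!all(hit_columns %in% names(x))) names(x) <- hit_columns[seq_along(x)]
    x
  } else {
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               col.names = hit_columns, fill = FALSE)
  }
  num_cols <- c("identity", "length", "mismatches", "gaps", "qstart", "qend",
                "sstart", "send", "evalue", "bitscore")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(is.na(v) & !is.na(df[[cc]])))
      stop("malformed hit row at line ",
           which(is.na(v) & !is.na(df[[cc]]))[1], " (column ", cc, ")")
    df[[cc]] <- v
  }
  if (any(df$evalue < 0)) stop("negative E-value at line ",
                               which(df$evalue < 0)[1])
  ord <- order(df$query, df$evalue, -df$bitscore, seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  best <- df[!duplicated(df$query), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Keep only significant hits
#'
#' An alignment is significant only if it is longer than 200 bp for DNA or
#' longer than 50 bp for RNA (strict inequalities).
#'
#' @param hits best-hit data.frame from [parse_best_hits()].
#' @param molecule `"DNA"` or `"RNA"`.
#' @return filtered data.frame.
#' @export
apply_significance <- function(hits, molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  thr <- if (molecule == "DNA") 200 else 50
  hits[hits$length > thr, , drop = FALSE]
}

#' Summarize significant hits per subject species
#'
#' @param hits significant hits.
#' @return data.frame, one row per species, sorted by number of alignments
#'   descending: `n`, mean/max identity, mean/max match length, arithmetic
#'   mean E-value and a log10-scale geometric mean (arithmetic means of
#'   E-values are dominated by the single worst hit).
#' @export
summarize_species <- function(hits) {
  stopifnot(nrow(hits) >= 1)
  sp <- split(hits, hits$species)
  out <- do.call(rbind, lapply(sp, function(h) data.frame(
    species = h$species[1], n = nrow(h),
    mean_identity = mean(h$identity), max_identity = max(h$identity),
    mean_length = mean(h$length), max_length = max(h$length),
    mean_evalue = mean(h$evalue),
    geomean_log10_evalue = mean(log10(pmax(h$evalue, 1e-300))))))
  out <- out[order(-out$n, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Roll significant hits up to gene symbols
#'
#' @param hits significant hits.
#' @param gi_to_symbol data.frame with columns `gi` and `symbol` (a local
#'   lookup fixture; no live database access).
#' @return list with `per_gene` (data.frame `symbol`, `n`, sorted by count),
#'   `unresolved` (hits whose GI is absent from the table), and `genes`
#'   (unique symbol character vector).
#' @export
map_genes <- function(hits, gi_to_symbol) {
  stopifnot(all(c("gi", "symbol") %in% names(gi_to_symbol)))
  sym <- gi_to_symbol$symbol[match(hits$gi, gi_to_symbol$gi)]
  resolved <- !is.na(sym)
  tab <- sort(table(sym[resolved]), decreasing = TRUE)
  per_gene <- data.frame(symbol = names(tab), n = as.integer(tab))
  list(per_gene = per_gene, unresolved = sum(!resolved),
       genes = per_gene$symbol)
}

#' Intersection of two gene-symbol sets
#' @param a,b character vectors of gene symbols.
#' @return list with `n_common` and `common`.
#' @export
gene_set_overlap <- function(a, b) {
  common <- intersect(unique(a), unique(b))
  list(n_common = length(common), common = common)
}

#' Cross-overlap between two contig sets by local alignment
#'
#' Fraction of query contigs with at least one local alignment to any
#' subject contig exceeding `min_identity` percent identity over at least
#' `min_length` aligned bases, plus the total subject bases spanned by such
#' alignments. Scoring is match +1 / mismatch -1 / gap -2 (Smith-Waterman).
#'
#' @param query,subject named character vectors of contigs.
#' @param min_identity percent identity threshold (strict).
#' @param min_length minimum aligned length to count an alignment.
#' @return list with `fraction`, `n_query`, `n_overlapping`,
#'   `spanned_bases`.
#' @export
cross_overlap <- function(query, subject, min_identity = 98,
                          min_length = 100) {
  stopifnot(length(query) >= 1, length(subject) >= 1)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  hit <- logical(length(query))
  spans <- list()
  for (i in seq_along(query)) {
    for (j in seq_along(subject)) {
      for (qseq in c(query[[i]], revcomp(query[[i]]))) {
        al <- Biostrings::pairwiseAlignment(qseq, subject[[j]],
                                            type = "local",
                                            substitutionMatrix = mat,
                                            gapOpening = 0, gapExtension = 2)
        alen <- nchar(as.character(Biostrings::alignedPattern(al)))
        if (alen >= min_length && Biostrings::pid(al) > min_identity) {
          hit[i] <- TRUE
          sj <- Biostrings::subject(al)
          spans[[length(spans) + 1]] <-
            data.frame(j = j, start = Biostrings::start(sj),
                       end = Biostrings::end(sj))
          break
        }
      }
    }
  }
  spanned <- 0L
  if (length(spans)) {
    sp <- do.call(rbind, spans)
    for (j in unique(sp$j)) {
      s <- sp[sp$j == j, ]
      spanned <- spanned +
        sum(IRanges::width(IRanges::reduce(IRanges::IRanges(s$start, s$end))))
    }
  }
  list(fraction = mean(hit), n_query = length(query),
       n_overlapping = sum(hit), spanned_bases = spanned)
}

#' Contig summary statistics
#'
#' N50 is base-weighted: the largest length L such that contigs of length L
#' or more contain at least half of the total assembled bases. A count-based
#' alternative (largest L such that at least half of the contigs reach L)
#' is available behind `count_based`.
#'
#' @param contigs named character vector (or numeric lengths).
#' @param count_based use the count-based N50 variant.
#' @return list with `n`, `total_bp`, `min`, `max`, `n50`.
#' @export
contig_stats <- function(contigs, count_based = FALSE) {
  if (length(contigs) == 0) stop("no contigs")
  lens <- if (is.numeric(contigs)) contigs else nchar(contigs)
  lens <- sort(lens, decreasing = TRUE)
  n50 <- if (count_based) {
    lens[ceiling(length(lens) / 2)]
  } else {
    lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
  }
  list(n = length(lens), total_bp = sum(lens), min = min(lens),
       max = max(lens), n50 = n50)
}
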