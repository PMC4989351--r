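# Independent reference implementations ("oracles") used to validate the
# optimized code paths: a brute-force read placement scan, a per-base
# coverage counter, a successive-difference gap scan, and a dense GLS
# solver. All are written for clarity, not speed, and only run at small
# scale.

# Brute-force placement scan for a single read over small contigs.
# Returns the optimal placement under the matcher's acceptance rules:
# <= max_mm mismatches, > min_ident percent identity over aligned bases
# (gap excluded), >= min_exact contiguous exact matches (a gap breaks the
# run), a single gap of at most max_gap bases, and the two-phase rule that
# gapped placements are considered only when no ungapped placement is
# acceptable anywhere. Result: list(status, edit, starts) where starts is
# the set of (contig, start, strand) rows attaining the optimal edit.
oracle_scan <- function(rd, contigs, max_mm = 2, min_ident = 95,
                        min_exact = 35, max_hits = 100, max_gap = 9) {
  acc <- function(neq_pre, neq_suf, g) {
    # neq_pre/neq_suf: logical mismatch vectors of the aligned prefix and
    # suffix segments (suffix empty for ungapped); g = gap bases
    mm <- sum(neq_pre) + sum(neq_suf)
    aligned <- length(neq_pre) + length(neq_suf)
    ident <- 100 * (aligned - mm) / aligned
    runs <- function(x) {
      if (!length(x)) return(0L)
      r <- rle(!x)
      m <- r$lengths[r$values]
      if (length(m)) max(m) else 0L
    }
    run <- max(runs(neq_pre), runs(neq_suf))
    list(ok = mm <= max_mm && ident > min_ident && run >= min_exact,
         mm = mm, edit = mm + g)
  }
  scan_orient <- function(rv, refv, gapped) {
    len <- length(rv); L <- length(refv)
    out <- list()
    if (!gapped) {
      S <- L - len + 1
      if (S < 1) return(out)
      mm <- integer(S)
      for (j in seq_len(len)) mm <- mm + (refv[j:(j + S - 1)] != rv[j])
      for (s in which(mm <= max_mm)) {
        a <- acc(refv[s:(s + len - 1)] != rv, logical(0), 0)
        if (a$ok) out[[length(out) + 1]] <- c(start = s, edit = a$edit)
      }
    } else {
      S <- L - len + 1
      if (S < 1) return(out)
      # cumulative prefix mismatches P[b, s] = sum over the first b read
      # bases of (ref[s + j - 1] != read[j]); candidates are screened on
      # total mismatch count, then re-checked in full
      MM <- matrix(0L, len, S)
      for (j in seq_len(len)) MM[j, ] <- refv[j:(j + S - 1)] != rv[j]
      P <- apply(MM, 2, cumsum)
      if (is.null(dim(P))) P <- matrix(P, nrow = len)
      check_detail <- function(s, g, kind) {
        best <- NULL
        bs <- if (kind == "del") seq_len(len - 1) else seq_len(len - g - 1)
        for (b in bs) {
          pre <- refv[s:(s + b - 1)] != rv[1:b]
          suf <- if (kind == "del")
            refv[(s + b + g):(s + len + g - 1)] != rv[(b + 1):len]
          else refv[(s + b):(s + len - g - 1)] != rv[(b + g + 1):len]
          a <- acc(pre, suf, g)
          if (a$ok && (is.null(best) || a$edit < best)) best <- a$edit
        }
        best
      }
      for (g in seq_len(max_gap)) {
        # deletion of g reference bases after read position b
        Sg <- S - g
        if (Sg >= 1) {
          T1 <- P[, seq_len(Sg), drop = FALSE]
          T2 <- P[, g + seq_len(Sg), drop = FALSE]
          tot <- T1 - T2 + rep(T2[len, ], each = len)
          minmm <- apply(tot[seq_len(len - 1), , drop = FALSE], 2, min)
          for (s in which(minmm <= max_mm)) {
            best <- check_detail(s, g, "del")
            if (!is.null(best))
              out[[length(out) + 1]] <- c(start = s, edit = best)
          }
        }
        # insertion of g read bases after read position b
        if (len - g >= 2) {
          Si <- L - (len - g) + 1
          MI <- matrix(0L, len - g, Si)
          for (j in seq_len(len - g))
            MI[j, ] <- refv[j:(j + Si - 1)] != rv[j + g]
          Pi <- apply(MI, 2, cumsum)
          if (is.null(dim(Pi))) Pi <- matrix(Pi, nrow = len - g)
          Sb <- min(S, Si)
          tot <- P[seq_len(len - g - 1), seq_len(Sb), drop = FALSE] -
            Pi[seq_len(len - g - 1), seq_len(Sb), drop = FALSE] +
            rep(Pi[len - g, seq_len(Sb)], each = len - g - 1)
          minmm <- apply(tot, 2, min)
          cand <- which(minmm <= max_mm)
          # starts beyond the ungapped range (read tail off the contig end
          # but the shorter gapped span fits) are checked unscreened
          if (Si > Sb) cand <- c(cand, seq(Sb + 1, Si))
          for (s in cand) {
            best <- check_detail(s, g, "ins")
            if (!is.null(best))
              out[[length(out) + 1]] <- c(start = s, edit = best)
          }
        }
      }
    }
    out
  }
  collect <- function(gapped) {
    plc <- list()
    for (ci in seq_along(contigs)) {
      refv <- utf8ToInt(contigs[[ci]])
      for (strand in c("+", "-")) {
        rseq <- if (strand == "+") rd else revcomp(rd)
        hits <- scan_orient(utf8ToInt(rseq), refv, gapped)
        for (h in hits)
          plc[[length(plc) + 1]] <- data.frame(
            contig = ci, start = unname(h["start"]), strand = strand,
            edit = unname(h["edit"]))
      }
    }
    if (length(plc)) do.call(rbind, plc) else NULL
  }
  plc <- collect(gapped = FALSE)
  if (is.null(plc)) plc <- collect(gapped = TRUE)
  if (is.null(plc)) return(list(status = "unmapped"))
  # collapse duplicate (contig,start,strand) keeping lowest edit
  plc <- plc[order(plc$edit, plc$contig, plc$start, plc$strand), ]
  key <- paste(plc$contig, plc$start, plc$strand)
  plc <- plc[!duplicated(key), ]
  if (nrow(plc) > max_hits) return(list(status = "multi"))
  best <- plc[plc$edit == min(plc$edit), , drop = FALSE]
  list(status = "mapped", edit = min(plc$edit),
       starts = best, n_placements = nrow(plc))
}

# Per-base coverage counter: covered non-N positions per contig, counting
# each mapped alignment's reference span position by position.
oracle_breadth <- function(aln, ref) {
  contigs <- if (inherits(ref, "reference_genome")) ref$contigs else ref
  a <- aln$alignments[aln$alignments$status == "mapped", , drop = FALSE]
  cov_tot <- 0; den_tot <- 0
  for (ct in names(contigs)) {
    L <- nchar(contigs[[ct]])
    hit <- logical(L)
    ai <- a[a$contig == ct, , drop = FALSE]
    if (nrow(ai)) for (i in seq_len(nrow(ai))) {
      span <- nchar(ai$seq[i]) + max(0, -ai$gap_len[i]) -
        max(0, ai$gap_len[i])
      s <- ai$start[i]; e <- min(L, s + span - 1)
      hit[s:e] <- TRUE
    }
    isN <- strsplit(contigs[[ct]], "")[[1]] == "N"
    cov_tot <- cov_tot + sum(hit & !isN)
    den_tot <- den_tot + sum(!isN)
  }
  cov_tot / den_tot
}

# Successive-difference gap scan.
oracle_gaps <- function(pos, min_gap) {
  d <- diff(pos)
  i <- which(d >= min_gap)
  data.frame(start = pos[i], end = pos[i + 1], span = d[i])
}

# Dense GLS per-marker solve with V = sg2 * G + se2 * I.
oracle_gls <- function(y, x, G, sg2, se2) {
  n <- length(y)
  V <- sg2 * G + se2 * diag(n)
  X <- cbind(1, x)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  b <- solve(XtVX, t(X) %*% Vi %*% y)
  list(effect = b[2], se = sqrt(solve(XtVX)[2, 2]))
}

# A genome of length L carrying host-derived tracts totalling frac of its
# length, used by the contamination tests (uses the caller's RNG stream).
contaminated_genome <- function(host_seq, L, frac, tag) {
  g <- random_dna(L)
  tract <- round(frac * L)
  if (tract > 0) {
    src <- sample.int(nchar(host_seq) - tract, 1)
    at <- sample.int(L - tract, 1)
    g <- paste0(substr(g, 1, at - 1), substr(host_seq, src, src + tract - 1),
                substr(g, at + tract, L))
  }
  setNames(g, tag)
}
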