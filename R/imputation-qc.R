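# Imputation quality control: per-variant accuracy (correlation between
# imputed and sequence-called dosages), MAF filtering and binning, the
# positional accuracy track, gap detection from inter-variant distances,
# and sliding-window flagging of low-accuracy runs that mark candidate
# misassembled regions.

#' Per-variant imputation accuracy track
#'
#' Pearson correlation between imputed and called dosages at each variant,
#' computed over pairwise-complete individuals; NA when either vector is
#' constant (zero variance) or fewer than two complete pairs remain.
#'
#' @param imputed n x m numeric matrix of imputed dosages in `[0, 2]`.
#' @param truth n x m matrix of sequence-called dosages `{0, 1, 2}`.
#' @param variants optional data.frame with columns `contig`, `position`
#'   (and optionally `maf`) describing the m columns; defaults are taken
#'   from a `genotype_panel` when `imputed` carries one.
#' @return data.frame of class `accuracy_track`: `contig`, `position`,
#'   `maf` (NA when unknown), `r`, `r2`, `n` (informative individuals),
#'   sorted by contig then position.
#' @export
per_variant_accuracy <- function(imputed, truth, variants = NULL) {
  if (inherits(imputed, "genotype_panel")) {
    if (is.null(variants)) variants <- panel_variants(imputed)
    if (is.null(imputed$imputed))
      stop("panel has no imputed dosages; run corrupt_to_imputed() first")
    imputed <- imputed$imputed
  }
  if (inherits(truth, "genotype_panel")) {
    if (is.null(variants)) variants <- panel_variants(truth)
    truth <- truth$true
  }
  if (!all(dim(imputed) == dim(truth)))
    stop("imputed and truth matrices must have identical dimensions")
  if (nrow(imputed) < 2) stop("need at least 2 individuals")
  m <- ncol(imputed)
  if (is.null(variants))
    variants <- data.frame(contig = "contig1", position = seq_len(m))
  stopifnot(nrow(variants) == m)
  r <- n_inf <- numeric(m)
  for (j in seq_len(m)) {
    ok <- is.finite(imputed[, j]) & is.finite(truth[, j])
    n_inf[j] <- sum(ok)
    r[j] <- if (n_inf[j] >= 2 && sd(imputed[ok, j]) > 0 &&
                sd(truth[ok, j]) > 0)
      cor(imputed[ok, j], truth[ok, j]) else NA_real_
  }
  out <- data.frame(contig = variants$contig, position = variants$position,
                    maf = if ("maf" %in% names(variants)) variants$maf
                          else NA_real_,
                    r = r, r2 = r^2, n = as.integer(n_inf))
  out <- out[order(out$contig, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("accuracy_track", "data.frame")
  out
}

#' Drop rare variants from a track or panel
#'
#' Retains variants whose minor allele frequency is strictly greater than
#' the threshold.
#'
#' @param x an `accuracy_track` (or any data.frame with a `maf` column) or
#'   a `genotype_panel`.
#' @param threshold MAF cut; variants at exactly the threshold are dropped.
#' @return same type as `x`, filtered.
#' @export
maf_filter <- function(x, threshold = 0.05) {
  if (inherits(x, "genotype_panel")) {
    keep <- x$map$maf > threshold
    x$map <- x$map[keep, , drop = FALSE]
    rownames(x$map) <- NULL
    x$true <- x$true[, keep, drop = FALSE]
    if (!is.null(x$imputed)) x$imputed <- x$imputed[, keep, drop = FALSE]
    x$m <- sum(keep)
    x
  } else {
    stopifnot("maf" %in% names(x))
    out <- x[!is.na(x$maf) & x$maf > threshold, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
}

#' Mean accuracy per MAF bin
#'
#' Bins are left-open, right-closed on the given increasing edges. NA
#' accuracies are excluded from means and counts; empty bins are reported
#' with `n = 0` and `mean_r = NA` rather than zero.
#'
#' @param track an `accuracy_track`.
#' @param edges increasing numeric bin edges (length >= 2).
#' @return data.frame with `bin`, `maf_lo`, `maf_hi`, `n`, `mean_r`,
#'   `mean_r2`.
#' @export
bin_by_maf <- function(track, edges = c(0, 0.01, 0.05, 0.1, 0.2, 0.5)) {
  stopifnot(length(edges) >= 2, all(diff(edges) > 0),
            "maf" %in% names(track))
  idx <- cut(track$maf, edges, labels = FALSE)
  nb <- length(edges) - 1
  out <- data.frame(bin = sprintf("(%g,%g]", edges[-length(edges)],
                                  edges[-1]),
                    maf_lo = edges[-length(edges)], maf_hi = edges[-1],
                    n = 0L, mean_r = NA_real_, mean_r2 = NA_real_)
  for (b in seq_len(nb)) {
    rr <- track$r[!is.na(idx) & idx == b]
    rr <- rr[!is.na(rr)]
    out$n[b] <- length(rr)
    if (length(rr)) {
      out$mean_r[b] <- mean(rr)
      out$mean_r2[b] <- mean(rr^2)
    }
  }
  out
}

#' Detect assembly gaps from inter-variant distances
#'
#' A gap is an interval between consecutive track positions on the same
#' contig whose span is at least `min_gap` bases; reported boundaries are
#' the flanking variant positions, so the gap length is the raw coordinate
#' difference.
#'
#' @param track an `accuracy_track` (or data.frame with `contig`,
#'   `position`), positions sorted within contig.
#' @param min_gap minimum inter-variant distance to flag, in bases.
#' @return data.frame of flagged regions: `contig`, `start`, `end`, `kind`
#'   (`"gap"`), `span_bp`, `span_mb` (two decimals).
#' @export
detect_gaps <- function(track, min_gap = 1e6) {
  stopifnot(all(c("contig", "position") %in% names(track)), min_gap > 0)
  out <- list()
  for (ctg in unique(track$contig)) {
    pos <- track$position[track$contig == ctg]
    if (is.unsorted(pos)) stop("positions must be sorted within contig")
    if (length(pos) < 2) next
    d <- diff(pos)
    hit <- which(d >= min_gap)
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(
        contig = ctg, start = pos[hit], end = pos[hit + 1], kind = "gap",
        span_bp = d[hit], span_mb = round_half_up(d[hit] / 1e6, 2))
  }
  if (!length(out))
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), kind = character(),
                      span_bp = numeric(), span_mb = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag low-accuracy runs by a sliding-window scan
#'
#' Windows of `window_bp` bases advance in steps of `window_bp / 2`; a
#' window is flagged when it holds at least `min_variants` variants and the
#' median of their defined accuracies is below `r_threshold`. Overlapping
#' or adjacent flagged windows are merged into one region. NA accuracies do
#' not enter the median but do count toward the variant total.
#'
#' @param track an `accuracy_track`.
#' @param window_bp window width in bases.
#' @param r_threshold flag when the window median r falls below this.
#' @param min_variants minimum variants per window.
#' @return data.frame of flagged regions: `contig`, `start`, `end`, `kind`
#'   (`"low_accuracy_run"`), `mean_r`, `n_variants`.
#' @export
flag_low_accuracy_runs <- function(track, window_bp = 250000,
                                   r_threshold = 0.3, min_variants = 10) {
  stopifnot(window_bp > 0, r_threshold > 0, min_variants > 0)
  regions <- list()
  for (ctg in unique(track$contig)) {
    tr <- track[track$contig == ctg, , drop = FALSE]
    pos <- tr$position
    if (is.unsorted(pos)) stop("positions must be sorted within contig")
    step <- window_bp / 2
    starts <- seq(min(pos), max(pos), by = step)
    flagged <- list()
    for (s in starts) {
      inw <- pos >= s & pos < s + window_bp
      if (sum(inw) < min_variants) next
      rr <- tr$r[inw]
      rr_def <- rr[!is.na(rr)]
      if (length(rr_def) && median(rr_def) < r_threshold)
        flagged[[length(flagged) + 1]] <- c(s, s + window_bp)
    }
    if (!length(flagged)) next
    fl <- do.call(rbind, flagged)
    fl <- fl[order(fl[, 1]), , drop = FALSE]
    # merge overlapping/adjacent windows
    merged <- list(fl[1, ])
    for (i in seq_len(nrow(fl))[-1]) {
      last <- merged[[length(merged)]]
      if (fl[i, 1] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], fl[i, 2]))
      } else merged[[length(merged) + 1]] <- fl[i, ]
    }
    for (mg in merged) {
      inr <- pos >= mg[1] & pos < mg[2]
      rr <- tr$r[inr]
      regions[[length(regions) + 1]] <- data.frame(
        contig = ctg, start = mg[1], end = mg[2],
        kind = "low_accuracy_run",
        mean_r = mean(rr, na.rm = TRUE), n_variants = sum(inr))
    }
  }
  if (!length(regions))
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), kind = character(),
                      mean_r = numeric(), n_variants = integer()))
  res <- do.call(rbind, regions)
  rownames(res) <- NULL
  res
}
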