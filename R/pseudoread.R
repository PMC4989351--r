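# Pseudo-read contamination enrichment: exhaustively tile a candidate
# genome with simulated paired reads, map them against a host reference,
# and compare mapping rates across species. A suspect genome that carries
# host-derived sequence maps at a much higher rate than clean controls.

#' Pseudo-read generation configuration
#'
#' @param read_length mate length in bases.
#' @param fragment_min,fragment_max fragment length bounds (inclusive);
#'   lengths are drawn i.i.d. discrete uniform.
#' @param step distance between successive fragment anchors in bases.
#' @param seed integer seed for the fragment-length draws.
#' @return a `pseudoread_config` list.
#' @export
pseudoread_config <- function(read_length = 100, fragment_min = 200,
                              fragment_max = 500, step = 1, seed = 1) {
  stopifnot(step >= 1, read_length >= 1, read_length <= fragment_min,
            fragment_min <= fragment_max)
  structure(list(read_length = as.integer(read_length),
                 fragment_min = as.integer(fragment_min),
                 fragment_max = as.integer(fragment_max),
                 step = as.integer(step), seed = as.integer(seed)),
            class = "pseudoread_config")
}

#' Tile a genome with paired pseudo-reads
#'
#' Anchors a fragment at every `step`-th position of every contig, draws its
#' length i.i.d. discrete uniform on `[fragment_min, fragment_max]`, and
#' emits mate 1 as the first `read_length` bases of the fragment and mate 2
#' as the reverse complement of its last `read_length` bases. Fragments
#' whose drawn length overruns the contig end are skipped (anchored-start
#' policy), so for a contig of length L with step 1 the pair count lies
#' between `L - fragment_max + 1` and `L - fragment_min + 1`.
#'
#' @param genome named character vector of contig sequences (or a
#'   `reference_genome`).
#' @param config a [pseudoread_config()].
#' @return a [read_pairs] object; names carry the source contig, anchor and
#'   fragment length.
#' @export
generate_pseudoreads <- function(genome, config = pseudoread_config()) {
  if (inherits(genome, "reference_genome")) genome <- genome$contigs
  stopifnot(is.character(genome), length(genome) >= 1)
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  rl <- config$read_length
  ids <- seqs1 <- seqs2 <- vector("list", length(genome))
  with_seed(config$seed, {
    for (ci in seq_along(genome)) {
      seq <- genome[[ci]]
      L <- nchar(seq)
      if (L < config$fragment_min) {
        warning("contig ", names(genome)[ci], " shorter than fragment_min; ",
                "no pseudo-reads generated")
        next
      }
      anchors <- seq.int(1L, L, by = config$step)
      flen <- config$fragment_min - 1L +
        sample.int(config$fragment_max - config$fragment_min + 1L,
                   length(anchors), replace = TRUE)
      fend <- anchors + flen - 1L
      fit <- fend <= L  # anchors whose drawn fragment overruns are skipped
      anchors <- anchors[fit]; fend <- fend[fit]
      if (!length(anchors)) next
      seqs1[[ci]] <- substr(rep(seq, length(anchors)), anchors,
                            anchors + rl - 1L)
      seqs2[[ci]] <- revcomp(substr(rep(seq, length(anchors)),
                                    fend - rl + 1L, fend))
      ids[[ci]] <- sprintf("pseudo|src=%s|start=%d|flen=%d",
                           names(genome)[ci], anchors,
                           fend - anchors + 1L)
    }
  })
  read_pairs(id = unlist(ids), seq1 = unlist(seqs1), seq2 = unlist(seqs2))
}

#' Mapping rate of pseudo-reads against a host reference
#'
#' Aligns with the package matcher under its standard acceptance rules and
#' reports the fraction of pairs with at least one mate mapped (pair level)
#' alongside the fraction of individual mates mapped (read level).
#'
#' @param reads a [read_pairs] of pseudo-reads.
#' @param host_ref a `reference_genome` (or named contig vector).
#' @param ... passed to [align_reads()].
#' @return list with `pair_rate`, `read_rate`, `n_pairs`.
#' @export
map_rate <- function(reads, host_ref, ...) {
  stopifnot(length(reads) >= 1)
  aln <- align_reads(reads, host_ref, ...)
  a <- aln$alignments
  ok <- a$status == "mapped"
  ok1 <- ok[a$mate == 1]; ok2 <- ok[a$mate == 2]
  list(pair_rate = mean(ok1 | ok2), read_rate = mean(ok),
       n_pairs = length(reads))
}

#' Fold-enrichment verdict for a suspect genome
#'
#' One ratio per control species: suspect mapping rate divided by the
#' control's. Verdict is `"contaminated"` when the minimum ratio is at least
#' `threshold`, `"negative"` otherwise, and `"indeterminate"` when the
#' suspect and every control rate are all zero. A zero control rate with a
#' positive suspect rate gives an infinite ratio, flagged in
#' `infinite_ratio`.
#'
#' @param suspect_rate suspect mapping rate in `[0, 1]`.
#' @param control_rates named numeric vector of control rates.
#' @param threshold minimum fold-enrichment to call contamination.
#' @return list of class `enrichment_report`: `suspect_rate`,
#'   `control_rates`, `ratios`, `min_ratio`, `infinite_ratio`, `threshold`,
#'   `verdict`.
#' @export
fold_enrichment <- function(suspect_rate, control_rates, threshold = 5) {
  stopifnot(length(suspect_rate) == 1, length(control_rates) >= 1,
            suspect_rate >= 0, suspect_rate <= 1,
            all(control_rates >= 0), all(control_rates <= 1), threshold > 0)
  if (suspect_rate == 0 && all(control_rates == 0)) {
    ratios <- rep(NA_real_, length(control_rates))
    names(ratios) <- names(control_rates)
    verdict <- "indeterminate"
    min_ratio <- NA_real_
  } else {
    ratios <- suspect_rate / control_rates
    min_ratio <- min(ratios)
    verdict <- if (min_ratio >= threshold) "contaminated" else "negative"
  }
  structure(list(suspect_rate = suspect_rate,
                 control_rates = control_rates, ratios = ratios,
                 min_ratio = min_ratio,
                 infinite_ratio = any(is.infinite(ratios)),
                 threshold = threshold, verdict = verdict),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("Pseudo-read fold-enrichment report\n")
  cat(sprintf("  suspect mapping rate: %.4g\n", x$suspect_rate))
  for (i in seq_along(x$control_rates))
    cat(sprintf("  vs %s (rate %.4g): %.3g-fold\n",
                if (!is.null(names(x$control_rates)))
                  names(x$control_rates)[i] else paste0("control", i),
                x$control_rates[i], x$ratios[i]))
  cat(sprintf("  verdict: %s (threshold %g-fold)\n", x$verdict, x$threshold))
  if (isTRUE(x$infinite_ratio))
    cat("  note: at least one control rate was zero (infinite ratio)\n")
  invisible(x)
}

#' Run the full enrichment screen for one suspect and several controls
#'
#' Generates pseudo-reads for the suspect and each control genome, maps all
#' of them against the host reference, and computes the fold-enrichment
#' report.
#'
#' @param suspect named contig vector (or `reference_genome`).
#' @param controls named list of genomes.
#' @param host_ref the host `reference_genome`.
#' @param config a [pseudoread_config()]; each genome gets a distinct
#'   child seed.
#' @param threshold verdict threshold for [fold_enrichment()].
#' @return `enrichment_report` with an extra `rates` data.frame (species,
#'   pair_rate, read_rate, n_pairs).
#' @export
enrichment_screen <- function(suspect, controls, host_ref,
                              config = pseudoread_config(), threshold = 5) {
  stopifnot(length(controls) >= 1)
  if (is.null(names(controls)))
    names(controls) <- paste0("control", seq_along(controls))
  rate_of <- function(genome, tag) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, tag)
    map_rate(generate_pseudoreads(genome, cfg), host_ref)
  }
  srate <- rate_of(suspect, "suspect")
  crates <- lapply(names(controls),
                   function(nm) rate_of(controls[[nm]], nm))
  names(crates) <- names(controls)
  rep <- fold_enrichment(srate$pair_rate,
                         vapply(crates, `[[`, numeric(1), "pair_rate"),
                         threshold = threshold)
  rep$rates <- data.frame(
    species = c("suspect", names(controls)),
    pair_rate = c(srate$pair_rate,
                  vapply(crates, `[[`, numeric(1), "pair_rate")),
    read_rate = c(srate$read_rate,
                  vapply(crates, `[[`, numeric(1), "read_rate")),
    n_pairs = c(srate$n_pairs, vapply(crates, `[[`, numeric(1), "n_pairs")))
  rep
}
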