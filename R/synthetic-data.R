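# Synthetic-data generators. These emulate the statistical structure the
# diagnostics assume -- diploid genomes with known variants, paired-end reads
# with a 200-500 bp fragment distribution, host/contaminant mixtures,
# references with planted gaps or misassemblies, imputed-vs-true genotype
# panels with MAF- and position-dependent error, and phenotypes with planted
# QTL -- so that every downstream stage can be audited against ground truth.
# Every generator is deterministic given its seed; read names carry their
# source (contig, haplotype, start, fragment length) for lossless accounting.

#' Generate a random reference genome with optional assembly gaps
#'
#' Gap intervals (half-open, 0-based) are rendered as runs of `N`.
#'
#' @param n_contigs number of contigs.
#' @param lengths integer vector of contig lengths (recycled to `n_contigs`).
#' @param gap_spec optional data.frame (`contig`, `start`, `end`) of gaps;
#'   contig may be given by name (`"chr1"`, ...) or index.
#' @param seed integer seed; the same seed yields a byte-identical genome.
#' @return a [reference_genome].
#' @export
make_reference <- function(n_contigs = 1, lengths = 1e5, gap_spec = NULL,
                           seed = 1) {
  stopifnot(n_contigs >= 1, all(lengths > 0))
  lengths <- rep_len(as.integer(lengths), n_contigs)
  nms <- paste0("chr", seq_len(n_contigs))
  contigs <- with_seed(seed, vapply(lengths, random_dna, ""))
  names(contigs) <- nms
  if (!is.null(gap_spec) && nrow(gap_spec)) {
    check_regions(gap_spec, "gap")
    if (is.numeric(gap_spec$contig)) gap_spec$contig <- nms[gap_spec$contig]
    for (ct in unique(gap_spec$contig)) {
      g <- gap_spec[gap_spec$contig == ct, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
        stop("overlapping gaps requested on contig ", ct)
      for (i in seq_len(nrow(g)))
        substr(contigs[[ct]], g$start[i] + 1, g$end[i]) <-
          strrep("N", g$end[i] - g$start[i])
    }
  }
  reference_genome(contigs, gaps = gap_spec)
}

#' Plant SNPs and short indels on a reference, producing a diploid donor
#'
#' Variants are placed on non-gap positions with at least 10 bp spacing so
#' no two variants fall within one indel's span. Heterozygous variants are
#' carried by exactly one haplotype; truth records use anchored, left-aligned
#' (VCF-style) alleles with 1-based positions.
#'
#' @param ref a [reference_genome].
#' @param n_snp,n_indel counts of SNPs and indels to plant.
#' @param het_fraction probability that a variant is heterozygous.
#' @param seed integer seed.
#' @param indel_max maximum indel length in bases (1..`indel_max`).
#' @return an object of class `donor_genome`: haplotype sequences `hap1`,
#'   `hap2` (named per contig) and a `truth` data.frame (`CHROM`, `POS`,
#'   `REF`, `ALT`, `GT`, `CLASS`, `HAP`).
#' @export
plant_variants <- function(ref, n_snp, n_indel, het_fraction = 0.5, seed = 1,
                           indel_max = 9) {
  stopifnot(inherits(ref, "reference_genome"), n_snp >= 0, n_indel >= 0,
            het_fraction >= 0, het_fraction <= 1, indel_max >= 1,
            indel_max <= 9)
  n_var <- n_snp + n_indel
  with_seed(seed, {
    lens <- contig_lengths(ref)
    # candidate positions: non-gap, away from contig edges, >= 10 bp apart
    picks <- list()
    for (ct in names(lens)) {
      chars <- strsplit(ref$contigs[[ct]], "")[[1]]
      ok <- which(chars != "N")
      ok <- ok[ok >= 2 & ok <= lens[[ct]] - indel_max - 1]
      # anchored indels need a non-N anchor and non-N span
      picks[[ct]] <- ok
    }
    avail <- vapply(picks, function(p) length(p) %/% 10L, 0L)
    if (n_var > sum(avail))
      stop("requested ", n_var, " variants but only ~", sum(avail),
           " spaced positions are available")
    # allocate variants to contigs proportionally to available space
    alloc <- if (n_var == 0) integer(length(lens)) else
      as.vector(rmultinom(1, n_var, avail / sum(avail)))
    truth <- list()
    hap1 <- hap2 <- ref$contigs
    for (k in seq_along(lens)) {
      ct <- names(lens)[k]
      if (alloc[k] == 0) next
      pos <- sort(sample(picks[[ct]], min(length(picks[[ct]]), alloc[k] * 12)))
      keep <- c(TRUE, diff(pos) >= 10)[seq_along(pos)]
      # greedy spacing filter
      sel <- integer(0); last <- -Inf
      for (p in pos) if (p - last >= 10) { sel <- c(sel, p); last <- p }
      if (length(sel) < alloc[k])
        stop("could not place ", alloc[k], " spaced variants on ", ct)
      sel <- sort(sample(sel, alloc[k]))
      is_snp <- sample(rep(c(TRUE, FALSE),
                           times = round(alloc[k] * c(n_snp, n_indel) / n_var)))
      is_snp <- rep_len(is_snp, alloc[k])
      het <- runif(alloc[k]) < het_fraction
      hap_of <- ifelse(het, sample(1:2, alloc[k], replace = TRUE), 0L)
      recs <- vector("list", alloc[k])
      for (i in seq_len(alloc[k])) {
        p <- sel[i]
        rb <- substr(ref$contigs[[ct]], p, p)
        if (is_snp[i]) {
          alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
          recs[[i]] <- data.frame(CHROM = ct, POS = p, REF = rb, ALT = alt,
                                  GT = if (het[i]) "het" else "hom",
                                  CLASS = "SNP", HAP = hap_of[i])
        } else {
          g <- sample(indel_max, 1)
          if (runif(1) < 0.5) { # insertion after p
            ins <- random_dna(g)
            recs[[i]] <- data.frame(CHROM = ct, POS = p, REF = rb,
                                    ALT = paste0(rb, ins),
                                    GT = if (het[i]) "het" else "hom",
                                    CLASS = "indel", HAP = hap_of[i])
          } else {            # deletion of g bases after p
            del <- substr(ref$contigs[[ct]], p, p + g)
            recs[[i]] <- data.frame(CHROM = ct, POS = p, REF = del, ALT = rb,
                                    GT = if (het[i]) "het" else "hom",
                                    CLASS = "indel", HAP = hap_of[i])
          }
        }
      }
      tt <- do.call(rbind, recs)
      truth[[ct]] <- tt
      # apply edits right-to-left so earlier coordinates stay valid
      for (h in 1:2) {
        seqc <- ref$contigs[[ct]]
        for (i in rev(seq_len(nrow(tt)))) {
          if (tt$GT[i] == "het" && tt$HAP[i] != h) next
          p <- tt$POS[i]
          seqc <- paste0(substr(seqc, 1, p - 1), tt$ALT[i],
                         substr(seqc, p + nchar(tt$REF[i]), nchar(seqc)))
        }
        if (h == 1) hap1[[ct]] <- seqc else hap2[[ct]] <- seqc
      }
    }
    truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
    if (is.null(truth))
      truth <- data.frame(CHROM = character(), POS = integer(),
                          REF = character(), ALT = character(),
                          GT = character(), CLASS = character(),
                          HAP = integer())
    # canonicalize indel representation (left-aligned) so truth records
    # compare 1:1 with normalized calls
    for (i in seq_len(nrow(truth))) {
      nv <- normalize_variant(ref$contigs[[truth$CHROM[i]]], truth$POS[i],
                              truth$REF[i], truth$ALT[i])
      truth$POS[i] <- nv$pos; truth$REF[i] <- nv$ref; truth$ALT[i] <- nv$alt
    }
    truth <- truth[order(truth$CHROM, truth$POS), , drop = FALSE]
    rownames(truth) <- NULL
    structure(list(hap1 = hap1, hap2 = hap2, truth = truth, reference = ref),
              class = "donor_genome")
  })
}

#' @export
print.donor_genome <- function(x, ...) {
  cat("donor_genome:", length(x$hap1), "contig(s),", nrow(x$truth),
      "truth variants (", sum(x$truth$CLASS == "SNP"), "SNP /",
      sum(x$truth$CLASS == "indel"), "indel )\n")
  invisible(x)
}

#' Read-simulation configuration
#'
#' @param read_length read length in bases (2 x `read_length` per fragment).
#' @param fragment_min,fragment_max fragment-length bounds; lengths are drawn
#'   discrete-uniform on `[fragment_min, fragment_max]` (mean 350 with the
#'   defaults).
#' @param depth target fold-coverage of the genome.
#' @param error_rate per-base substitution error probability.
#' @param bias coverage-bias model: `"poisson"` (uniform fragment starts) or
#'   `"clustered"` (gamma-mixed window rates, yielding more uncovered
#'   sequence than Poisson at equal depth).
#' @param seed integer seed.
#' @return a list of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 100, fragment_min = 200,
                            fragment_max = 500, depth = 10, error_rate = 0,
                            bias = c("poisson", "clustered"), seed = 1) {
  bias <- match.arg(bias)
  stopifnot(fragment_min <= fragment_max, depth >= 0, read_length >= 1,
            error_rate >= 0, error_rate <= 1,
            read_length <= fragment_min)
  structure(list(read_length = read_length, fragment_min = fragment_min,
                 fragment_max = fragment_max, depth = depth,
                 error_rate = error_rate, bias = bias, seed = seed),
            class = "read_sim_config")
}

# simulate n_frags pairs from a set of haplotype sequences (single haplotype
# per call); used by simulate_reads and mix_contaminants
sim_pairs_from <- function(seqs, n_frags, config, tag = "frag") {
  rl <- config$read_length
  lens <- nchar(seqs)
  keep <- lens >= config$fragment_max
  if (!all(keep)) {
    warning("skipping ", sum(!keep), " contig(s) shorter than fragment_max")
    seqs <- seqs[keep]; lens <- lens[keep]
  }
  if (length(seqs) == 0 || n_frags == 0)
    return(read_pairs())
  ci <- sample.int(length(seqs), n_frags, replace = TRUE,
                   prob = lens / sum(lens))
  flen <- sample(config$fragment_min:config$fragment_max, n_frags,
                 replace = TRUE)
  maxstart <- lens[ci] - flen + 1
  if (config$bias == "poisson") {
    start <- floor(runif(n_frags) * maxstart) + 1
  } else {
    # clustered: gamma-weighted 2-kb windows, then uniform within window
    start <- integer(n_frags)
    for (s in unique(ci)) {
      idx <- which(ci == s)
      nw <- max(1L, lens[s] %/% 2000L)
      w <- rgamma(nw, shape = 0.2, rate = 1)
      win <- sample.int(nw, length(idx), replace = TRUE, prob = w / sum(w))
      st <- (win - 1) * 2000L + floor(runif(length(idx)) * 2000L) + 1L
      start[idx] <- pmin(st, maxstart[idx])
    }
  }
  frag_of <- function(i) substr(seqs[[ci[i]]], start[i], start[i] + flen[i] - 1)
  m1 <- unname(substring(seqs[ci], start, start + rl - 1))
  m2 <- revcomp(unname(substring(seqs[ci], start + flen - rl,
                                 start + flen - 1)))
  if (config$error_rate > 0) {
    m1 <- add_seq_errors(m1, config$error_rate)
    m2 <- add_seq_errors(m2, config$error_rate)
  }
  id <- sprintf("%s%06d|src=%s|start=%d|flen=%d", tag, seq_len(n_frags),
                names(seqs)[ci], start, flen)
  read_pairs(id, m1, m2)
}

# substitute random bases at rate e (per base, independent)
add_seq_errors <- function(reads, e) {
  n_err <- rbinom(length(reads), nchar(reads), e)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    ch <- strsplit(reads[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn per the configuration; mate 1 is the first
#' `read_length` bases of the fragment, mate 2 the reverse complement of the
#' last `read_length` bases. For a diploid donor, each fragment samples one
#' haplotype at random. The expected base yield equals
#' `depth * genome length` by construction. Read names record contig,
#' haplotype, start and fragment length.
#'
#' @param genome a [reference_genome], `donor_genome` or named character
#'   vector of sequences.
#' @param config a [read_sim_config].
#' @return a [read_pairs] object.
#' @export
simulate_reads <- function(genome, config) {
  stopifnot(inherits(config, "read_sim_config"))
  with_seed(config$seed, {
    if (inherits(genome, "donor_genome")) {
      lens <- nchar(genome$hap1)
      total <- sum(lens)
      n_frags <- round(config$depth * total / (2 * config$read_length))
      hap_pick <- sample(1:2, n_frags, replace = TRUE)
      rp1 <- sim_pairs_from(setNames(genome$hap1,
                                     paste0(names(genome$hap1), ":h1")),
                            sum(hap_pick == 1), config)
      rp2 <- sim_pairs_from(setNames(genome$hap2,
                                     paste0(names(genome$hap2), ":h2")),
                            sum(hap_pick == 2), config)
      out <- c(rp1, rp2)
      out$id <- sprintf("frag%06d|%s", seq_along(out$id),
                        sub("^frag[0-9]+\\|", "", out$id))
      out
    } else {
      seqs <- if (inherits(genome, "reference_genome")) genome$contigs
      else genome
      total <- sum(nchar(seqs))
      n_frags <- round(config$depth * total / (2 * config$read_length))
      sim_pairs_from(seqs, n_frags, config)
    }
  })
}

#' Mix host reads with simulated contaminant reads
#'
#' @param host_reads host [read_pairs].
#' @param contaminant_genomes named list of genomes (named character vectors
#'   or [reference_genome]s), one per contaminant source.
#' @param proportions named numeric vector of target read-pair fractions per
#'   contaminant (summing to at most 1; the host takes the remainder).
#' @param config a [read_sim_config] (read/fragment geometry for the
#'   contaminant reads).
#' @return list with `reads` (combined, shuffled [read_pairs]) and `labels`
#'   (data.frame `read`, `source` ground truth, suitable for a sidecar TSV).
#' @export
mix_contaminants <- function(host_reads, contaminant_genomes, proportions,
                             config) {
  stopifnot(sum(proportions) <= 1, !is.null(names(proportions)),
            all(names(proportions) %in% names(contaminant_genomes)))
  with_seed(child_seed(config$seed, "mix"), {
    n_host <- length(host_reads)
    if (length(proportions) == 0 || sum(proportions) == 0) {
      labels <- data.frame(read = host_reads$id, source = "host")
      return(list(reads = host_reads, labels = labels))
    }
    total <- round(n_host / (1 - sum(proportions)))
    parts <- list(host_reads)
    src <- list(rep("host", n_host))
    for (nm in names(proportions)) {
      g <- contaminant_genomes[[nm]]
      seqs <- if (inherits(g, "reference_genome")) g$contigs else g
      names(seqs) <- paste0(nm, ":", names(seqs))
      n_i <- rbinom(1, total, proportions[[nm]])
      rp <- sim_pairs_from(seqs, n_i, config, tag = paste0(nm, "_frag"))
      parts[[length(parts) + 1]] <- rp
      src[[length(src) + 1]] <- rep(nm, length(rp))
    }
    reads <- do.call(c, parts)
    source <- unlist(src)
    ord <- sample.int(length(reads))
    reads <- reads[ord]
    labels <- data.frame(read = reads$id, source = source[ord])
    list(reads = reads, labels = labels)
  })
}

#' Plant a misassembly into a reference genome
#'
#' Modes: `shuffle_blocks` permutes fixed-size blocks within the region,
#' `delete` removes the region, `invert` reverse-complements it. The edit is
#' recorded in the returned genome's `misassembly` truth table.
#'
#' @param ref a [reference_genome].
#' @param contig contig name.
#' @param start,end half-open 0-based region bounds.
#' @param mode one of `"shuffle_blocks"`, `"delete"`, `"invert"`.
#' @param block_size block size for `shuffle_blocks` (bases).
#' @param seed seed for the block permutation.
#' @return a [reference_genome] with the edit applied and recorded.
#' @export
make_misassembled_reference <- function(ref, contig, start, end,
                                        mode = c("shuffle_blocks", "delete",
                                                 "invert"),
                                        block_size = 10000, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "reference_genome"),
            contig %in% names(ref$contigs),
            start >= 0, end > start, end <= nchar(ref$contigs[[contig]]))
  if (!is.null(ref$gaps) && nrow(ref$gaps)) {
    g <- ref$gaps[ref$gaps$contig == contig, , drop = FALSE]
    if (nrow(g) && any(g$start < end & g$end > start))
      stop("misassembly region overlaps an annotated gap")
  }
  seqc <- ref$contigs[[contig]]
  region <- substr(seqc, start + 1, end)
  newregion <- switch(mode,
    delete = "",
    invert = revcomp(region),
    shuffle_blocks = with_seed(seed, {
      n <- nchar(region)
      nb <- ceiling(n / block_size)
      blocks <- substring(region, (seq_len(nb) - 1) * block_size + 1,
                          pmin(seq_len(nb) * block_size, n))
      paste(blocks[sample.int(nb)], collapse = "")
    }))
  contigs <- ref$contigs
  contigs[[contig]] <- paste0(substr(seqc, 1, start), newregion,
                              substr(seqc, end + 1, nchar(seqc)))
  rec <- data.frame(contig = contig, start = start, end = end, mode = mode)
  reference_genome(contigs, gaps = if (mode == "delete") NULL else ref$gaps,
                   misassembly = rbind(ref$misassembly, rec))
}

#' Simulate a genotype panel with drawn MAFs and optional LD
#'
#' Haplotypes are generated from a Gaussian copula with AR(1) correlation
#' `exp(-distance / ld_decay)` between adjacent variants (no LD when
#' `ld_decay = 0`), then thresholded at each variant's drawn allele
#' frequency; dosage = sum of the two haplotypes.
#'
#' @param n individuals.
#' @param m variants.
#' @param maf_dist function of one argument returning `m` MAFs in (0, 0.5],
#'   or a fixed numeric vector.
#' @param ld_decay LD decay scale in bp (0 disables LD).
#' @param chrom_length chromosome length over which positions are placed.
#' @param contig contig name used in the map.
#' @param seed integer seed.
#' @return an object of class `genotype_panel`: `true` (n x m dosage matrix),
#'   `imputed` (`NULL` until [corrupt_to_imputed()]), `map` (data.frame
#'   `contig`, `pos`, `maf`).
#' @export
simulate_genotype_panel <- function(n, m, maf_dist = NULL, ld_decay = 0,
                                    chrom_length = 1e6, contig = "chr1",
                                    seed = 1) {
  stopifnot(n >= 2, m >= 1)
  with_seed(seed, {
    maf <- if (is.null(maf_dist)) runif(m, 0.05, 0.5)
    else if (is.function(maf_dist)) maf_dist(m) else rep_len(maf_dist, m)
    stopifnot(all(maf > 0), all(maf <= 0.5))
    pos <- sort(sample.int(chrom_length, m))
    thr <- qnorm(maf)
    haps <- vector("list", 2)
    for (h in 1:2) {
      z <- matrix(0, n, m)
      z[, 1] <- rnorm(n)
      if (m > 1) {
        d <- diff(pos)
        rho <- if (ld_decay > 0) exp(-d / ld_decay) else rep(0, m - 1)
        for (j in 2:m)
          z[, j] <- rho[j - 1] * z[, j - 1] +
            sqrt(1 - rho[j - 1]^2) * rnorm(n)
      }
      haps[[h]] <- sweep(z, 2, thr, `<`) * 1L
    }
    true <- haps[[1]] + haps[[2]]
    structure(list(true = true, imputed = NULL,
                   map = data.frame(contig = contig, pos = pos, maf = maf),
                   n = n, m = m),
              class = "genotype_panel")
  })
}

# variant table of a genotype_panel in accuracy-track layout
panel_variants <- function(panel) {
  data.frame(contig = panel$map$contig, position = panel$map$pos,
             maf = panel$map$maf)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", x$n, "individuals x", x$m, "variants",
      if (!is.null(x$imputed)) "(imputed dosages present)" else "", "\n")
  invisible(x)
}

#' Corrupt true genotypes into imputed dosages
#'
#' Each cell is replaced, with probability
#' `base_error * (1 + maf_error_slope * (0.5 - MAF)/0.5)` (capped at 1), by a
#' random genotype drawn at the variant's allele frequency, so expected
#' accuracy decreases as MAF decreases (rarer variants impute worse). Within
#' `bad_regions` the imputed column is permuted across individuals, driving
#' accuracy to ~0, emulating imputation across a misassembled interval.
#'
#' @param panel a `genotype_panel`.
#' @param base_error error probability at MAF = 0.5.
#' @param maf_error_slope relative error inflation at MAF -> 0.
#' @param bad_regions optional data.frame (`contig`, `start`, `end`),
#'   half-open 0-based.
#' @param seed integer seed.
#' @return the panel with `imputed` filled.
#' @export
corrupt_to_imputed <- function(panel, base_error = 0.08, maf_error_slope = 3,
                               bad_regions = NULL, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"),
            base_error >= 0, base_error <= 1, maf_error_slope >= 0)
  check_regions(bad_regions)
  with_seed(seed, {
    e <- pmin(1, base_error * (1 + maf_error_slope *
                                 (0.5 - panel$map$maf) / 0.5))
    imp <- panel$true
    if (base_error > 0) {
      flip <- matrix(runif(panel$n * panel$m), panel$n, panel$m) <
        matrix(e, panel$n, panel$m, byrow = TRUE)
      repl <- matrix(rbinom(panel$n * panel$m, 2,
                            rep(panel$map$maf, each = panel$n)),
                     panel$n, panel$m)
      imp[flip] <- repl[flip]
    }
    if (!is.null(bad_regions) && nrow(bad_regions)) {
      for (i in seq_len(nrow(bad_regions))) {
        j <- which(panel$map$contig == bad_regions$contig[i] &
                     panel$map$pos > bad_regions$start[i] &
                     panel$map$pos <= bad_regions$end[i])
        for (jj in j) imp[, jj] <- imp[sample.int(panel$n), jj]
      }
    }
    panel$imputed <- imp
    panel$bad_regions <- bad_regions
    panel
  })
}

#' Simulate phenotypes with planted QTL and polygenic background
#'
#' Two modes. Variance-fraction mode (`qtl_varfrac` given): additive genetic
#' values are the sum of a polygenic term over all markers and QTL terms
#' scaled so each QTL explains the requested fraction of the additive
#' variance; environmental noise is added to give narrow-sense heritability
#' `h2`. Raw-effect mode (`qtl_effect` given): the genetic value is exactly
#' `sum(effect * dosage)` with no background, and `h2 = 1` yields a
#' noise-free phenotype.
#'
#' @param panel a `genotype_panel`.
#' @param qtl_index integer indices of QTL variants in the panel map.
#' @param qtl_effect raw allele-substitution effects (raw-effect mode).
#' @param qtl_varfrac fractions of additive variance per QTL
#'   (variance-fraction mode).
#' @param h2 narrow-sense heritability of the generating model; `h2 = 0`
#'   gives pure noise, independent of genotype. The default 0.7 emulates a
#'   deregressed progeny-difference phenotype (high reliability).
#' @param seed integer seed.
#' @return numeric phenotype vector with attributes `genetic_values` and
#'   `h2_realized`.
#' @export
simulate_phenotypes <- function(panel, qtl_index = integer(),
                                qtl_effect = NULL, qtl_varfrac = NULL,
                                h2 = 0.7, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"), h2 >= 0, h2 <= 1,
            all(qtl_index >= 1), all(qtl_index <= panel$m))
  with_seed(seed, {
    X <- panel$true
    n <- panel$n
    if (h2 == 0) {
      y <- rnorm(n)
      attr(y, "genetic_values") <- rep(0, n)
      attr(y, "h2_realized") <- 0
      return(y)
    }
    if (!is.null(qtl_effect)) {
      stopifnot(length(qtl_effect) == length(qtl_index))
      g <- as.vector(X[, qtl_index, drop = FALSE] %*% qtl_effect)
    } else {
      beta <- rnorm(panel$m) / sqrt(panel$m)
      u <- as.vector(X %*% beta)
      u <- if (sd(u) > 0) (u - mean(u)) / sd(u) else u
      qf <- if (is.null(qtl_varfrac)) numeric(0)
      else rep_len(qtl_varfrac, length(qtl_index))
      u <- u * sqrt(max(0, 1 - sum(qf)))
      g <- u
      for (i in seq_along(qtl_index)) {
        x <- X[, qtl_index[i]]
        if (sd(x) == 0) stop("QTL variant ", qtl_index[i], " is monomorphic")
        g <- g + (x - mean(x)) / sd(x) * sqrt(qf[i])
      }
    }
    vg <- var(g)
    y <- if (h2 == 1 || vg == 0) g
    else g + rnorm(n, sd = sqrt(vg * (1 - h2) / h2))
    attr(y, "genetic_values") <- g
    attr(y, "h2_realized") <- if (var(y) > 0) vg / var(y) else 0
    y
  })
}
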