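# GBLUP-based single-marker association scan: a genomic relationship
# matrix (GRM), a null animal model y = mu + g + e with g ~ N(0, sg2 * G)
# fitted by REML through one eigendecomposition of G, and a per-marker
# generalized least squares regression on allele substitution effects with
# the covariance fixed at the null estimates. The single spectral
# decomposition is reused across all markers, so each marker costs O(n).

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centers dosages by twice the observed allele frequency and scales by the
#' summed expected heterozygosity: `G = Z Z' / (2 * sum(p * (1 - p)))`.
#' Monomorphic markers carry no relationship information and are excluded.
#'
#' @param dosages n x m numeric matrix of allele dosages in `[0, 2]` (or a
#'   `genotype_panel`, whose imputed dosages are used when present).
#' @return n x n symmetric matrix with attribute `n_markers` (markers
#'   actually used).
#' @export
build_grm <- function(dosages) {
  if (inherits(dosages, "genotype_panel"))
    dosages <- if (!is.null(dosages$imputed)) dosages$imputed
               else dosages$true
  stopifnot(is.matrix(dosages), nrow(dosages) >= 2, ncol(dosages) >= 1)
  p <- colMeans(dosages) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic; GRM undefined")
  X <- dosages[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  G <- (G + t(G)) / 2
  attr(G, "n_markers") <- sum(poly)
  G
}

#' Fit the null GBLUP animal model by REML
#'
#' Model: `y = mu + g + e`, `g ~ N(0, sg2 * G)`, `e ~ N(0, se2 * I)`.
#' The restricted likelihood is profiled over `delta = se2 / sg2` using a
#' single eigendecomposition of G; at each delta the scale and intercept
#' have closed forms. Individuals with missing phenotype are dropped
#' listwise.
#'
#' @param phenotype numeric vector of length n (NAs dropped with the
#'   matching G rows).
#' @param G genomic relationship matrix from [build_grm()]; must be
#'   positive semi-definite within tolerance.
#' @param covariates optional numeric matrix of fixed covariates (an
#'   intercept is always included).
#' @return object of class `gblup_null` with variance components `sigma_g2`
#'   and `sigma_e2`, `h2`, `delta`, `logLik` (restricted), fixed-effect
#'   estimates, and the spectral cache (`U`, `d`, rotated data) reused by
#'   [gwas_scan()].
#' @export
fit_null <- function(phenotype, G, covariates = NULL) {
  stopifnot(is.numeric(phenotype), nrow(G) == length(phenotype))
  ok <- !is.na(phenotype)
  y <- phenotype[ok]
  G <- G[ok, ok, drop = FALSE]
  n <- length(y)
  if (n < 3) stop("need at least 3 phenotyped individuals")
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates)[ok, ,
                                                                drop = FALSE])
  p <- ncol(X)
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("G is not positive semi-definite (min eigenvalue ",
         signif(min(eg$values), 3), ")")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  reml_at <- function(log_delta) {
    delta <- exp(log_delta)
    w <- d + delta
    XtW <- Xt / w
    A <- crossprod(Xt, XtW)           # X' W^-1 X
    b <- solve(A, crossprod(XtW, yt))
    r <- yt - Xt %*% b
    rss <- sum(r^2 / w)
    sg2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * sg2) + (n - p) + sum(log(w)) +
                    determinant(A, logarithm = TRUE)$modulus -
                    determinant(crossprod(X), logarithm = TRUE)$modulus)
    list(ll = as.numeric(ll), sg2 = sg2, beta = drop(b), delta = delta)
  }
  # coarse grid then local refinement over log(delta)
  grid <- seq(-12, 12, by = 0.5)
  lls <- vapply(grid, function(g) reml_at(g)$ll, numeric(1))
  g0 <- grid[which.max(lls)]
  opt <- optimize(function(g) reml_at(g)$ll,
                  interval = c(g0 - 0.5, g0 + 0.5), maximum = TRUE,
                  tol = 1e-8)
  best <- reml_at(opt$maximum)
  sg2 <- best$sg2
  se2 <- best$delta * sg2
  structure(list(sigma_g2 = sg2, sigma_e2 = se2,
                 h2 = sg2 / (sg2 + se2), delta = best$delta,
                 logLik = best$ll, fixed = best$beta,
                 n = n, kept = which(ok),
                 U = U, d = d, yt = yt, Xt = Xt, y = y, X = X),
            class = "gblup_null")
}

#' @export
print.gblup_null <- function(x, digits = 4, ...) {
  cat("GBLUP null model (REML via spectral decomposition)\n")
  cat(sprintf("  n = %d phenotyped individuals\n", x$n))
  cat(sprintf("  sigma_g2 = %s, sigma_e2 = %s\n",
              signif(x$sigma_g2, digits), signif(x$sigma_e2, digits)))
  cat(sprintf("  h2 = %s\n", signif(x$h2, digits)))
  cat(sprintf("  restricted logLik = %s\n", signif(x$logLik, digits + 2)))
  invisible(x)
}

#' @export
coef.gblup_null <- function(object, ...) object$fixed

#' @export
summary.gblup_null <- function(object, ...) {
  out <- list(fit = object,
              vc = data.frame(component = c("genomic", "residual"),
                              variance = c(object$sigma_g2,
                                           object$sigma_e2),
                              proportion = c(object$h2, 1 - object$h2)))
  class(out) <- "summary.gblup_null"
  out
}

#' @export
print.summary.gblup_null <- function(x, ...) {
  print(x$fit)
  cat("  variance components:\n")
  print(x$vc, row.names = FALSE)
  invisible(x)
}

#' Single-marker association scan
#'
#' For each marker, the allele substitution effect is estimated by
#' generalized least squares with covariance `sigma_g2 * G + sigma_e2 * I`
#' held fixed at the null REML estimates; the Wald statistic is referred to
#' a standard Gaussian. Monomorphic markers yield NA rows.
#'
#' @param phenotype numeric vector (same individuals the null was fitted
#'   on; NAs dropped identically).
#' @param dosages n x m dosage matrix or `genotype_panel` (its map supplies
#'   positions; imputed dosages are used when present).
#' @param null a `gblup_null` from [fit_null()].
#' @param variants optional data.frame (`contig`, `position`, `maf`).
#' @param bonferroni also report Bonferroni-adjusted p-values.
#' @return data.frame of class `gwas_result`: `contig`, `position`, `maf`,
#'   `effect`, `se`, `p`, `logp` (-log10 p), sorted by contig and position.
#' @export
gwas_scan <- function(phenotype, dosages, null, variants = NULL,
                      bonferroni = FALSE) {
  stopifnot(inherits(null, "gblup_null"))
  if (inherits(dosages, "genotype_panel")) {
    if (is.null(variants)) variants <- panel_variants(dosages)
    dosages <- if (!is.null(dosages$imputed)) dosages$imputed
               else dosages$true
  }
  stopifnot(nrow(dosages) == length(phenotype))
  Z <- dosages[null$kept, , drop = FALSE]
  m <- ncol(Z)
  if (is.null(variants))
    variants <- data.frame(contig = "contig1", position = seq_len(m))
  stopifnot(nrow(variants) == m)
  w <- null$sigma_g2 * null$d + null$sigma_e2
  Ut1 <- null$Xt[, 1]                 # rotated intercept
  yt <- null$yt
  Zt <- crossprod(null$U, Z)          # n x m rotated markers
  a11 <- sum(Ut1^2 / w)
  c1 <- sum(Ut1 * yt / w)
  a12 <- colSums(Zt * (Ut1 / w))
  a22 <- colSums(Zt^2 / w)
  c2 <- colSums(Zt * (yt / w))
  det <- a11 * a22 - a12^2
  effect <- (a11 * c2 - a12 * c1) / det
  se <- sqrt(a11 / det)
  pfreq <- colMeans(Z) / 2
  mono <- pfreq <= 0 | pfreq >= 1
  effect[mono] <- NA_real_; se[mono] <- NA_real_
  z <- effect / se
  pval <- 2 * pnorm(-abs(z))
  out <- data.frame(contig = variants$contig, position = variants$position,
                    maf = if ("maf" %in% names(variants)) variants$maf
                          else pmin(pfreq, 1 - pfreq),
                    effect = effect, se = se, p = pval,
                    logp = -log10(pval))
  if (bonferroni) out$p_bonferroni <- pmin(pval * sum(!mono), 1)
  out <- out[order(out$contig, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Peaks and signal discontinuities in a scan
#'
#' For each contig the peak is the variant with the largest -log10 p. The
#' discontinuity diagnostic is the largest drop in -log10 p between
#' adjacent variants within `window` bases of the peak; a drop is reported
#' only when it is at least `drop_threshold` units. When imputation-QC
#' flags are supplied, each discontinuity records whether its boundary
#' interval overlaps a flagged region.
#'
#' @param results a `gwas_result` (sorted by position within contig).
#' @param window half-width around the peak to search, in bases.
#' @param drop_threshold minimum adjacent -log10 p drop to report.
#' @param flags optional flagged-region data.frame (`contig`, `start`,
#'   `end`) from the imputation-QC scan.
#' @return list with `peaks` (one row per contig) and `discontinuities`
#'   (possibly empty; columns `contig`, `start`, `end`, `drop`,
#'   `overlaps_flag`).
#' @export
region_report <- function(results, window = 1e6, drop_threshold = 2,
                          flags = NULL) {
  stopifnot(inherits(results, "data.frame"),
            all(c("contig", "position", "logp") %in% names(results)))
  peaks <- list(); disc <- list()
  for (ctg in unique(results$contig)) {
    r <- results[results$contig == ctg & is.finite(results$logp), ,
                 drop = FALSE]
    if (!nrow(r)) next
    if (is.unsorted(r$position)) stop("results must be sorted by position")
    top <- which.max(r$logp)
    peaks[[length(peaks) + 1]] <- data.frame(
      contig = ctg, position = r$position[top], logp = r$logp[top],
      effect = if ("effect" %in% names(r)) r$effect[top] else NA_real_)
    near <- which(abs(r$position - r$position[top]) <= window)
    if (length(near) < 2) next
    rr <- r[near, , drop = FALSE]
    drops <- rr$logp[-nrow(rr)] - rr$logp[-1]
    i <- which.max(drops)
    if (drops[i] >= drop_threshold) {
      s <- rr$position[i]; e <- rr$position[i + 1]
      overlaps <- if (!is.null(flags)) {
        any(flags$contig == ctg & flags$start <= e & flags$end >= s)
      } else NA
      disc[[length(disc) + 1]] <- data.frame(
        contig = ctg, start = s, end = e, drop = drops[i],
        overlaps_flag = overlaps)
    }
  }
  empty <- data.frame(contig = character(), start = numeric(),
                      end = numeric(), drop = numeric(),
                      overlaps_flag = logical())
  list(peaks = if (length(peaks)) do.call(rbind, peaks)
       else data.frame(contig = character(), position = numeric(),
                       logp = numeric(), effect = numeric()),
       discontinuities = if (length(disc)) do.call(rbind, disc) else empty)
}
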