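# Logistic saturation model of variant discovery against sequencing depth:
#
#   variants(depth) = Asymptote / (1 + exp(-beta0 - beta1 * depth))
#
# with variants counted in millions. The asymptote is the modelled total
# number of discoverable variants in an individual as depth -> infinity; the
# discovered *fraction* at a given depth depends only on (beta0, beta1), so
# depth targets for a desired discovery fraction have a closed form.

#' Fraction of discoverable variants found at a given depth
#'
#' The asymptote cancels out of the fraction:
#' `1 / (1 + exp(-beta0 - beta1 * depth))`, evaluated overflow-safely.
#'
#' @param beta0 intercept coefficient.
#' @param beta1 depth coefficient (per X of coverage).
#' @param depth average fold-coverage (X).
#' @return discovery fraction in (0, 1).
#' @export
saturation_fraction <- function(beta0, beta1, depth) {
  plogis(beta0 + beta1 * depth)
}

#' Depth required to reach a discovery fraction
#'
#' Inverts the saturation curve:
#' `depth = (qlogis(f) - beta0) / beta1`, the unique depth at which
#' [saturation_fraction()] equals `f`.
#'
#' @param beta0,beta1 logistic coefficients.
#' @param f target discovery fraction, strictly in (0, 1).
#' @return required depth in X.
#' @export
depth_for_fraction <- function(beta0, beta1, f) {
  if (any(f <= 0) || any(f >= 1)) stop("fraction must be strictly in (0, 1)")
  if (any(beta1 == 0)) stop("beta1 must be non-zero")
  (qlogis(f) - beta0) / beta1
}

#' Expected uncovered genome fraction under Poisson coverage
#'
#' With reads landing uniformly, the fraction of bases covered by no read is
#' `exp(-depth)`; observed uncovered fractions above this indicate
#' systematic coverage bias.
#'
#' @param depth average fold-coverage (X).
#' @return expected uncovered fraction.
#' @export
poisson_uncovered <- function(depth) {
  stopifnot(all(depth >= 0))
  exp(-depth)
}

#' Fit the logistic saturation model by least squares
#'
#' Minimizes `sum((observed - A / (1 + exp(-b0 - b1 * d)))^2)` over
#' `(A, b0, b1)` by Levenberg-Marquardt, initialized with
#' `A0 = 1.05 * max(observed)` and a linear logit regression for the betas.
#'
#' @param points data.frame with columns `depth` and `variants` (millions),
#'   or two numeric vectors via `depth`/`variants`.
#' @param depth,variants alternative vector interface.
#' @return an object of class `saturation_fit` with components
#'   `coefficients` (`asymptote`, `beta0`, `beta1`), `r.squared`, `fitted`,
#'   `residuals`, `data`, `n`, plus the usual methods (`print`, `summary`,
#'   `coef`, `predict`, `plot`, `residuals`).
#' @export
fit_logistic_saturation <- function(points = NULL, depth = NULL,
                                    variants = NULL) {
  if (!is.null(points)) {
    stopifnot(all(c("depth", "variants") %in% names(points)))
    depth <- points$depth; variants <- points$variants
  }
  ok <- is.finite(depth) & is.finite(variants)
  depth <- depth[ok]; variants <- variants[ok]
  if (length(depth) < 4) stop("need at least 4 points to fit")
  if (length(unique(depth)) < 2) stop("need at least 2 distinct depths")
  a0 <- 1.05 * max(variants)
  frac <- pmin(pmax(variants / a0, 1e-4), 1 - 1e-4)
  lf <- lm(qlogis(frac) ~ depth)
  start <- list(A = a0, b0 = unname(coef(lf)[1]), b1 = unname(coef(lf)[2]))
  fit <- minpack.lm::nlsLM(variants ~ A * plogis(b0 + b1 * depth),
                           data = data.frame(depth = depth,
                                             variants = variants),
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$convInfo$isConv)
    stop("saturation fit did not converge (last iterate: ",
         paste(signif(coef(fit), 6), collapse = ", "), ")")
  cf <- coef(fit)
  fitted <- cf[["A"]] * plogis(cf[["b0"]] + cf[["b1"]] * depth)
  resid <- variants - fitted
  sse <- sum(resid^2)
  sst <- sum((variants - mean(variants))^2)
  structure(list(coefficients = c(asymptote = unname(cf[["A"]]),
                                  beta0 = unname(cf[["b0"]]),
                                  beta1 = unname(cf[["b1"]])),
                 r.squared = if (sst > 0) 1 - sse / sst else NA_real_,
                 fitted = fitted, residuals = resid,
                 data = data.frame(depth = depth, variants = variants),
                 n = length(depth), sse = sse),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, digits = 4, ...) {
  cat("Logistic variant-discovery saturation fit\n")
  cat(sprintf("  asymptote: %s million variants\n",
              signif(x$coefficients[["asymptote"]], digits)))
  cat(sprintf("  beta0 = %s, beta1 = %s (per X)\n",
              signif(x$coefficients[["beta0"]], digits),
              signif(x$coefficients[["beta1"]], digits)))
  cat(sprintf("  R-squared = %s on %d points\n", signif(x$r.squared, digits),
              x$n))
  invisible(x)
}

#' @export
coef.saturation_fit <- function(object, ...) object$coefficients

#' @export
residuals.saturation_fit <- function(object, ...) object$residuals

#' @export
summary.saturation_fit <- function(object, fractions = c(0.95, 0.99), ...) {
  cf <- object$coefficients
  depths <- depth_for_fraction(cf[["beta0"]], cf[["beta1"]], fractions)
  out <- list(fit = object,
              depth_targets = data.frame(
                fraction = fractions,
                depth = round_half_up(depths, 1)))
  class(out) <- "summary.saturation_fit"
  out
}

#' @export
print.summary.saturation_fit <- function(x, ...) {
  print(x$fit)
  cat("  depth targets (X, half-up to 1 decimal):\n")
  for (i in seq_len(nrow(x$depth_targets)))
    cat(sprintf("    %4.0f %% of variants at %.1fX\n",
                100 * x$depth_targets$fraction[i], x$depth_targets$depth[i]))
  invisible(x)
}

#' @export
predict.saturation_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$depth
  else if (is.data.frame(newdata)) newdata$depth else newdata
  cf <- object$coefficients
  cf[["asymptote"]] * saturation_fraction(cf[["beta0"]], cf[["beta1"]], d)
}

#' @export
plot.saturation_fit <- function(x, ...) {
  plot(x$data$depth, x$data$variants, xlab = "Average depth (X)",
       ylab = "Variants called (millions)", ...)
  cf <- x$coefficients
  curve(cf[["asymptote"]] * plogis(cf[["beta0"]] + cf[["beta1"]] * t),
        xname = "t", add = TRUE)
  abline(h = cf[["asymptote"]], lty = 2)
  invisible(x)
}

#' Bootstrap standard errors for the saturation fit
#'
#' Case-resampling bootstrap of the fitted parameters.
#'
#' @param fit a `saturation_fit`.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return named numeric vector of standard errors for
#'   (`asymptote`, `beta0`, `beta1`).
#' @export
bootstrap_se <- function(fit, B = 100, seed = 1) {
  d <- fit$data
  with_seed(seed, {
    est <- matrix(NA_real_, B, 3)
    for (b in seq_len(B)) {
      i <- sample.int(nrow(d), replace = TRUE)
      f <- try(fit_logistic_saturation(d[i, , drop = FALSE]), silent = TRUE)
      if (!inherits(f, "try-error")) est[b, ] <- coef(f)
    }
    se <- apply(est, 2, sd, na.rm = TRUE)
    names(se) <- c("asymptote", "beta0", "beta1")
    se
  })
}

#' Tabulate breadth of coverage against depth and solve for depth targets
#'
#' Fits the same logistic form to breadth (asymptote bounded at 1) and, for
#' each requested breadth target, reports the depth at which it is reached.
#' Because uncovered fraction decays roughly exponentially with depth, the
#' target depth is obtained by interpolating `log(1 - breadth)` against
#' depth (exact under the Poisson coverage model); the bounded logistic fit
#' is reported alongside when enough points are available.
#'
#' @param samples data.frame with columns `sample`, `depth`, `breadth`.
#' @param targets breadth targets in (0, 1).
#' @return list with `table` (input, passthrough), `fit` (bounded
#'   `saturation_fit` or `NULL`), and `depth_at_target` data.frame.
#' @export
coverage_summary <- function(samples, targets = c(0.995)) {
  stopifnot(all(c("sample", "depth", "breadth") %in% names(samples)),
            nrow(samples) >= 1, all(targets > 0), all(targets < 1))
  tab <- samples[order(samples$depth), , drop = FALSE]
  fit <- NULL
  if (nrow(tab) >= 4 && length(unique(tab$depth)) >= 2) {
    fit <- try(minpack.lm::nlsLM(
      breadth ~ A * plogis(b0 + b1 * depth), data = tab,
      start = list(A = 1, b0 = 0, b1 = 0.2),
      upper = c(A = 1, b0 = Inf, b1 = Inf),
      lower = c(A = 1e-6, b0 = -Inf, b1 = 1e-8)), silent = TRUE)
    if (inherits(fit, "try-error")) fit <- NULL
  }
  u <- log(pmax(1 - tab$breadth, 1e-12))
  dat <- lapply(targets, function(tg) {
    ut <- log(1 - tg)
    est <- if (nrow(tab) >= 2 && any(u <= ut) && any(u >= ut)) {
      approx(u, tab$depth, xout = ut, ties = mean)$y
    } else if (nrow(tab) >= 2) {
      # extrapolate from the log-linear trend
      lfit <- lm(tab$depth ~ u)
      unname(predict(lfit, data.frame(u = ut)))
    } else NA_real_
    data.frame(target = tg, depth = est)
  })
  list(table = tab, fit = fit, depth_at_target = do.call(rbind, dat))
}
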