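# Shared helpers: seeding, sequence utilities, rounding conventions.

#' Derive a child seed from a master seed and a tag
#'
#' All stochastic operations take a `seed` argument; pipelines that run
#' several operations derive one child stream per operation from a single
#' master seed so that runs are reproducible end to end without reusing the
#' same stream twice.
#'
#' @param master integer master seed.
#' @param tag character tag naming the operation (or an integer replicate id).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(master, tag) {
  h <- sum(utf8ToInt(paste0(tag)) * seq_along(utf8ToInt(paste0(tag))))
  as.integer((as.numeric(master) * 69069 + as.numeric(h) * 1013904223) %% 2147483647)
}

# evaluate expr under a given seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA string of length n (uniform base composition)
#'
#' Uses the caller's RNG stream; seed with `set.seed()` or `with_seed`.
#'
#' @param n length in bases.
#' @return a single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Round half-up to a number of decimals
#'
#' R's `round()` rounds half to even; depth targets are conventionally
#' reported with half-up rounding (23.15 -> 23.2).
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# validate a half-open interval table (0-based start, exclusive end)
check_regions <- function(regions, what = "region") {
  if (is.null(regions) || nrow(regions) == 0) return(invisible(NULL))
  stopifnot(all(c("contig", "start", "end") %in% names(regions)))
  if (any(regions$end <= regions$start))
    stop(what, " intervals must have end > start (half-open, 0-based)")
  invisible(NULL)
}
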