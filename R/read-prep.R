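# Read preparation: lossless partitioning of raw paired reads into
# unique / duplicate / short files, and exact-match adapter trimming.
# Dedup is sequence-only and pair-aware: a pair is a duplicate only when both
# mates match both mates of an already-retained pair. Every operation is
# lossless: the three-way partition conserves the read-name multiset.

#' Partition read pairs into first occurrences and exact duplicates
#'
#' @param reads a [read_pairs] object.
#' @return a list of class `read_partition` with elements `unique`,
#'   `duplicates` (both [read_pairs]) and `counts`.
#' @export
partition_duplicates <- function(reads) {
  stopifnot(inherits(reads, "read_pairs"))
  key <- paste(reads$seq1, reads$seq2, sep = "\r")
  dup <- duplicated(key)
  structure(list(unique = reads[!dup], duplicates = reads[dup],
                 short = read_pairs(),
                 counts = c(unique = sum(!dup), duplicates = sum(dup),
                            short = 0L, input = length(reads))),
            class = "read_partition")
}

#' @export
print.read_partition <- function(x, ...) {
  cat("read_partition:\n")
  print(x$counts)
  invisible(x)
}

#' Trim an adapter by exact string matching
#'
#' The leftmost exact occurrence of the adapter and everything 3' of it is
#' removed from each mate; reads without an exact occurrence are unchanged
#' (no mismatch tolerance by design).
#'
#' @param reads a [read_pairs] object or a character vector of sequences.
#' @param adapter non-empty uppercase adapter sequence.
#' @return same type as `reads`, trimmed.
#' @export
trim_adapter <- function(reads, adapter) {
  if (!is.character(adapter) || length(adapter) != 1 || nchar(adapter) == 0)
    stop("adapter must be a single non-empty string")
  adapter <- toupper(adapter)
  trim1 <- function(s) {
    hit <- regexpr(adapter, s, fixed = TRUE)
    ifelse(hit > 0, substr(s, 1, hit - 1), s)
  }
  if (inherits(reads, "read_pairs")) {
    reads$seq1 <- trim1(reads$seq1)
    reads$seq2 <- trim1(reads$seq2)
    reads
  } else trim1(reads)
}

#' Partition read pairs by minimum length
#'
#' Pairs where either mate is shorter than `min_len` leave the paired stream
#' entirely (both mates go to the short file), since downstream paired
#' alignment requires intact pairs.
#'
#' @param reads a [read_pairs] object.
#' @param min_len minimum retained read length in bases; reads of exactly
#'   `min_len` are retained ("shorter than" is strict).
#' @return a `read_partition` with elements `unique` (retained pairs),
#'   `short` and `counts`.
#' @export
partition_by_length <- function(reads, min_len = 35) {
  stopifnot(inherits(reads, "read_pairs"), min_len >= 1)
  short <- nchar(reads$seq1) < min_len | nchar(reads$seq2) < min_len
  structure(list(unique = reads[!short], duplicates = read_pairs(),
                 short = reads[short],
                 counts = c(unique = sum(!short), duplicates = 0L,
                            short = sum(short), input = length(reads))),
            class = "read_partition")
}

#' Run the full read-preparation pipeline
#'
#' Fixed order: duplicate partition, adapter trim, an error-correction hook
#' (identity by default; external correctors are out of scope), a second
#' duplicate partition, then the length partition. Returns all partitions and
#' a per-stage count report; the union of outputs conserves the input.
#'
#' @param reads a [read_pairs] object.
#' @param adapter optional adapter to trim (skipped if `NULL`).
#' @param min_len minimum retained read length.
#' @param correct optional function `read_pairs -> read_pairs` standing in
#'   for an error-correction stage.
#' @return list with `retained` ([read_pairs]), `duplicates`, `duplicates2`,
#'   `short` and `report` (data.frame of per-stage counts).
#' @export
prep_reads <- function(reads, adapter = NULL, min_len = 35, correct = NULL) {
  p1 <- partition_duplicates(reads)
  kept <- p1$unique
  if (!is.null(adapter)) kept <- trim_adapter(kept, adapter)
  if (!is.null(correct)) kept <- correct(kept)
  p2 <- partition_duplicates(kept)
  p3 <- partition_by_length(p2$unique, min_len)
  report <- data.frame(
    stage = c("input", "duplicates", "post_trim_duplicates", "short",
              "retained"),
    pairs = c(length(reads), length(p1$duplicates), length(p2$duplicates),
              length(p3$short), length(p3$unique)))
  list(retained = p3$unique, duplicates = p1$duplicates,
       duplicates2 = p2$duplicates, short = p3$short, report = report)
}
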