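# Raw-read cleanup: 3' adapter trimming, exact-duplicate collapsing,
# contaminant removal, and dataset-level composition summaries.

#' Trim a 3' adapter from a read
#'
#' Scans insert lengths from short to long and trims at the leftmost
#' position where the read suffix matches a prefix of the adapter over at
#' least `min_overlap` bases with at most `floor(max_mismatch_frac * L)`
#' mismatches, where `L` is the compared length. RNA inputs are handled in
#' DNA space (U as T).
#'
#' @param sequence Read sequence (character scalar).
#' @param adapter Adapter sequence.
#' @param max_mismatch_frac Maximum mismatch fraction in the compared
#'   region (default 0.25).
#' @param min_overlap Minimum read/adapter overlap to accept a trim
#'   position, default 6 nt.
#' @param min_insert Smallest insert length considered, default 0.
#' @return List with `sequence` (possibly shortened) and logical `trimmed`.
#' @examples
#' trim_adapter(paste0(strrep("ACGT", 7), "TGGAATTC"), "TGGAATTCTCGG")
#' @export
trim_adapter <- function(sequence, adapter, max_mismatch_frac = 0.25,
                         min_overlap = 6L, min_insert = 0L) {
  stopifnot(nzchar(adapter))
  read_v <- strsplit(chartr("Uu", "Tt", toupper(sequence)), "")[[1]]
  ad_v <- strsplit(toupper(chartr("Uu", "Tt", adapter)), "")[[1]]
  n <- length(read_v)
  for (i in seq(from = max(0L, min_insert), to = n - min_overlap)) {
    L <- min(n - i, length(ad_v))
    mm <- sum(read_v[(i + 1):(i + L)] != ad_v[seq_len(L)])
    if (mm <= floor(max_mismatch_frac * L)) {
      return(list(sequence = substr(sequence, 1L, i), trimmed = TRUE))
    }
  }
  list(sequence = sequence, trimmed = FALSE)
}

#' Collapse exact duplicate sequences
#'
#' @param sequences Character vector of read sequences.
#' @return Data frame with `sequence` and `copies`, one row per distinct
#'   sequence in order of first occurrence; `sum(copies)` equals the input
#'   length.
#' @export
collapse_reads <- function(sequences) {
  if (length(sequences) == 0L)
    return(data.frame(sequence = character(0), copies = integer(0)))
  tab <- table(factor(sequences, levels = unique(sequences)))
  data.frame(sequence = names(tab), copies = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Remove reads matching a contaminant library
#'
#' A read is removed when it aligns to any window of any contaminant
#' sequence, on either strand, with at most `max_mismatch` mismatches over
#' the full read length. Matching is ungapped (Hamming), mirroring a
#' no-indel short-read aligner.
#'
#' @param sequences Character vector of read sequences.
#' @param contaminants Character vector of contaminant sequences (rRNA,
#'   tRNA, adapters, ...).
#' @param max_mismatch Maximum mismatches, default 3.
#' @return Surviving sequences, in input order.
#' @export
filter_contaminants <- function(sequences, contaminants, max_mismatch = 3L) {
  if (length(sequences) == 0L || length(contaminants) == 0L)
    return(sequences)
  subjects <- Biostrings::DNAStringSet(contaminants)
  subjects <- c(subjects, Biostrings::reverseComplement(subjects))
  hit <- vapply(sequences, function(s) {
    counts <- Biostrings::vcountPattern(s, subjects,
                                        max.mismatch = max_mismatch)
    any(counts > 0L)
  }, logical(1), USE.NAMES = FALSE)
  sequences[!hit]
}

#' Similarity index between two sequence sets
#'
#' The number of sequences in the intersection of the two sets divided by
#' the number in their union (Jaccard index), used to compare small-RNA
#' datasets.
#'
#' @param set_a,set_b Character vectors of distinct sequences.
#' @return Fraction in `[0, 1]`.
#' @examples
#' similarity_index(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
similarity_index <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  u <- union(a, b)
  if (length(u) == 0L) stop("similarity index of two empty sets is undefined")
  length(intersect(a, b)) / length(u)
}

#' Summarise length and base composition of a read set
#'
#' Computed over unique sequences: the read-length histogram, the base
#' fractions at the 5' position and at position 10 (1-based), and the
#' observation-frequency histogram of copy counts.
#'
#' @param sequences Character vector of (collapsed) sequences, or an
#'   [aligned_reads()] table with a `sequence` column.
#' @param copies Optional copy counts parallel to `sequences`.
#' @return An object of class `composition_summary`: list with
#'   `length_histogram`, `base_fraction_5p`, `base_fraction_pos10`,
#'   `copy_histogram`, `n_unique`, `n_total`.
#' @export
composition_stats <- function(sequences, copies = NULL) {
  if (is.data.frame(sequences)) {
    if (is.null(copies) && "copies" %in% names(sequences))
      copies <- sequences$copies
    sequences <- sequences$sequence
  }
  if (is.null(copies)) copies <- rep(1L, length(sequences))
  keep <- !duplicated(sequences)
  seqs <- sequences[keep]
  cps <- copies[keep]
  lens <- nchar(seqs)
  base_frac <- function(pos) {
    b <- substr(seqs[lens >= pos], pos, pos)
    if (length(b) == 0L) return(setNames(numeric(0), character(0)))
    tab <- table(b)
    as.numeric(tab) / sum(tab) -> fr
    setNames(fr, names(tab))
  }
  out <- list(length_histogram = table(lens),
              base_fraction_5p = base_frac(1L),
              base_fraction_pos10 = base_frac(10L),
              copy_histogram = table(cps),
              n_unique = length(seqs),
              n_total = sum(cps))
  class(out) <- "composition_summary"
  out
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Small-RNA composition summary\n")
  cat("  unique sequences:", x$n_unique, " total reads:", x$n_total, "\n")
  if (length(x$length_histogram)) {
    mode_len <- names(x$length_histogram)[which.max(x$length_histogram)]
    cat("  modal length:", mode_len, "nt\n")
  }
  if ("T" %in% names(x$base_fraction_5p))
    cat(sprintf("  5' U fraction: %.3f\n", x$base_fraction_5p[["T"]]))
  if ("A" %in% names(x$base_fraction_pos10))
    cat(sprintf("  position-10 A fraction: %.3f\n",
                x$base_fraction_pos10[["A"]]))
  invisible(x)
}
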