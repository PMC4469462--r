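#' @importFrom stats density dnorm pnorm quantile rbinom rpois runif setNames
#' @importFrom utils head read.delim tail write.table
NULL

# All coordinates in this package are 0-based half-open (BED convention).
# GTF-style 1-based inputs are shifted at the I/O boundary only.

#' Construct a genomic interval table
#'
#' A genomic interval is a row of a data frame with columns `chrom`,
#' `start`, `end` and (optionally) `strand`. Coordinates are 0-based
#' half-open, as in BED. This helper validates and normalises such a table.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start.
#' @param end Integer vector, 0-based exclusive end; must exceed `start`.
#' @param strand Strand of each interval: `"+"`, `"-"` or `"*"`
#'   (unstranded). Recycled.
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 200, "+")
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop("interval chrom must be non-empty")
  if (any(df$start < 0) || any(df$end <= df$start))
    stop("intervals must satisfy 0 <= start < end")
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(df)
}

#' Overlap length of two intervals
#'
#' Number of bases shared by two half-open intervals; zero when they touch
#' end-to-start or sit on different chromosomes. Strand is ignored.
#'
#' @param a,b Single-row interval data frames (or lists) with `chrom`,
#'   `start`, `end`.
#' @return Integer number of overlapping bases.
#' @examples
#' a <- genomic_intervals("chr1", 10, 20)
#' b <- genomic_intervals("chr1", 15, 30)
#' overlap_length(a, b)  # 5
#' @export
overlap_length <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  as.integer(max(0, min(a$end, b$end) - max(a$start, b$start)))
}

# Vectorised overlap of one interval against many; returns bases per row.
overlap_vec <- function(chrom, start, end, df) {
  if (nrow(df) == 0L) return(numeric(0))
  out <- pmin(df$end, end) - pmax(df$start, start)
  out[df$chrom != chrom] <- 0
  pmax(out, 0)
}

#' Merge overlapping intervals on one chromosome
#'
#' Collapses a set of intervals into the minimal set of disjoint intervals
#' covering their union, sorted by start. All input intervals must lie on a
#' single chromosome.
#'
#' @param regions Interval data frame (one chromosome).
#' @return Interval data frame of disjoint merged regions, strand `"*"`.
#' @examples
#' r <- genomic_intervals("chr1", c(0, 5, 30), c(10, 20, 40))
#' merge_overlapping(r)
#' @export
merge_overlapping <- function(regions) {
  validate_intervals(regions)
  if (nrow(regions) == 0L) return(regions)
  if (length(unique(regions$chrom)) != 1L)
    stop("merge_overlapping expects intervals on a single chromosome")
  ir <- IRanges::reduce(IRanges::IRanges(regions$start + 1L, regions$end))
  genomic_intervals(regions$chrom[1L],
                    IRanges::start(ir) - 1L, IRanges::end(ir))
}

#' Shrink a region to the span of the reads it contains
#'
#' Returns the tight interval `[min start, max end)` over the aligned reads
#' that intersect `region` by at least one base, optionally restricted to
#' one strand. Used to trim cluster boundaries to actual read evidence.
#'
#' @param region Single-row interval data frame.
#' @param reads Aligned-read table (see [aligned_reads()]).
#' @param strand_filter Optional strand (`"+"` or `"-"`); only reads on this
#'   strand are considered.
#' @return A one-row interval data frame, or a zero-row data frame when no
#'   read qualifies.
#' @export
shrink_to_reads <- function(region, reads, strand_filter = NULL) {
  keep <- reads$chrom == region$chrom &
    reads$start < region$end & reads$end > region$start
  if (!is.null(strand_filter)) keep <- keep & reads$strand == strand_filter
  if (!any(keep)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0)))
  }
  genomic_intervals(region$chrom,
                    min(reads$start[keep]), max(reads$end[keep]),
                    if (is.null(region$strand)) "*" else region$strand)
}

#' Construct an aligned-read table
#'
#' One row per genomic alignment of a collapsed small-RNA sequence.
#' Coordinates are 0-based half-open; `length(sequence) == end - start`
#' when sequences are supplied. `copies` is the number of raw reads
#' collapsed into the sequence and `n_alignments` the number of genomic
#' placements the producing alignment mode reported for it.
#'
#' @param chrom,start,end,strand Alignment coordinates; strand `"+"`/`"-"`.
#' @param read_id Identifier of the collapsed sequence.
#' @param sequence Optional nucleotide string (A/C/G/T/N) per read.
#' @param copies Raw-read copy count, default 1.
#' @param mismatches Mismatch count of the alignment, default 0.
#' @param n_alignments Number of placements of the sequence, default 1.
#' @return A data frame of class `aligned_reads`.
#' @export
aligned_reads <- function(chrom, start, end, strand, read_id = NULL,
                          sequence = NULL, copies = 1L, mismatches = 0L,
                          n_alignments = 1L) {
  n <- max(length(chrom), length(start), length(end))
  if (is.null(read_id)) read_id <- sprintf("read%06d", seq_len(n))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   strand = rep_len(as.character(strand), n),
                   read_id = as.character(read_id),
                   copies = rep_len(as.integer(copies), n),
                   mismatches = rep_len(as.integer(mismatches), n),
                   n_alignments = rep_len(as.integer(n_alignments), n),
                   stringsAsFactors = FALSE)
  if (!is.null(sequence)) {
    df$sequence <- as.character(sequence)
    bad <- nchar(df$sequence) != df$end - df$start
    if (any(bad)) stop("sequence length must equal end - start")
  }
  validate_intervals(df)
  if (any(df$strand == "*")) stop("aligned reads must be stranded")
  if (any(df$copies < 1L) || any(df$n_alignments < 1L))
    stop("copies and n_alignments must be >= 1")
  class(df) <- c("aligned_reads", "data.frame")
  df
}

# 5' position of each read: start for +, end - 1 for -.
five_prime_pos <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1)
}

# Fast count of reads intersecting [lo, hi) given pre-sorted start/end
# vectors for one chromosome: #(start < hi) - #(end <= lo).
count_intersecting <- function(sorted_starts, sorted_ends, lo, hi) {
  findInterval(hi, sorted_starts, left.open = TRUE) -
    findInterval(lo, sorted_ends)
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
df_to_gr <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = strand)
}

# Summed overlap (bases) of each query row with the union of track rows.
# mode = "sum": overlap with the reduced track union; mode = "max": the
# largest single-interval overlap against the raw track records.
track_overlap <- function(query, track, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  if (nrow(query) == 0L) return(numeric(0))
  if (nrow(track) == 0L) return(numeric(nrow(query)))
  qgr <- df_to_gr(query)
  tgr <- df_to_gr(track)
  GenomicRanges::strand(qgr) <- "*"
  GenomicRanges::strand(tgr) <- "*"
  if (mode == "sum") tgr <- GenomicRanges::reduce(tgr)
  hits <- GenomicRanges::findOverlaps(qgr, tgr)
  if (length(hits) == 0L) return(numeric(nrow(query)))
  w <- GenomicRanges::width(IRanges::pintersect(
    qgr[S4Vectors::queryHits(hits)], tgr[S4Vectors::subjectHits(hits)]))
  agg <- if (mode == "sum") {
    tapply(w, S4Vectors::queryHits(hits), sum)
  } else {
    tapply(w, S4Vectors::queryHits(hits), max)
  }
  out <- numeric(nrow(query))
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}
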