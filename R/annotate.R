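# Exclusive genomic classification of uniquely aligned reads:
# repeat > mRNA (exon) > intron > intergenic, with a 50%-of-read-length
# overlap requirement. Strand is ignored; the tracks are positional.

READ_CLASSES <- c("repeat", "mRNA", "intron", "intergenic")

#' Classify aligned reads into exclusive genomic classes
#'
#' A read belongs to a class when at least half of its length overlaps
#' that class's track, testing the tracks in the priority order
#' repeat > mRNA > intron; reads failing all three are intergenic. By
#' default the overlap with a track is summed over the track's (merged)
#' intervals; `overlap_mode = "max"` instead takes the largest
#' single-interval overlap.
#'
#' @param reads An [aligned_reads()] table.
#' @param tracks An [annotation_tracks()] list.
#' @param min_frac Minimum overlapping fraction of the read length,
#'   default 0.5.
#' @param overlap_mode `"sum"` (default) or `"max"`.
#' @return Character vector of classes, one per read.
#' @export
classify_reads <- function(reads, tracks, min_frac = 0.5,
                           overlap_mode = c("sum", "max")) {
  overlap_mode <- match.arg(overlap_mode)
  n <- nrow(reads)
  if (n == 0L) return(character(0))
  len <- reads$end - reads$start
  cls <- rep("intergenic", n)
  track_list <- list(`repeat` = tracks$repeats,
                     mRNA = tracks$mrna_exons,
                     intron = tracks$introns)
  unassigned <- rep(TRUE, n)
  for (nm in names(track_list)) {
    if (!any(unassigned)) break
    ov <- track_overlap(reads[unassigned, , drop = FALSE], track_list[[nm]],
                        mode = overlap_mode)
    hit <- ov >= min_frac * len[unassigned]
    idx <- which(unassigned)[hit]
    cls[idx] <- nm
    unassigned[idx] <- FALSE
  }
  cls
}

#' Count and fraction of reads per genomic class
#'
#' @inheritParams classify_reads
#' @return Data frame with `class`, `count`, `fraction`; counts sum to
#'   `nrow(reads)` and fractions to 1 (all zero for empty input).
#' @export
classify_all <- function(reads, tracks, min_frac = 0.5,
                         overlap_mode = c("sum", "max")) {
  cls <- classify_reads(reads, tracks, min_frac, overlap_mode)
  counts <- vapply(READ_CLASSES, function(k) sum(cls == k), integer(1))
  frac <- if (length(cls)) counts / length(cls) else numeric(4L)
  data.frame(class = READ_CLASSES, count = as.integer(counts),
             fraction = as.numeric(frac), stringsAsFactors = FALSE)
}
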