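# Ping-pong signature: sites inside 3' UTR clusters where plus- and
# minus-strand 5' ends overlap by exactly 10 bases, and attribution of the
# antisense reads to their best genomic source.
#
# 5'-end convention: plus-strand 5' = start; minus-strand 5' = end - 1.
# A site requires minus_5p - plus_5p = 9, so the first 10 bases of the two
# partners cover the same 10 positions.

#' Find 10-bp 5'-overlap (ping-pong) sites in a cluster
#'
#' Enumerates all pairs of a plus-strand 5' position `p` and a minus-strand
#' 5' position `m` inside the cluster with `m - p = 9` where at least one
#' relaxed-mode read starts its 5' end at each position. One site is
#' reported per distinct position pair, aggregating all reads sharing
#' those 5' ends.
#'
#' @param cluster One-row cluster record (interval with `cluster_id`).
#' @param relaxed_reads Relaxed-mode [aligned_reads()] on the cluster's
#'   chromosome.
#' @return Data frame with one row per site: `cluster_id`, `plus_5p`,
#'   `minus_5p`, `n_plus_reads`, `n_minus_reads`, and the participating
#'   read ids (comma-separated `plus_reads`, `minus_reads`).
#' @export
find_pingpong_sites <- function(cluster, relaxed_reads) {
  rr <- reads_in(relaxed_reads, cluster$chrom, cluster$start, cluster$end)
  p5 <- five_prime_pos(rr)
  inside <- p5 >= cluster$start & p5 < cluster$end
  rr <- rr[inside, , drop = FALSE]
  p5 <- p5[inside]
  plus <- rr$strand == "+"
  empty <- data.frame(cluster_id = character(0), plus_5p = numeric(0),
                      minus_5p = numeric(0), n_plus_reads = integer(0),
                      n_minus_reads = integer(0), plus_reads = character(0),
                      minus_reads = character(0))
  if (!any(plus) || all(plus)) return(empty)
  p_pos <- sort(unique(p5[plus]))
  m_pos <- sort(unique(p5[!plus]))
  hit_p <- p_pos[(p_pos + 9) %in% m_pos]
  if (length(hit_p) == 0L) return(empty)
  out <- lapply(hit_p, function(p) {
    ps <- which(plus & p5 == p)
    ms <- which(!plus & p5 == p + 9)
    data.frame(cluster_id = cluster$cluster_id, plus_5p = p, minus_5p = p + 9,
               n_plus_reads = length(ps), n_minus_reads = length(ms),
               plus_reads = paste(rr$read_id[ps], collapse = ","),
               minus_reads = paste(rr$read_id[ms], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Ping-pong site composition summary
#'
#' Over the distinct antisense sequences participating at sites: the
#' fraction with a 5' U and the fraction with an A at (1-based) sequence
#' position 10; plus per-cluster site counts and the fraction of each
#' cluster covered by the 10-bp site footprints.
#'
#' @param sites Row-bound output of [find_pingpong_sites()] over one or
#'   more clusters.
#' @param relaxed_reads The relaxed-mode reads the sites were called from
#'   (must carry sequences).
#' @param clusters The clusters the sites live in (for coverage).
#' @return List with `frac_5u`, `frac_pos10_a`, `n_antisense_sequences`,
#'   and per-cluster data frame `per_cluster` (`cluster_id`, `n_sites`,
#'   `site_coverage`).
#' @export
pingpong_composition <- function(sites, relaxed_reads, clusters) {
  if (nrow(sites) == 0L) stop("no ping-pong sites to summarise")
  anti_ids <- unique(unlist(strsplit(sites$minus_reads, ",", fixed = TRUE)))
  seqs <- unique(relaxed_reads$sequence[match(anti_ids,
                                              relaxed_reads$read_id)])
  seqs <- seqs[!is.na(seqs)]
  frac_5u <- mean(substr(seqs, 1, 1) == "T")
  long_enough <- nchar(seqs) >= 10L
  frac_a10 <- mean(substr(seqs[long_enough], 10, 10) == "A")
  per <- do.call(rbind, lapply(split(sites, sites$cluster_id), function(s) {
    cl <- clusters[clusters$cluster_id == s$cluster_id[1], , drop = FALSE]
    cov_iv <- merge_overlapping(
      genomic_intervals(cl$chrom, s$plus_5p, s$plus_5p + 10))
    data.frame(cluster_id = s$cluster_id[1], n_sites = nrow(s),
               site_coverage = sum(cov_iv$end - cov_iv$start) /
                 (cl$end - cl$start), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(frac_5u = frac_5u, frac_pos10_a = frac_a10,
       n_antisense_sequences = length(seqs), per_cluster = per)
}

#' Attribute antisense reads to their best genomic source
#'
#' Each antisense read's strict unique placement is classified by at least
#' 1 bp of overlap, in priority order: the 3' UTR cluster where it was
#' discovered, then any intergenic cluster, then any other piRNA cluster,
#' then any other location. Reads without a strict unique placement are
#' classed `"other"` with a missing-location flag.
#'
#' @param antisense_ids Read ids of the antisense site participants.
#' @param discovery_cluster_ids Parallel vector naming the 3' UTR cluster
#'   each read was discovered in.
#' @param strict_reads Strict-mode [aligned_reads()] (at most one placement
#'   per read id).
#' @param utr3_clusters,other_clusters `pirna_clusters` tables from the two
#'   callers.
#' @return Data frame with `read_id`, `source_class`, placement
#'   coordinates, and `missing_location`.
#' @export
annotate_antisense_sources <- function(antisense_ids, discovery_cluster_ids,
                                       strict_reads, utr3_clusters,
                                       other_clusters) {
  stopifnot(length(antisense_ids) == length(discovery_cluster_ids),
            !anyDuplicated(strict_reads$read_id))
  m <- match(antisense_ids, strict_reads$read_id)
  n <- length(antisense_ids)
  cls <- rep("other", n)
  chrom <- rep(NA_character_, n)
  start <- rep(NA_real_, n)
  end <- rep(NA_real_, n)
  interg <- other_clusters[other_clusters$kind == "intergenic", , drop = FALSE]
  other_pi <- other_clusters[other_clusters$kind != "intergenic", ,
                             drop = FALSE]
  for (i in seq_len(n)) {
    if (is.na(m[i])) next
    rd <- strict_reads[m[i], ]
    chrom[i] <- rd$chrom
    start[i] <- rd$start
    end[i] <- rd$end
    home <- utr3_clusters[utr3_clusters$cluster_id ==
                            discovery_cluster_ids[i], , drop = FALSE]
    if (nrow(home) && any(overlap_vec(rd$chrom, rd$start, rd$end, home) > 0)) {
      cls[i] <- "same_utr3_cluster"
    } else if (any(overlap_vec(rd$chrom, rd$start, rd$end, interg) > 0)) {
      cls[i] <- "intergenic_cluster"
    } else if (any(overlap_vec(rd$chrom, rd$start, rd$end, other_pi) > 0) ||
               any(overlap_vec(rd$chrom, rd$start, rd$end,
                               utr3_clusters[utr3_clusters$cluster_id !=
                                               discovery_cluster_ids[i], ,
                                             drop = FALSE]) > 0)) {
      cls[i] <- "other_pirna_cluster"
    }
  }
  data.frame(read_id = antisense_ids, source_class = cls,
             chrom = chrom, start = start, end = end,
             missing_location = is.na(m), stringsAsFactors = FALSE)
}
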