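# Extended 3' UTR (xUTR) selection and RNA-seq expression against a
# shuffled-intergenic background.

#' Select clusters marking extended 3' UTRs
#'
#' Keeps 3' UTR clusters that extend beyond the annotated 3' UTR by more
#' than `min_beyond_frac` of the cluster length, and removes clusters whose
#' interval completely contains any other annotated gene (sense or
#' antisense). The unannotated region of each record is the cluster portion
#' lying 3' (in gene orientation) of the annotated 3' UTR end.
#'
#' @param clusters A `pirna_clusters` table from [call_utr3_clusters()]
#'   (every cluster must carry a source gene).
#' @param genes A [gene_models()] table.
#' @param min_beyond_frac Selection threshold on the beyond-UTR fraction;
#'   strict inequality. Default 0.30.
#' @return Data frame of xUTR records: `cluster_id`, `gene_id`, the
#'   unannotated region coordinates, and `beyond_fraction`.
#' @export
select_extended <- function(clusters, genes, min_beyond_frac = 0.30) {
  if (any(is.na(clusters$source_gene)))
    stop("select_extended requires clusters with source genes")
  spans <- gene_spans(genes)
  keep <- logical(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    frac <- clusters$beyond_utr_bases[i] /
      (clusters$end[i] - clusters$start[i])
    if (frac <= min_beyond_frac) next
    other <- spans[spans$gene_id != clusters$source_gene[i] &
                     spans$chrom == clusters$chrom[i], , drop = FALSE]
    contains <- other$start >= clusters$start[i] &
      other$end <= clusters$end[i]
    keep[i] <- !any(contains)
  }
  sel <- clusters[keep, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(data.frame(cluster_id = character(0), gene_id = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      beyond_fraction = numeric(0)))
  }
  g <- genes[match(sel$source_tx, genes$tx_id), , drop = FALSE]
  un_start <- ifelse(sel$strand == "+", g$utr3_end, sel$start)
  un_end <- ifelse(sel$strand == "+", sel$end, g$utr3_start)
  data.frame(cluster_id = sel$cluster_id, gene_id = sel$source_gene,
             chrom = sel$chrom, start = un_start, end = un_end,
             strand = sel$strand,
             beyond_fraction = sel$beyond_utr_bases / (sel$end - sel$start),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' RPKM-style expression of a region
#'
#' Counts RNA-seq reads intersecting the region by at least one base in
#' the sense direction (read strand equal to region strand) and returns
#' `n * 1e9 / (length * total_aligned)`.
#'
#' @param region One-row stranded interval data frame.
#' @param rnaseq_reads [aligned_reads()] table of RNA-seq alignments.
#' @param total_aligned Total aligned reads in the library.
#' @return List with `n_reads` and `rpkm`.
#' @examples
#' reg <- genomic_intervals("chr1", 0, 1000, "+")
#' @export
region_rpkm <- function(region, rnaseq_reads, total_aligned) {
  stopifnot(total_aligned >= 1)
  len <- region$end - region$start
  if (length(len) != 1L || len <= 0) stop("region must be a single non-empty interval")
  n <- sum(rnaseq_reads$chrom == region$chrom &
             rnaseq_reads$strand == region$strand &
             rnaseq_reads$start < region$end &
             rnaseq_reads$end > region$start)
  list(n_reads = n, rpkm = n * 1e9 / (len * total_aligned))
}

#' Shuffle regions into intergenic space
#'
#' For every input region, draws a same-length region on the same
#' chromosome, uniformly at random within intergenic space and overlapping
#' no annotated base (gene spans and repeats). Shuffled regions may
#' overlap each other. Placement is deterministic for a fixed RNG state.
#'
#' @param regions Interval data frame to shuffle.
#' @param tracks An [annotation_tracks()] list (defines annotated space).
#' @param chrom_lengths Named chromosome lengths.
#' @param max_tries Retries per region before failing, default 1000.
#' @return Interval data frame of shuffled regions (strand of the input is
#'   carried over).
#' @export
shuffled_background <- function(regions, tracks, chrom_lengths,
                                max_tries = 1000L) {
  ann <- rbind(gene_spans(tracks$genes)[, c("chrom", "start", "end")],
               tracks$repeats[, c("chrom", "start", "end")])
  out <- regions
  for (i in seq_len(nrow(regions))) {
    len <- regions$end[i] - regions$start[i]
    chrom <- regions$chrom[i]
    L <- chrom_lengths[[chrom]]
    a <- ann[ann$chrom == chrom, , drop = FALSE]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- floor(runif(1, 0, L - len))
      if (!any(a$start < s + len & a$end > s)) {
        out$start[i] <- s
        out$end[i] <- s + len
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could not place shuffled region %d (%s, %d bp) in intergenic space",
                   i, chrom, len))
  }
  out
}

#' Expression cutoff from background regions
#'
#' The empirical `q`-quantile (linear interpolation between order
#' statistics) of background RPKM values; a region counts as expressed
#' when its RPKM exceeds this cutoff, so a fraction `q` of background
#' regions lie below it.
#'
#' @param background_rpkm Numeric vector of background RPKM values
#'   (at least 20).
#' @param q Quantile, default 0.95.
#' @return The RPKM cutoff.
#' @export
expression_cutoff <- function(background_rpkm, q = 0.95) {
  if (length(background_rpkm) < 20L)
    stop("need at least 20 background records")
  as.numeric(stats::quantile(background_rpkm, q, type = 7, names = FALSE))
}

#' Quantify xUTR records against RNA-seq data
#'
#' Computes the RPKM of each record's unannotated region and of its host
#' gene's annotated mRNA (union of annotated exons, sense strand), and
#' flags records whose unannotated region exceeds a background-derived
#' expression cutoff.
#'
#' @param xutr Output of [select_extended()].
#' @param genes A [gene_models()] table.
#' @param rnaseq_reads RNA-seq [aligned_reads()].
#' @param total_aligned Library size; defaults to `nrow(rnaseq_reads)`.
#' @param cutoff RPKM cutoff from [expression_cutoff()].
#' @return The input with `rpkm_unannotated`, `rpkm_mrna` and `expressed`
#'   columns appended.
#' @export
quantify_xutr <- function(xutr, genes, rnaseq_reads,
                          total_aligned = nrow(rnaseq_reads), cutoff) {
  ex <- exon_intervals(genes)
  n <- nrow(xutr)
  rpkm_un <- numeric(n)
  rpkm_mr <- numeric(n)
  for (i in seq_len(n)) {
    rec <- region_rpkm(xutr[i, c("chrom", "start", "end", "strand")],
                       rnaseq_reads, total_aligned)
    rpkm_un[i] <- rec$rpkm
    ge <- ex[ex$gene_id == xutr$gene_id[i], , drop = FALSE]
    ge <- merge_overlapping(genomic_intervals(ge$chrom, ge$start, ge$end))
    cnt <- 0L
    for (j in seq_len(nrow(ge))) {
      cnt <- cnt + region_rpkm(
        genomic_intervals(ge$chrom[j], ge$start[j], ge$end[j],
                          xutr$strand[i]),
        rnaseq_reads, total_aligned)$n_reads
    }
    rpkm_mr[i] <- cnt * 1e9 / (sum(ge$end - ge$start) * total_aligned)
  }
  xutr$rpkm_unannotated <- rpkm_un
  xutr$rpkm_mrna <- rpkm_mr
  xutr$expressed <- rpkm_un > cutoff
  xutr
}
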