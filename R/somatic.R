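# Somatic 3' UTR small-RNA cluster calling by density rules and
# MIWI2-dependence classification from wild-type/knockout library pairs.

#' Call somatic 3' UTR small-RNA clusters
#'
#' Per coding gene, using the largest 3' UTR isoform as the cluster
#' region: keeps genes where the per-bp density of sense small RNAs in the
#' 3' UTR is at least `ratio` times that in the coding region, with at
#' least `min_reads` sense reads in the UTR and a normalised density
#' `n * 1e9 / (utr_length * total_aligned)` strictly above `min_density`
#' (reads per kb of 3' UTR per million aligned reads). The 3' boundary is
#' then extended in `ext_step`-bp windows while each window holds at least
#' one sense read, stopping at the 5' end of the next same-strand gene.
#'
#' @param reads Strict-mode [aligned_reads()].
#' @param genes A [gene_models()] table; genes without a CDS or 3' UTR are
#'   skipped.
#' @param total_aligned Library size; defaults to `nrow(reads)`.
#' @param min_reads Minimum sense reads in the UTR, default 3.
#' @param min_density Density threshold (reads/kb UTR/million aligned),
#'   default 7.5; applied to the pre-extension boundary.
#' @param ratio Minimum UTR-to-CDS per-bp density ratio, default 2.
#' @param ext_step 3'-extension window in bp, default 2000.
#' @param chrom_lengths Named chromosome lengths (extension bound).
#' @return Data frame of class `somatic_clusters`: one row per called
#'   gene with the (possibly 3'-extended) cluster interval, sense read
#'   count and the three densities.
#' @export
call_somatic_clusters <- function(reads, genes, total_aligned = nrow(reads),
                                  min_reads = 3L, min_density = 7.5,
                                  ratio = 2.0, ext_step = 2000,
                                  chrom_lengths = NULL) {
  stopifnot(total_aligned >= 1)
  spans <- gene_spans(genes)
  out <- list()
  for (gid in unique(genes$gene_id)) {
    iso <- genes[genes$gene_id == gid & genes$coding &
                   !is.na(genes$utr3_start) & !is.na(genes$cds_start), ,
                 drop = FALSE]
    if (nrow(iso) == 0L) next
    iso <- iso[which.max(iso$utr3_end - iso$utr3_start), ]
    strand <- iso$strand
    chrom <- iso$chrom
    sense <- reads[reads$chrom == chrom & reads$strand == strand, ,
                   drop = FALSE]
    utr_len <- iso$utr3_end - iso$utr3_start
    cds_len <- iso$cds_end - iso$cds_start
    n_utr <- sum(sense$start < iso$utr3_end & sense$end > iso$utr3_start)
    n_cds <- sum(sense$start < iso$cds_end & sense$end > iso$cds_start)
    utr_density <- n_utr / utr_len
    cds_density <- n_cds / cds_len
    density <- n_utr * 1e9 / (utr_len * total_aligned)
    if (n_utr < min_reads) next
    if (utr_density < ratio * cds_density) next
    if (density <= min_density) next
    lo <- iso$utr3_start
    hi <- iso$utr3_end
    # 3' extension, bounded by the next same-strand gene (or chromosome end)
    same <- spans[spans$chrom == chrom & spans$strand == strand &
                    spans$gene_id != gid, , drop = FALSE]
    if (strand == "+") {
      bound <- suppressWarnings(min(same$start[same$start >= hi]))
      if (!is.finite(bound))
        bound <- if (is.null(chrom_lengths)) max(sense$end, hi) else
          chrom_lengths[[chrom]]
      repeat {
        whi <- min(bound, hi + ext_step)
        if (whi <= hi) break
        if (sum(sense$start < whi & sense$end > hi) >= 1L) hi <- whi
        else break
      }
    } else {
      bound <- suppressWarnings(max(same$end[same$end <= lo]))
      if (!is.finite(bound))
        bound <- if (is.null(chrom_lengths)) min(sense$start, lo) else 0
      repeat {
        wlo <- max(bound, lo - ext_step)
        if (wlo >= lo) break
        if (sum(sense$start < lo & sense$end > wlo) >= 1L) lo <- wlo
        else break
      }
    }
    n_final <- sum(sense$start < hi & sense$end > lo)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gid, chrom = chrom, start = lo, end = hi, strand = strand,
      n_sense = n_final, density = density, utr_density = utr_density,
      cds_density = cds_density, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), strand = character(0),
               n_sense = integer(0), density = numeric(0),
               utr_density = numeric(0), cds_density = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("somatic_clusters", "data.frame")
  res
}

#' Classify somatic clusters as MIWI2-dependent or -independent
#'
#' Per cluster, computes the wild-type small-RNA density (reads per kb per
#' million aligned) and the knockout read count. Clusters with any
#' knockout reads are MIWI2-independent. Clusters with no knockout reads
#' and a WT density in the bottom quartile (density less than or equal to
#' the linear-interpolation 25th percentile over all clusters) are
#' filtered as too weakly supported to call; the remainder are
#' MIWI2-dependent.
#'
#' @param clusters A `somatic_clusters` table (called from WT data).
#' @param wt_reads,ko_reads Strict-mode [aligned_reads()] for the
#'   wild-type and knockout libraries.
#' @param wt_total,ko_total Library sizes; default to the row counts.
#' @return Data frame of class `dependence_calls` with `gene_id`,
#'   `wt_density`, `ko_reads`, and `verdict` in
#'   `c("independent", "dependent", "filtered")`.
#' @export
classify_miwi2_dependence <- function(clusters, wt_reads, ko_reads,
                                      wt_total = nrow(wt_reads),
                                      ko_total = nrow(ko_reads)) {
  if (nrow(clusters) == 0L) stop("no clusters to classify")
  n <- nrow(clusters)
  wt_density <- numeric(n)
  ko_n <- integer(n)
  for (i in seq_len(n)) {
    cl <- clusters[i, ]
    len <- cl$end - cl$start
    n_wt <- sum(wt_reads$chrom == cl$chrom & wt_reads$strand == cl$strand &
                  wt_reads$start < cl$end & wt_reads$end > cl$start)
    ko_n[i] <- sum(ko_reads$chrom == cl$chrom &
                     ko_reads$strand == cl$strand &
                     ko_reads$start < cl$end & ko_reads$end > cl$start)
    wt_density[i] <- n_wt * 1e9 / (len * wt_total)
  }
  q1 <- as.numeric(stats::quantile(wt_density, 0.25, type = 7,
                                   names = FALSE))
  verdict <- ifelse(ko_n >= 1L, "independent",
                    ifelse(wt_density <= q1, "filtered", "dependent"))
  res <- data.frame(gene_id = clusters$gene_id, wt_density = wt_density,
                    ko_reads = ko_n, verdict = verdict,
                    stringsAsFactors = FALSE)
  attr(res, "q1_wt_density") <- q1
  class(res) <- c("dependence_calls", "data.frame")
  res
}

#' @export
print.dependence_calls <- function(x, ...) {
  tab <- table(factor(x$verdict,
                      levels = c("dependent", "independent", "filtered")))
  cat("MIWI2 dependence calls:\n")
  cat(sprintf("  dependent: %d  independent: %d  filtered: %d\n",
              tab[["dependent"]], tab[["independent"]], tab[["filtered"]]))
  cat(sprintf("  WT density Q1: %.3g\n", attr(x, "q1_wt_density")))
  invisible(x)
}

#' @export
print.somatic_clusters <- function(x, ...) {
  cat(sprintf("Somatic 3' UTR small-RNA clusters: %d gene(s)\n", nrow(x)))
  if (nrow(x))
    cat(sprintf("  median density: %.2f reads/kb/M\n",
                stats::median(x$density)))
  invisible(x)
}
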