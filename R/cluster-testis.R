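# Density-based seeding of read pileups and the two cluster-refinement
# chains for the testis dataset: 3' UTR piRNA clusters and
# intergenic/other piRNA clusters.

#' Kernel-density seed regions of small-RNA enrichment
#'
#' Estimates a Gaussian kernel density over read 5' positions (bandwidth =
#' `feature_length / 2`) and keeps maximal runs of positions whose density
#' exceeds the mean plus `k_sd` standard deviations of the density expected
#' for the same number of reads placed uniformly over the chromosome. The
#' null mean and SD are computed analytically from the kernel
#' (`null = "analytic"`) or by permutation rounds of uniform placements.
#'
#' @param reads An [aligned_reads()] table (strict-mode alignments).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param feature_length Kernel feature length in bp; the Gaussian
#'   bandwidth is half of it. Default 1000.
#' @param k_sd Threshold in null standard deviations above the null mean,
#'   default 15.
#' @param grid_step Spacing of the density evaluation grid in bp.
#' @param null `"analytic"` or `"permutation"`.
#' @param n_perm Number of permutation rounds when `null = "permutation"`.
#' @return Data frame of seed regions: `chrom`, `start`, `end`, `strand`
#'   (`"*"`; seeding pools both strands), `peak_density` (reads/bp),
#'   `n_reads`.
#' @export
density_seeds <- function(reads, chrom_lengths, feature_length = 1000,
                          k_sd = 15, grid_step = 25,
                          null = c("analytic", "permutation"), n_perm = 20L) {
  null <- match.arg(null)
  stopifnot(!is.null(names(chrom_lengths)))
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      peak_density = numeric(0), n_reads = integer(0))
  if (nrow(reads) == 0L) return(empty)
  bw <- feature_length / 2
  out <- list()
  for (chrom in intersect(names(chrom_lengths), unique(reads$chrom))) {
    L <- chrom_lengths[[chrom]]
    sub <- reads[reads$chrom == chrom, , drop = FALSE]
    x <- five_prime_pos(sub)
    n <- length(x)
    npt <- max(512L, ceiling(L / grid_step))
    d <- stats::density(x, bw = bw, from = 0, to = L, n = npt)
    dens <- d$y * n                        # reads per bp
    if (null == "analytic") {
      mu0 <- n / L
      v <- n * (1 / (2 * bw * sqrt(pi) * L) - 1 / L^2)
      sd0 <- sqrt(max(v, 0))
    } else {
      vals <- unlist(lapply(seq_len(n_perm), function(i) {
        stats::density(runif(n, 0, L), bw = bw, from = 0, to = L,
                       n = npt)$y * n
      }))
      mu0 <- mean(vals)
      sd0 <- stats::sd(vals)
    }
    thr <- mu0 + k_sd * sd0
    above <- dens > thr
    if (!any(above)) next
    r <- rle(above)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    spacing <- d$x[2] - d$x[1]
    for (j in which(r$values)) {
      lo <- max(0, d$x[starts_i[j]] - spacing / 2)
      hi <- min(L, d$x[ends_i[j]] + spacing / 2)
      keep <- sub$start < hi & sub$end > lo
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = floor(lo), end = ceiling(hi), strand = "*",
        peak_density = max(dens[starts_i[j]:ends_i[j]]),
        n_reads = sum(keep), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Sorted per-chromosome read coordinate index for fast window counts.
read_index <- function(reads, strand = NULL) {
  if (!is.null(strand)) reads <- reads[reads$strand == strand, , drop = FALSE]
  lapply(split(reads[, c("start", "end")], reads$chrom), function(df) {
    list(starts = sort(df$start), ends = sort(df$end))
  })
}

idx_count <- function(idx, chrom, lo, hi) {
  ci <- idx[[chrom]]
  if (is.null(ci)) return(0L)
  count_intersecting(ci$starts, ci$ends, lo, hi)
}

# Iteratively extend [lo, hi) by `step`-bp flank windows while a candidate
# window contains >= min_reads read alignments. Both flanks independently.
extend_by_windows <- function(idx, chrom, lo, hi, step, min_reads,
                              chrom_len) {
  repeat {
    grew <- FALSE
    wlo <- max(0, lo - step)
    if (lo > 0 && idx_count(idx, chrom, wlo, lo) >= min_reads) {
      lo <- wlo
      grew <- TRUE
    }
    whi <- min(chrom_len, hi + step)
    if (hi < chrom_len && idx_count(idx, chrom, hi, whi) >= min_reads) {
      hi <- whi
      grew <- TRUE
    }
    if (!grew) break
  }
  c(lo, hi)
}

reads_in <- function(reads, chrom, lo, hi) {
  reads[reads$chrom == chrom & reads$start < hi & reads$end > lo, ,
        drop = FALSE]
}

new_clusters <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("pirna_clusters", "data.frame")
  df
}

empty_clusters <- function() {
  new_clusters(data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), strand = character(0),
                          cluster_id = character(0),
                          source_gene = character(0),
                          source_tx = character(0),
                          n_sense = integer(0), n_antisense = integer(0),
                          kind = character(0),
                          beyond_utr_bases = numeric(0)))
}

#' Call 3' UTR piRNA clusters from seed regions
#'
#' Refines density seeds into 3' UTR clusters: (1) extend each seed in
#' `ext_step`-bp windows while a candidate window holds at least
#' `ext_min_reads` alignments; (2) merge overlapping regions; (3) shrink to
#' aligned reads; (4) keep regions overlapping a coding gene's 3' UTR by at
#' least 1 bp; (5) keep unidirectional regions (> `strand_frac` of reads on
#' one strand) and call that strand; (6) assign as source the gene whose
#' 3' UTR has the greatest sense-direction overlap; (7) trim the cluster 5'
#' end to the annotated 3' UTR start; (8) shrink to sense-strand reads;
#' (9) truncate any 3'-end overlap with an adjacent gene, but retain
#' clusters that completely contain that gene.
#'
#' @param seeds Output of [density_seeds()].
#' @param reads Strict-mode [aligned_reads()].
#' @param genes A [gene_models()] table; non-coding genes are ignored.
#' @param chrom_lengths Named chromosome lengths.
#' @param ext_step,ext_min_reads Extension window (bp) and the minimum
#'   alignments per window; defaults 1000 and 2.
#' @param strand_frac Unidirectionality threshold (exclusive), default 0.6.
#' @return A `pirna_clusters` data frame with per-cluster strand call,
#'   source gene and isoform, sense/antisense read counts, and
#'   `beyond_utr_bases`, the cluster bases lying 3' of the annotated
#'   3' UTR end.
#' @export
call_utr3_clusters <- function(seeds, reads, genes, chrom_lengths,
                               ext_step = 1000, ext_min_reads = 2,
                               strand_frac = 0.6) {
  if (nrow(seeds) == 0L) return(empty_clusters())
  idx <- read_index(reads)
  utr3s <- utr3_intervals(genes, coding_only = TRUE)
  spans <- gene_spans(genes)
  out <- list()
  for (chrom in unique(seeds$chrom)) {
    L <- chrom_lengths[[chrom]]
    sd_sub <- seeds[seeds$chrom == chrom, , drop = FALSE]
    ext <- t(vapply(seq_len(nrow(sd_sub)), function(i) {
      extend_by_windows(idx, chrom, sd_sub$start[i], sd_sub$end[i],
                        ext_step, ext_min_reads, L)
    }, numeric(2)))
    merged <- merge_overlapping(genomic_intervals(chrom, ext[, 1], ext[, 2]))
    for (i in seq_len(nrow(merged))) {
      reg <- shrink_to_reads(merged[i, ], reads)
      if (nrow(reg) == 0L) next
      ov_utr <- overlap_vec(reg$chrom, reg$start, reg$end, utr3s)
      if (!any(ov_utr > 0)) next
      rr <- reads_in(reads, chrom, reg$start, reg$end)
      n_plus <- sum(rr$strand == "+")
      n_minus <- sum(rr$strand == "-")
      if (max(n_plus, n_minus) / (n_plus + n_minus) <= strand_frac) next
      cl_strand <- if (n_plus > n_minus) "+" else "-"
      cand <- which(ov_utr > 0 & utr3s$strand == cl_strand)
      if (length(cand) == 0L) next
      ord <- order(-ov_utr[cand],
                   -(utr3s$end[cand] - utr3s$start[cand]),
                   utr3s$gene_id[cand])
      src <- utr3s[cand[ord[1]], ]
      lo <- reg$start
      hi <- reg$end
      if (cl_strand == "+") lo <- max(lo, src$start) else hi <- min(hi, src$end)
      if (lo >= hi) next
      reg2 <- shrink_to_reads(genomic_intervals(chrom, lo, hi, cl_strand),
                              reads, strand_filter = cl_strand)
      if (nrow(reg2) == 0L) next
      # a read straddling the UTR start must not undo the 5' trim
      lo <- if (cl_strand == "+") max(reg2$start, src$start) else reg2$start
      hi <- if (cl_strand == "-") min(reg2$end, src$end) else reg2$end
      if (lo >= hi) next
      # 3'-end overlap with adjacent genes: truncate unless the cluster
      # completely contains the other gene's span.
      other <- spans[spans$gene_id != src$gene_id & spans$chrom == chrom, ,
                     drop = FALSE]
      ov_g <- overlap_vec(chrom, lo, hi, other)
      for (k in which(ov_g > 0)) {
        g <- other[k, ]
        if (lo <= g$start && hi >= g$end) next     # fully contained: retain
        if (cl_strand == "+" && g$start > lo) hi <- min(hi, g$start)
        if (cl_strand == "-" && g$end < hi) lo <- max(lo, g$end)
      }
      if (lo >= hi) next
      reg3 <- shrink_to_reads(genomic_intervals(chrom, lo, hi, cl_strand),
                              reads, strand_filter = cl_strand)
      if (nrow(reg3) == 0L) next
      # straddling reads must not undo the 5' trim or the 3' truncation
      reg3$start <- max(reg3$start, lo)
      reg3$end <- min(reg3$end, hi)
      rr <- reads_in(reads, chrom, reg3$start, reg3$end)
      n_sense <- sum(rr$strand == cl_strand)
      n_anti <- nrow(rr) - n_sense
      if (n_sense / (n_sense + n_anti) <= strand_frac) next
      beyond <- if (cl_strand == "+") max(0, reg3$end - src$end) else
        max(0, src$start - reg3$start)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = reg3$start, end = reg3$end,
        strand = cl_strand, cluster_id = NA_character_,
        source_gene = src$gene_id, source_tx = src$tx_id,
        n_sense = n_sense, n_antisense = n_anti, kind = "utr3",
        beyond_utr_bases = beyond, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_clusters())
  res <- do.call(rbind, out)
  res$cluster_id <- sprintf("tc%04d", seq_len(nrow(res)))
  new_clusters(res)
}

# Expand clusters to the union span with repeat elements lying within
# `gap` bp, merging clusters that become connected; iterate to a fix point.
merge_with_repeats <- function(regions, repeats, gap = 50) {
  repeat {
    before <- regions
    for (i in seq_len(nrow(regions))) {
      near <- repeats$chrom == regions$chrom[i] &
        repeats$start <= regions$end[i] + gap &
        repeats$end >= regions$start[i] - gap
      if (any(near)) {
        regions$start[i] <- min(regions$start[i], repeats$start[near])
        regions$end[i] <- max(regions$end[i], repeats$end[near])
      }
    }
    regions <- do.call(rbind, lapply(split(regions, regions$chrom),
                                     merge_overlapping))
    rownames(regions) <- NULL
    if (nrow(regions) == nrow(before) &&
        all(regions$start == before$start) && all(regions$end == before$end))
      return(regions)
  }
}

# CDS-exon and 3' UTR sub-tracks used to classify non-UTR clusters.
genic_subtracks <- function(genes) {
  ex <- exon_intervals(genes)
  cds <- genes[!is.na(genes$cds_start), , drop = FALSE]
  cds_iv <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  if (nrow(cds) > 0L && nrow(ex) > 0L) {
    keep <- lapply(seq_len(nrow(cds)), function(i) {
      e <- ex[ex$gene_id == cds$gene_id[i], , drop = FALSE]
      s <- pmax(e$start, cds$cds_start[i])
      en <- pmin(e$end, cds$cds_end[i])
      ok <- en > s
      data.frame(chrom = e$chrom[ok], start = s[ok], end = en[ok])
    })
    cds_iv <- do.call(rbind, keep)
  }
  list(exon = cds_iv,
       utr = utr3_intervals(genes, coding_only = FALSE),
       intron = intron_intervals(genes))
}

#' Call intergenic and other piRNA clusters from seed regions
#'
#' Refinement chain for clusters away from 3' UTRs: (1) extend seeds in
#' `ext_step`-bp windows holding at least `ext_min_reads` alignment;
#' (2) merge clusters with repeat elements lying within `repeat_gap` bp
#' (union of spans), since unique alignments cannot cover the repeats that
#' intergenic clusters span; (3) repeat the window extension; (4) flag
#' clusters that grew by more than `growth_flag_frac` of their pre-step-3
#' length and split any flagged cluster in which two opposite-strand read
#' blocks merged, at the midpoint between the blocks; (5) shrink to aligned
#' reads; (6) classify each cluster as exon, UTR or intron when at least
#' half of its contained sequences fall in that track, else intergenic.
#'
#' @inheritParams call_utr3_clusters
#' @param repeats Repeat-element interval data frame.
#' @param repeat_gap Maximum cluster-to-repeat gap merged over, default 50.
#' @param growth_flag_frac Fractional growth that flags a cluster for the
#'   strand-split check, default 0.2.
#' @return A `pirna_clusters` data frame with `kind` in
#'   `c("exon", "utr_other", "intron", "intergenic")`.
#' @export
call_other_clusters <- function(seeds, reads, repeats, genes, chrom_lengths,
                                ext_step = 500, ext_min_reads = 1,
                                repeat_gap = 50, growth_flag_frac = 0.2) {
  if (nrow(seeds) == 0L) return(empty_clusters())
  idx <- read_index(reads)
  sub_tracks <- genic_subtracks(genes)
  out <- list()
  for (chrom in unique(seeds$chrom)) {
    L <- chrom_lengths[[chrom]]
    sd_sub <- seeds[seeds$chrom == chrom, , drop = FALSE]
    ext <- t(vapply(seq_len(nrow(sd_sub)), function(i) {
      extend_by_windows(idx, chrom, sd_sub$start[i], sd_sub$end[i],
                        ext_step, ext_min_reads, L)
    }, numeric(2)))
    regions <- merge_overlapping(genomic_intervals(chrom, ext[, 1], ext[, 2]))
    regions <- merge_with_repeats(regions, repeats, repeat_gap)
    pre_len <- regions$end - regions$start
    ext2 <- t(vapply(seq_len(nrow(regions)), function(i) {
      extend_by_windows(idx, chrom, regions$start[i], regions$end[i],
                        ext_step, ext_min_reads, L)
    }, numeric(2)))
    # clusters that grew beyond growth_flag_frac of their pre-extension
    # length during this round - e.g. by hopping along stray reads after
    # a repeat merge - may have swallowed an opposite-strand population
    # and get the strand-split check
    merged2 <- merge_overlapping(genomic_intervals(chrom, ext2[, 1],
                                                   ext2[, 2]))
    pieces <- list()
    for (i in seq_len(nrow(merged2))) {
      members <- which(ext2[, 1] < merged2$end[i] &
                         ext2[, 2] > merged2$start[i])
      base_len <- sum(pre_len[members])
      grown <- (merged2$end[i] - merged2$start[i] - base_len) >
        growth_flag_frac * base_len
      iv <- c(merged2$start[i], merged2$end[i])
      if (grown) {
        rr <- reads_in(reads, chrom, iv[1], iv[2])
        split_at <- strand_split_point(rr)
        if (!is.na(split_at)) {
          pieces[[length(pieces) + 1L]] <- c(iv[1], split_at)
          pieces[[length(pieces) + 1L]] <- c(split_at, iv[2])
          next
        }
      }
      pieces[[length(pieces) + 1L]] <- iv
    }
    for (iv in pieces) {
      reg <- shrink_to_reads(genomic_intervals(chrom, iv[1], iv[2]), reads)
      if (nrow(reg) == 0L) next
      rr <- reads_in(reads, chrom, reg$start, reg$end)
      n_plus <- sum(rr$strand == "+")
      n_minus <- nrow(rr) - n_plus
      cl_strand <- if (n_plus >= n_minus) "+" else "-"
      kind <- "intergenic"
      for (nm in c("exon", "utr", "intron")) {
        tr <- sub_tracks[[nm]]
        if (nrow(tr) == 0L) next
        ov <- track_overlap(rr, tr, mode = "sum")
        frac_in <- mean(ov >= 0.5 * (rr$end - rr$start))
        if (frac_in >= 0.5) {
          kind <- c(exon = "exon", utr = "utr_other", intron = "intron")[[nm]]
          break
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = reg$start, end = reg$end, strand = cl_strand,
        cluster_id = NA_character_, source_gene = NA_character_,
        source_tx = NA_character_,
        n_sense = max(n_plus, n_minus), n_antisense = min(n_plus, n_minus),
        kind = kind, beyond_utr_bases = 0, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_clusters())
  res <- do.call(rbind, out)
  res$cluster_id <- sprintf("oc%04d", seq_len(nrow(res)))
  new_clusters(res)
}

# Split point for a cluster holding one plus block and one minus block in
# clean succession along the chromosome; NA when strands interleave or
# only one strand is present.
strand_split_point <- function(rr) {
  if (nrow(rr) < 2L) return(NA_real_)
  rr <- rr[order(rr$start), , drop = FALSE]
  s <- rr$strand
  if (length(unique(s)) < 2L) return(NA_real_)
  flips <- sum(s[-1] != s[-length(s)])
  if (flips != 1L) return(NA_real_)
  up <- s == s[1]
  up_end <- max(rr$end[up])
  down_start <- min(rr$start[!up])
  if (down_start < up_end) return(NA_real_)   # blocks overlap: leave intact
  floor((up_end + down_start) / 2)
}

#' @export
print.pirna_clusters <- function(x, ...) {
  cat(sprintf("piRNA clusters: %d region(s)\n", nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  kinds: %s\n",
                paste(sprintf("%s=%d", names(table(x$kind)), table(x$kind)),
                      collapse = ", ")))
    cat(sprintf("  median length: %.0f bp\n", stats::median(x$end - x$start)))
  }
  invisible(x)
}

#' @method summary pirna_clusters
#' @export
summary.pirna_clusters <- function(object, ...) {
  data.frame(kind = names(table(object$kind)),
             n = as.integer(table(object$kind)),
             median_length = vapply(names(table(object$kind)), function(k) {
               stats::median(object$end[object$kind == k] -
                               object$start[object$kind == k])
             }, numeric(1)), row.names = NULL)
}
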