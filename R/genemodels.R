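#' Construct a gene-model table
#'
#' One row per isoform. Intervals are 0-based half-open on the gene strand.
#' Exon coordinates are comma-separated lists (BED12 style, but absolute
#' genomic positions). `cds_*` and `utr3_*` are `NA` for non-coding
#' isoforms. The 3' UTR, when present, abuts or lies 3' of the CDS on the
#' gene strand: downstream of `cds_end` for `+` genes, upstream of
#' `cds_start` for `-` genes.
#'
#' @param gene_id,tx_id Gene and isoform identifiers.
#' @param chrom,strand Chromosome and gene strand (`"+"`/`"-"`).
#' @param tx_start,tx_end Transcript span.
#' @param cds_start,cds_end CDS span, `NA` when non-coding.
#' @param utr3_start,utr3_end 3' UTR span, `NA` when absent.
#' @param exon_starts,exon_ends Comma-separated absolute exon coordinates,
#'   sorted and non-overlapping.
#' @param coding Logical; whether the gene is protein-coding.
#' @return A data frame of class `gene_models`.
#' @export
gene_models <- function(gene_id, tx_id, chrom, strand, tx_start, tx_end,
                        cds_start = NA, cds_end = NA,
                        utr3_start = NA, utr3_end = NA,
                        exon_starts, exon_ends, coding = TRUE) {
  df <- data.frame(gene_id = as.character(gene_id),
                   tx_id = as.character(tx_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   tx_start = as.numeric(tx_start),
                   tx_end = as.numeric(tx_end),
                   cds_start = as.numeric(cds_start),
                   cds_end = as.numeric(cds_end),
                   utr3_start = as.numeric(utr3_start),
                   utr3_end = as.numeric(utr3_end),
                   exon_starts = as.character(exon_starts),
                   exon_ends = as.character(exon_ends),
                   coding = as.logical(coding),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$strand %in% c("+", "-")),
            all(df$tx_start >= 0), all(df$tx_end > df$tx_start))
  has_utr <- !is.na(df$utr3_start)
  if (any(has_utr & is.na(df$cds_start)))
    stop("a 3' UTR requires a CDS")
  ok <- ifelse(df$strand == "+",
               df$utr3_start >= df$cds_end, df$utr3_end <= df$cds_start)
  if (any(has_utr & !ok))
    stop("3' UTR must lie 3' of the CDS on the gene strand")
  class(df) <- c("gene_models", "data.frame")
  df
}

parse_pos_list <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])

# Per-isoform exon intervals as one interval table.
exon_intervals <- function(genes) {
  if (nrow(genes) == 0L)
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    s <- parse_pos_list(genes$exon_starts[i])
    e <- parse_pos_list(genes$exon_ends[i])
    data.frame(chrom = genes$chrom[i], start = s, end = e,
               strand = genes$strand[i], gene_id = genes$gene_id[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Intron intervals (gaps between consecutive exons of each isoform).
intron_intervals <- function(genes) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    s <- parse_pos_list(genes$exon_starts[i])
    e <- parse_pos_list(genes$exon_ends[i])
    if (length(s) < 2L) return(NULL)
    data.frame(chrom = genes$chrom[i], start = e[-length(e)], end = s[-1],
               strand = genes$strand[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0))
  out
}

# 3' UTR intervals of coding isoforms, one row per isoform that has one.
utr3_intervals <- function(genes, coding_only = TRUE) {
  keep <- !is.na(genes$utr3_start)
  if (coding_only) keep <- keep & genes$coding
  g <- genes[keep, , drop = FALSE]
  data.frame(chrom = g$chrom, start = g$utr3_start, end = g$utr3_end,
             strand = g$strand, gene_id = g$gene_id, tx_id = g$tx_id,
             stringsAsFactors = FALSE)
}

# Gene transcript spans collapsed per gene (min start / max end).
gene_spans <- function(genes) {
  if (nrow(genes) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      gene_id = character(0)))
  sp <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$tx_start),
               end = max(g$tx_end), strand = g$strand[1],
               gene_id = g$gene_id[1], stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

#' Bundle annotation tracks for read classification
#'
#' @param genes A [gene_models()] table.
#' @param repeats Interval data frame of repeat elements.
#' @return A list with components `repeats`, `mrna_exons`, `introns` and
#'   `genes`, the track set consumed by [classify_reads()] and the cluster
#'   callers.
#' @export
annotation_tracks <- function(genes, repeats) {
  validate_intervals(repeats)
  list(repeats = repeats,
       mrna_exons = exon_intervals(genes),
       introns = intron_intervals(genes),
       genes = genes)
}
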