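# File I/O. BED is 0-based half-open, which matches the internal
# convention, so coordinates pass through unshifted.

#' Read a BED6 file of aligned small-RNA reads
#'
#' The name column carries the read identifier and the score column the
#' collapsed copy count. Extra columns beyond the sixth, if present, are
#' read as `sequence`, `mismatches` and `n_alignments`.
#'
#' @param path Path to a tab-separated BED6(+) file without header.
#' @return An [aligned_reads()] table.
#' @export
read_reads_bed <- function(path) {
  if (file.size(path) == 0L)
    return(aligned_reads(character(0), numeric(0), numeric(0),
                         character(0)))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "read_id", "copies", "strand")
  extra <- c("sequence", "mismatches", "n_alignments")
  if (ncol(df) > 6L)
    names(df)[7:min(9L, ncol(df))] <- extra[seq_len(min(3L, ncol(df) - 6L))]
  has_seq <- "sequence" %in% names(df) && !any(df$sequence == "*")
  aligned_reads(df$chrom, df$start, df$end, df$strand, df$read_id,
                sequence = if (has_seq) df$sequence,
                copies = df$copies,
                mismatches = if ("mismatches" %in% names(df)) df$mismatches else 0L,
                n_alignments = if ("n_alignments" %in% names(df)) df$n_alignments else 1L)
}

#' Write aligned reads as BED6(+3)
#'
#' @param reads An [aligned_reads()] table.
#' @param path Output path.
#' @export
write_reads_bed <- function(reads, path) {
  seq_col <- if (!is.null(reads$sequence)) reads$sequence else
    rep("*", nrow(reads))
  out <- data.frame(reads$chrom, format_coord(reads$start),
                    format_coord(reads$end), reads$read_id, reads$copies,
                    reads$strand, seq_col,
                    reads$mismatches, reads$n_alignments)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a BED6 interval file
#'
#' @param path Path to a BED file (first six columns used; fewer allowed).
#' @return An interval data frame with a `name` column when present.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0)))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df)[seq_len(min(6L, ncol(df)))] <- cols[seq_len(min(6L, ncol(df)))]
  if (!"strand" %in% names(df)) df$strand <- "*"
  validate_intervals(df)
  df
}

#' Write intervals as BED6
#'
#' @param regions Interval data frame; optional `name` and `score` columns
#'   populate BED columns 4 and 5.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  n <- nrow(regions)
  out <- data.frame(regions$chrom, format_coord(regions$start),
                    format_coord(regions$end),
                    if ("name" %in% names(regions)) regions$name else ".",
                    if ("score" %in% names(regions)) regions$score else 0L,
                    if ("strand" %in% names(regions)) regions$strand else
                      rep("*", n))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read and write gene models as TSV
#'
#' Gene models travel as a headered TSV with one row per isoform and the
#' columns of [gene_models()].
#'
#' @param path File path.
#' @return `read_gene_models` returns a [gene_models()] table.
#' @export
read_gene_models <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  gene_models(df$gene_id, df$tx_id, df$chrom, df$strand,
              df$tx_start, df$tx_end, df$cds_start, df$cds_end,
              df$utr3_start, df$utr3_end, df$exon_starts, df$exon_ends,
              df$coding)
}

#' @rdname read_gene_models
#' @param genes A [gene_models()] table.
#' @export
write_gene_models <- function(genes, path) {
  write_tsv(as.data.frame(genes), path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
}

read_tsv <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Write collapsed sequences as FASTA
#'
#' Copy counts are encoded in the header as `>id_x<copies>`, the usual
#' convention for collapsed small-RNA FASTA files.
#'
#' @param sequences Character vector of sequences.
#' @param ids Identifiers (without the copy suffix).
#' @param copies Integer copy counts.
#' @param path Output path.
#' @export
write_collapsed_fasta <- function(sequences, ids, copies, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- sprintf("%s_x%d", ids, as.integer(copies))
  Biostrings::writeXStringSet(x, path)
}

#' Read a collapsed FASTA file
#'
#' @param path FASTA path; headers may carry `_x<copies>` suffixes.
#' @return Data frame with `read_id`, `sequence`, `copies`.
#' @export
read_collapsed_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- names(x)
  m <- regmatches(ids, regexec("^(.*)_x(\\d+)$", ids))
  copies <- vapply(m, function(g) if (length(g) == 3L) as.integer(g[3]) else 1L,
                   integer(1))
  base_id <- vapply(seq_along(m), function(i)
    if (length(m[[i]]) == 3L) m[[i]][2] else ids[i], character(1))
  data.frame(read_id = base_id, sequence = as.character(x),
             copies = copies, stringsAsFactors = FALSE)
}
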