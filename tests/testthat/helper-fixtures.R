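# Shared fixture builders. Everything is generated in code; no files.

# Two coding genes on chr1: gA on +, gB on -; gC is a small downstream
# gene used for adjacency/containment tests.
mini_genes <- function() {
  gene_models(
    gene_id = c("gA", "gB", "gC"),
    tx_id = c("tA", "tB", "tC"),
    chrom = "chr1",
    strand = c("+", "-", "+"),
    tx_start = c(1000, 20000, 12000),
    tx_end = c(8000, 26000, 12800),
    cds_start = c(1100, 23000, 12100),
    cds_end = c(3500, 25900, 12700),
    utr3_start = c(3500, 20000, 12700),
    utr3_end = c(8000, 23000, 12800),
    exon_starts = c("1000,2000,3000", "20000,23800,24800", "12000"),
    exon_ends = c("1400,2400,8000", "23200,24200,26000", "12800"),
    coding = TRUE)
}

mini_chrom_lengths <- function() c(chr1 = 1e6)

# n reads of fixed length with evenly spaced 5' ends inside [lo, hi)
plant_reads <- function(n, lo, hi, strand = "+", len = 29, chrom = "chr1",
                        prefix = "r") {
  p5 <- round(seq(lo, hi - 1, length.out = n))
  if (strand == "+") {
    start <- pmin(p5, hi - len)
    end <- start + len
  } else {
    end <- pmax(p5 + 1, lo + len)
    start <- end - len
  }
  aligned_reads(chrom, start, end, strand,
                read_id = sprintf("%s%04d", prefix, seq_len(n)))
}

# independent position-bitmap oracle for interval union
bitmap_union <- function(starts, ends, max_pos) {
  bits <- logical(max_pos)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) bits[(starts[i] + 1):ends[i]] <- TRUE
  }
  bits
}

intervals_to_bitmap <- function(df, max_pos) {
  bitmap_union(df$start, df$end, max_pos)
}

# brute-force sliding-window Hamming contaminant oracle (both strands)
oracle_contaminated <- function(read, contaminants, max_mismatch) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  rv <- strsplit(read, "")[[1]]
  L <- length(rv)
  for (con in c(contaminants, vapply(contaminants, rc, character(1)))) {
    cv <- strsplit(con, "")[[1]]
    if (length(cv) < L) next
    for (off in 0:(length(cv) - L)) {
      if (sum(cv[(off + 1):(off + L)] != rv) <= max_mismatch) return(TRUE)
    }
  }
  FALSE
}

# brute-force all-pairs ping-pong site oracle
oracle_pingpong <- function(cluster, reads) {
  p5 <- ifelse(reads$strand == "+", reads$start, reads$end - 1)
  keep <- reads$chrom == cluster$chrom & p5 >= cluster$start &
    p5 < cluster$end
  reads <- reads[keep, , drop = FALSE]
  p5 <- p5[keep]
  sites <- character(0)
  for (i in seq_len(nrow(reads))) {
    for (j in seq_len(nrow(reads))) {
      if (reads$strand[i] == "+" && reads$strand[j] == "-" &&
          p5[j] - p5[i] == 9) {
        sites <- c(sites, paste(p5[i], p5[j]))
      }
    }
  }
  sort(unique(sites))
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}
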