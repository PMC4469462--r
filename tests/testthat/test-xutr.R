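# constructed cluster rows with a chosen beyond-UTR fraction over gA
# (utr3 [3500, 8000), +). cluster length 1000 ending at 8000 + beyond.
fake_cluster <- function(beyond, id = "c1") {
  len <- 1000
  end <- 8000 + beyond
  df <- data.frame(chrom = "chr1", start = end - len, end = end,
                   strand = "+", cluster_id = id, source_gene = "gA",
                   source_tx = "tA", n_sense = 10L, n_antisense = 0L,
                   kind = "utr3", beyond_utr_bases = beyond,
                   stringsAsFactors = FALSE)
  class(df) <- c("pirna_clusters", "data.frame")
  df
}

test_that("extended-UTR selection applies a strict 30% threshold", {
  genes <- mini_genes()
  for (b in c(290, 300, 310)) {
    sel <- select_extended(fake_cluster(b), genes)
    if (b > 300) {
      expect_equal(nrow(sel), 1L)
      expect_equal(sel$beyond_fraction, b / 1000)
      # unannotated region = portion 3' of the annotated UTR end
      expect_equal(sel$start, 8000)
      expect_equal(sel$end, 8000 + b)
    } else {
      expect_equal(nrow(sel), 0L)
    }
  }
  # monotone in the threshold: raising it never adds records
  many <- do.call(rbind, lapply(c(250, 310, 350, 420), fake_cluster))
  class(many) <- c("pirna_clusters", "data.frame")
  n_by_thr <- vapply(c(0.25, 0.30, 0.35, 0.40),
                     function(t) nrow(select_extended(many, genes,
                                                      min_beyond_frac = t)),
                     numeric(1))
  expect_true(all(diff(n_by_thr) <= 0))
})

test_that("clusters fully containing another gene are removed from selection", {
  genes <- mini_genes()
  # cluster [11900, 13000) contains gC [12000, 12800) entirely
  df <- fake_cluster(400)
  df$start <- 11900
  df$end <- 13000
  expect_equal(nrow(select_extended(df, genes)), 0L)
  expect_error(select_extended(transform(df, source_gene = NA_character_),
                               genes), "source gene")
})

test_that("region RPKM matches its closed form and a scan oracle", {
  reg <- genomic_intervals("chr1", 0, 1000, "+")
  reads <- plant_reads(10, 100, 900, strand = "+", len = 50)
  out <- region_rpkm(reg, reads, 1e6)
  expect_equal(out$n_reads, 10L)
  expect_equal(out$rpkm, 10 * 1e9 / (1000 * 1e6))
  expect_equal(region_rpkm(reg, reads[0, ], 1e6)$rpkm, 0)
  # antisense reads are not counted
  expect_equal(region_rpkm(genomic_intervals("chr1", 0, 1000, "-"),
                           reads, 1e6)$n_reads, 0L)
  # random placements vs a brute-force scan
  set.seed(12)
  s <- floor(runif(300, 0, 5000))
  rna <- aligned_reads("chr1", s, s + 50,
                       sample(c("+", "-"), 300, replace = TRUE))
  reg2 <- genomic_intervals("chr1", 1200, 2600, "+")
  oracle <- sum(vapply(seq_len(300), function(i) {
    rna$strand[i] == "+" && rna$start[i] < 2600 && rna$end[i] > 1200
  }, logical(1)))
  expect_equal(region_rpkm(reg2, rna, 300)$n_reads, oracle)
  # linear in count, inverse-linear in length and library size
  expect_equal(region_rpkm(reg2, rna, 600)$rpkm,
               region_rpkm(reg2, rna, 300)$rpkm / 2)
})

test_that("shuffled background preserves geometry and avoids annotation", {
  genes <- mini_genes()
  tracks <- annotation_tracks(genes,
                              genomic_intervals("chr1", 50000, 52000))
  regions <- genomic_intervals("chr1", c(8000, 20000, 400000),
                               c(9500, 21000, 402000), "+")
  set.seed(99)
  bg <- shuffled_background(regions, tracks, mini_chrom_lengths())
  expect_equal(bg$end - bg$start, regions$end - regions$start)
  expect_equal(bg$chrom, regions$chrom)
  ann <- rbind(pirclust:::gene_spans(genes)[, c("chrom", "start", "end")],
               tracks$repeats[, c("chrom", "start", "end")])
  for (i in seq_len(nrow(bg))) {
    expect_equal(sum(pirclust:::overlap_vec(bg$chrom[i], bg$start[i],
                                            bg$end[i], ann)), 0)
  }
  set.seed(99)
  bg2 <- shuffled_background(regions, tracks, mini_chrom_lengths())
  expect_identical(bg, bg2)
  # unplaceable region errors with its identity
  huge <- genomic_intervals("chr1", 0, 999000)
  expect_error(shuffled_background(huge, tracks, mini_chrom_lengths(),
                                   max_tries = 50), "region 1")
})

test_that("expression cutoff is the linear-interpolation quantile", {
  expect_equal(expression_cutoff(1:100), 95.05)
  expect_equal(sum((1:100) < expression_cutoff(1:100)), 95)
  expect_equal(expression_cutoff(rep(0, 30)), 0)
  expect_error(expression_cutoff(1:10), "20 background")
  # agreement with an order-statistic oracle on random draws
  set.seed(4)
  x <- stats::rexp(400)
  xs <- sort(x)
  h <- 1 + 0.95 * 399
  oracle <- xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)])
  expect_equal(expression_cutoff(x), oracle)
})

test_that("xUTR quantification recovers the planted isoform abundance ratio", {
  cfg <- sim_config(seed = 23)
  ann <- simulate_annotation(cfg)
  rna <- simulate_rnaseq(cfg, ann)
  man <- ann$manifest
  ratios <- vapply(seq_len(nrow(man$xutrs)), function(i) {
    x <- man$xutrs[i, ]
    r_un <- region_rpkm(genomic_intervals(x$chrom, x$start, x$end,
                                          x$strand), rna, nrow(rna))$rpkm
    g <- ann$tracks$genes[ann$tracks$genes$gene_id == x$gene_id, ]
    ex <- pirclust:::exon_intervals(g)
    n_ex <- sum(vapply(seq_len(nrow(ex)), function(j)
      region_rpkm(genomic_intervals(ex$chrom[j], ex$start[j], ex$end[j],
                                    x$strand), rna, nrow(rna))$n_reads,
      numeric(1)))
    r_mr <- n_ex * 1e9 / (sum(ex$end - ex$start) * nrow(rna))
    r_un / r_mr
  }, numeric(1))
  expect_equal(mean(ratios), cfg$xutr_isoform_fraction, tolerance = 0.15)
})
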