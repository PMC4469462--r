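test_that("density seeding recovers a planted peak and covers its window", {
  reads <- plant_reads(200, 500000, 502000, len = 29)
  seeds <- density_seeds(reads, c(chr1 = 1e6))
  expect_equal(nrow(seeds), 1L)
  expect_lte(seeds$start, 500000)
  expect_gte(seeds$end, 502000)
  expect_equal(seeds$n_reads, 200L)
})

test_that("uniform background reads at low rate yield no seeds", {
  set.seed(31)
  n_with_seeds <- 0L
  for (i in 1:20) {
    s <- floor(runif(100, 0, 1e6 - 29))
    reads <- aligned_reads("chr1", s, s + 29,
                           sample(c("+", "-"), 100, replace = TRUE))
    if (nrow(density_seeds(reads, c(chr1 = 1e6))) > 0) {
      n_with_seeds <- n_with_seeds + 1L
    }
  }
  expect_lte(n_with_seeds, 1L)   # zero seeds in >= 95% of simulations
})

test_that("raising the seeding threshold never increases the seed count", {
  set.seed(32)
  reads <- rbind(plant_reads(60, 100000, 101000),
                 plant_reads(25, 400000, 401000),
                 plant_reads(10, 700000, 700500))
  class(reads) <- c("aligned_reads", "data.frame")
  n15 <- nrow(density_seeds(reads, c(chr1 = 1e6), k_sd = 15))
  n30 <- nrow(density_seeds(reads, c(chr1 = 1e6), k_sd = 30))
  n5 <- nrow(density_seeds(reads, c(chr1 = 1e6), k_sd = 5))
  expect_lte(n30, n15)
  expect_lte(n15, n5)
})

test_that("empty read set produces an empty seed list", {
  reads <- aligned_reads(character(0), numeric(0), numeric(0), character(0))
  expect_equal(nrow(density_seeds(reads, c(chr1 = 1e6))), 0L)
})

test_that("a planted sense cluster over a 3' UTR is called with its gene", {
  genes <- mini_genes()
  reads <- plant_reads(100, 4000, 6000, strand = "+", len = 29)
  seeds <- density_seeds(reads, mini_chrom_lengths())
  cl <- call_utr3_clusters(seeds, reads, genes, mini_chrom_lengths())
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$source_gene, "gA")
  expect_equal(cl$strand, "+")
  expect_equal(cl$n_antisense, 0L)
  # boundaries coincide with read evidence inside the UTR
  expect_equal(cl$start, min(reads$start))
  expect_equal(cl$end, max(reads$end))
  expect_gte(cl$start, 3500)
})

test_that("a 50/50 strand mix fails the unidirectionality filter", {
  genes <- mini_genes()
  reads <- rbind(plant_reads(50, 4000, 6000, strand = "+"),
                 plant_reads(50, 4000, 6000, strand = "-", prefix = "m"))
  class(reads) <- c("aligned_reads", "data.frame")
  seeds <- density_seeds(reads, mini_chrom_lengths())
  expect_gte(nrow(seeds), 1L)
  cl <- call_utr3_clusters(seeds, reads, genes, mini_chrom_lengths())
  expect_equal(nrow(cl), 0L)
})

test_that("seeds with no 3' UTR overlap are not reported as UTR clusters", {
  genes <- mini_genes()
  reads <- plant_reads(100, 100000, 102000, strand = "+")
  seeds <- density_seeds(reads, mini_chrom_lengths())
  expect_gte(nrow(seeds), 1L)
  cl <- call_utr3_clusters(seeds, reads, genes, mini_chrom_lengths())
  expect_equal(nrow(cl), 0L)
})

test_that("the cluster 5' end is trimmed to the annotated 3' UTR start", {
  genes <- mini_genes()
  # reads start upstream of the UTR (inside the CDS exon at 3000)
  reads <- plant_reads(120, 3100, 6000, strand = "+", len = 29)
  seeds <- density_seeds(reads, mini_chrom_lengths())
  cl <- call_utr3_clusters(seeds, reads, genes, mini_chrom_lengths())
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 3500)   # gA utr3_start
})

test_that("beyond-UTR bases are measured 3' of the annotated UTR end", {
  genes <- mini_genes()
  # minus-strand gene gB: UTR [20000, 23000); extension runs 3' = leftward
  reads <- plant_reads(150, 18000, 22900, strand = "-", len = 29)
  seeds <- density_seeds(reads, mini_chrom_lengths())
  cl <- call_utr3_clusters(seeds, reads, genes, mini_chrom_lengths())
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$source_gene, "gB")
  expect_equal(cl$strand, "-")
  expect_equal(cl$beyond_utr_bases, 20000 - cl$start)
  expect_gt(cl$beyond_utr_bases, 0)
})

test_that("a 3'-end overlap with an adjacent gene is truncated unless contained", {
  genes <- mini_genes()
  # gA cluster reads running from the UTR into gC (12000-12800)
  reads <- plant_reads(200, 4000, 12400, strand = "+", len = 29)
  seeds <- density_seeds(reads, mini_chrom_lengths())
  cl <- call_utr3_clusters(seeds, reads, genes, mini_chrom_lengths())
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$source_gene, "gA")
  expect_lte(cl$end, 12000)      # truncated at gC's 5' end
  # with reads spanning past gC entirely, the cluster contains gC and is
  # retained untruncated
  reads2 <- plant_reads(300, 4000, 14000, strand = "+", len = 29)
  seeds2 <- density_seeds(reads2, mini_chrom_lengths())
  cl2 <- call_utr3_clusters(seeds2, reads2, genes, mini_chrom_lengths())
  expect_equal(nrow(cl2), 1L)
  expect_gt(cl2$end, 12800)
})

test_that("other-cluster calling merges across nearby repeats", {
  genes <- mini_genes()
  reads <- rbind(plant_reads(40, 100000, 100500, strand = "+"),
                 plant_reads(40, 100840, 101200, strand = "+", prefix = "q"))
  class(reads) <- c("aligned_reads", "data.frame")
  repeats <- genomic_intervals("chr1", 100540, 100800)  # 40 bp from both
  seeds <- density_seeds(reads, mini_chrom_lengths())
  cl <- call_other_clusters(seeds, reads, repeats, genes,
                            mini_chrom_lengths())
  expect_equal(nrow(cl), 1L)
  expect_lte(cl$start, 100000 + 29)
  expect_gte(cl$end, 101100)
  expect_equal(cl$kind, "intergenic")
})

test_that("a flagged cluster holding two opposite-strand blocks is split", {
  genes <- mini_genes()
  # a plus block whose cluster, after merging with a repeat, extends along
  # stray minus reads: growth exceeds 20% and the strand blocks separate
  stray <- aligned_reads("chr1", c(203700, 204200), c(203729, 204229), "-",
                         read_id = c("s1", "s2"))
  reads <- rbind(plant_reads(60, 200000, 201000, strand = "+"), stray)
  class(reads) <- c("aligned_reads", "data.frame")
  repeats <- genomic_intervals("chr1", 201800, 203400)
  seeds <- density_seeds(reads, mini_chrom_lengths())
  cl <- call_other_clusters(seeds, reads, repeats, genes,
                            mini_chrom_lengths())
  cl <- cl[cl$end > 199000 & cl$start < 205000, ]
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$strand, c("+", "-"))
  expect_lte(cl$end[cl$strand == "+"], 201800)
  expect_gte(cl$start[cl$strand == "-"], 203700)
  # without the stray reads there is no extension past the repeat and the
  # plus cluster stays intact
  cl2 <- call_other_clusters(seeds,
                             plant_reads(60, 200000, 201000, strand = "+"),
                             repeats, genes, mini_chrom_lengths())
  cl2 <- cl2[cl2$end > 199000 & cl2$start < 205000, ]
  expect_equal(nrow(cl2), 1L)
})

test_that("clusters with most reads in introns classify as intron", {
  genes <- mini_genes()
  # gA intron 1 spans [1400, 2000)
  reads <- plant_reads(50, 1410, 1970, strand = "+", len = 25)
  seeds <- density_seeds(reads, mini_chrom_lengths())
  no_repeats <- genomic_intervals(character(0), numeric(0), numeric(0))
  cl <- call_other_clusters(seeds, reads, no_repeats, genes,
                            mini_chrom_lengths())
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$kind, "intron")
})

test_that("emitted UTR clusters satisfy their filter chain post hoc", {
  cfg <- sim_config(seed = 19)
  ann <- simulate_annotation(cfg)
  reads <- simulate_testis_reads(cfg, ann)$strict
  seeds <- density_seeds(reads, ann$chrom_lengths)
  cl <- call_utr3_clusters(seeds, reads, ann$tracks$genes,
                           ann$chrom_lengths)
  expect_gt(nrow(cl), 0)
  utr3s <- pirclust:::utr3_intervals(ann$tracks$genes)
  for (i in seq_len(nrow(cl))) {
    rr <- reads[reads$chrom == cl$chrom[i] & reads$start < cl$end[i] &
                  reads$end > cl$start[i], ]
    n_sense <- sum(rr$strand == cl$strand[i])
    expect_gt(n_sense / nrow(rr), 0.6)
    ov <- pirclust:::overlap_vec(cl$chrom[i], cl$start[i], cl$end[i], utr3s)
    expect_true(any(ov > 0 & utr3s$strand == cl$strand[i]))
  }
  # pairwise non-overlap per chromosome
  for (ch in unique(cl$chrom)) {
    sub <- cl[cl$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
})
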