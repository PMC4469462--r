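one_cluster <- function(start = 0, end = 2000, id = "c1") {
  df <- data.frame(chrom = "chr1", start = start, end = end, strand = "+",
                   cluster_id = id, stringsAsFactors = FALSE)
  class(df) <- c("pirna_clusters", "data.frame")
  df
}

test_that("a 10-bp 5' overlap is exactly offset 9, aggregated per position pair", {
  cl <- one_cluster()
  reads <- aligned_reads("chr1", c(100, 81), c(129, 110), c("+", "-"),
                         read_id = c("p1", "m1"))
  sites <- find_pingpong_sites(cl, reads)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$plus_5p, 100)
  expect_equal(sites$minus_5p, 109)
  # offset 8 gives no site
  reads8 <- aligned_reads("chr1", c(100, 80), c(129, 109), c("+", "-"))
  expect_equal(nrow(find_pingpong_sites(cl, reads8)), 0L)
  # several reads sharing the same 5' ends aggregate into one site
  reads3 <- aligned_reads("chr1", c(100, 100, 81, 83), c(129, 131, 110, 110),
                          c("+", "+", "-", "-"),
                          read_id = c("p1", "p2", "m1", "m2"))
  s3 <- find_pingpong_sites(cl, reads3)
  expect_equal(nrow(s3), 1L)
  expect_equal(s3$n_plus_reads, 2L)
  expect_equal(s3$n_minus_reads, 2L)
})

test_that("site enumeration equals the brute-force all-pairs oracle", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(50:200, 1)
    p5 <- sample(0:500, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- sample(24:32, n, replace = TRUE)
    start <- ifelse(strand == "+", p5, p5 - len + 1)
    keep <- start >= 0
    reads <- aligned_reads("chr1", start[keep],
                           start[keep] + len[keep], strand[keep])
    cl <- one_cluster(0, 600)
    sites <- find_pingpong_sites(cl, reads)
    got <- sort(paste(sites$plus_5p, sites$minus_5p))
    expect_identical(got, oracle_pingpong(cl, reads))
  }
})

test_that("site detection is symmetric under strand relabelling", {
  set.seed(78)
  n <- 120
  p5 <- sample(0:500, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- sample(24:32, n, replace = TRUE)
  start <- ifelse(strand == "+", p5, pmax(p5 - len + 1, 0))
  reads <- aligned_reads("chr1", start, start + len, strand)
  cl <- one_cluster(0, 600)
  sites <- find_pingpong_sites(cl, reads)
  # mirror the genome: x -> 600 - 1 - x, strands flipped
  m_start <- 600 - reads$end
  m_end <- 600 - reads$start
  m_strand <- ifelse(reads$strand == "+", "-", "+")
  mirrored <- aligned_reads("chr1", m_start, m_end, m_strand)
  m_sites <- find_pingpong_sites(cl, mirrored)
  expect_equal(nrow(m_sites), nrow(sites))
  # each original (p, m) maps to (599 - m, 599 - p)
  expect_setequal(paste(m_sites$plus_5p, m_sites$minus_5p),
                  paste(599 - sites$minus_5p, 599 - sites$plus_5p))
})

test_that("composition summarises antisense 5' U, position-10 A and coverage", {
  cl <- one_cluster(0, 200)
  seqs <- c(p1 = strrep("G", 29), p2 = strrep("G", 29),
            m1 = paste0("T", strrep("G", 8), "A", strrep("G", 19)),
            m2 = paste0("C", strrep("G", 8), "A", strrep("G", 19)))
  reads <- aligned_reads("chr1", c(100, 102, 81, 83), c(129, 131, 110, 112),
                         c("+", "+", "-", "-"),
                         read_id = c("p1", "p2", "m1", "m2"),
                         sequence = unname(seqs))
  sites <- find_pingpong_sites(cl, reads)
  expect_equal(nrow(sites), 2L)
  comp <- pingpong_composition(sites, reads, cl)
  expect_equal(comp$frac_pos10_a, 1.0)
  expect_equal(comp$frac_5u, 0.5)
  # two sites at plus_5p 100 and 102: footprint union [100, 112) = 12 bp
  expect_equal(comp$per_cluster$site_coverage, 12 / 200)
  expect_equal(comp$per_cluster$n_sites, 2L)
  expect_error(pingpong_composition(sites[0, ], reads, cl), "no ping-pong")
})

test_that("antisense sources are classified by priority with 1-bp overlap", {
  utr3 <- one_cluster(1000, 2000, id = "u1")
  other <- data.frame(chrom = "chr1",
                      start = c(5000, 9000), end = c(6000, 9800),
                      strand = "+", cluster_id = c("o1", "o2"),
                      kind = c("intergenic", "intron"),
                      stringsAsFactors = FALSE)
  class(other) <- c("pirna_clusters", "data.frame")
  strict <- aligned_reads("chr1",
                          c(1500, 5500, 9100, 50000),
                          c(1529, 5529, 9129, 50029),
                          "-", read_id = c("a", "b", "c", "d"))
  calls <- annotate_antisense_sources(c("a", "b", "c", "d", "missing"),
                                      rep("u1", 5), strict, utr3, other)
  expect_equal(calls$source_class,
               c("same_utr3_cluster", "intergenic_cluster",
                 "other_pirna_cluster", "other", "other"))
  expect_equal(calls$missing_location, c(rep(FALSE, 4), TRUE))
  # every read appears exactly once
  expect_equal(anyDuplicated(calls$read_id), 0L)
})

test_that("planted ping-pong pairs are found and composition recovered", {
  cfg <- sim_config(seed = 41, pingpong_pair_count = 60,
                    pingpong_pos10a_prob = 0.43)
  ann <- simulate_annotation(cfg)
  reads <- simulate_testis_reads(cfg, ann)
  man_cl <- ann$manifest$clusters
  utr3 <- man_cl[man_cl$kind == "utr3", ]
  utr3$cluster_id <- utr3$cluster_name
  class(utr3) <- c("pirna_clusters", "data.frame")
  sites <- do.call(rbind, lapply(seq_len(nrow(utr3)), function(i)
    find_pingpong_sites(utr3[i, ], reads$relaxed)))
  # every planted pair position is recovered
  planted <- paste(ann$manifest$pingpong$plus_5p,
                   ann$manifest$pingpong$minus_5p)
  expect_true(all(planted %in% paste(sites$plus_5p, sites$minus_5p)))
  comp <- pingpong_composition(sites, reads$relaxed, utr3)
  # binomial 3-sigma around the configured position-10 A probability
  p <- cfg$pingpong_pos10a_prob
  tol <- 3 * sqrt(p * (1 - p) / comp$n_antisense_sequences)
  expect_lt(abs(comp$frac_pos10_a - p), tol + 0.02)
})
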