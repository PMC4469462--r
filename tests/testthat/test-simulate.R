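test_that("generators are byte-deterministic given the config", {
  cfg <- sim_config(seed = 5)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  r1 <- simulate_testis_reads(cfg, a1)
  r2 <- simulate_testis_reads(cfg, a2)
  expect_identical(r1, r2)
  expect_identical(simulate_somatic_pair(cfg, a1),
                   simulate_somatic_pair(cfg, a1))
  expect_identical(simulate_rnaseq(cfg, a1), simulate_rnaseq(cfg, a1))
})

test_that("annotation has the requested structure and a consistent manifest", {
  cfg <- sim_config(seed = 2, n_genes = 20)
  ann <- simulate_annotation(cfg)
  genes <- ann$tracks$genes
  expect_equal(length(unique(genes$gene_id)), 20L)
  # genes non-overlapping per chromosome
  sp <- pirclust:::gene_spans(genes)
  for (ch in unique(sp$chrom)) {
    s <- sp[sp$chrom == ch, ]
    s <- s[order(s$start), ]
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  man <- ann$manifest
  expect_equal(nrow(man$xutrs), cfg$n_xutr_genes)
  # hidden extensions abut the annotated UTR and stay inside the genome
  g <- genes[match(man$xutrs$gene_id, genes$gene_id), ]
  ok <- ifelse(g$strand == "+", man$xutrs$start == g$utr3_end,
               man$xutrs$end == g$utr3_start)
  expect_true(all(ok))
  expect_true(all(man$xutrs$start >= 0 &
                    man$xutrs$end <= cfg$chrom_length))
  # every xUTR gene carries a planted cluster flagged as xutr
  cl <- man$clusters
  expect_setequal(cl$source_gene[cl$xutr], man$xutrs$gene_id)
  # repeats do not touch gene spans
  expect_equal(sum(pirclust:::track_overlap(ann$tracks$repeats, sp)), 0)
})

test_that("zero-feature configs produce empty manifests", {
  cfg0 <- sim_config(seed = 3, n_xutr_genes = 0, pingpong_pair_count = 0,
                     n_intergenic_clusters = 0)
  ann <- simulate_annotation(cfg0)
  expect_equal(nrow(ann$manifest$xutrs), 0L)
  expect_equal(nrow(ann$manifest$pingpong), 0L)
  reads <- simulate_testis_reads(cfg0, ann)
  expect_identical(reads$strict, reads$relaxed)
  # no antisense reads inside sense-strand clusters beyond background
  cl <- ann$manifest$clusters
  n_anti <- sum(vapply(seq_len(nrow(cl)), function(i) {
    rr <- reads$strict
    sum(rr$chrom == cl$chrom[i] & rr$start < cl$end[i] &
          rr$end > cl$start[i] & rr$strand != cl$strand[i])
  }, numeric(1)))
  bg_total <- cfg0$background_rate * cfg0$n_chroms * cfg0$chrom_length / 1e6
  expect_lte(n_anti, bg_total)   # only background can be antisense
  # infeasible geometry errors out
  expect_error(simulate_annotation(sim_config(chrom_length = 5e4)),
               "infeasible")
})

test_that("testis reads hit depth, length mode and 5' U bias", {
  cfg <- sim_config(seed = 9)
  ann <- simulate_annotation(cfg)
  reads <- simulate_testis_reads(cfg, ann)$strict
  cl <- ann$manifest$clusters
  in_cluster <- vapply(seq_len(nrow(cl)), function(i)
    sum(reads$chrom == cl$chrom[i] & reads$start >= cl$start[i] &
          reads$end <= cl$end[i]), numeric(1))
  expect_true(all(in_cluster >= cfg$cluster_read_depth))
  lens <- reads$end - reads$start
  expect_equal(as.integer(names(which.max(table(lens)))), 29L)
  frac_u <- mean(substr(reads$sequence, 1, 1) == "T")
  tol <- 3 * sqrt(0.7 * 0.3 / nrow(reads))
  expect_lt(abs(frac_u - cfg$testis_5u_prob), tol + 0.02)
  # manifest consistency: every planted cluster holds >= 1 emitted read
  expect_true(all(in_cluster >= 1))
})

test_that("planted ping-pong partners overlap by exactly 10 bases", {
  cfg <- sim_config(seed = 13)
  ann <- simulate_annotation(cfg)
  reads <- simulate_testis_reads(cfg, ann)
  anti <- reads$relaxed[!reads$relaxed$read_id %in% reads$strict$read_id, ]
  expect_equal(nrow(anti), cfg$pingpong_pair_count)
  pp <- ann$manifest$pingpong
  sense <- reads$strict[grepl("^pps", reads$strict$read_id), ]
  for (i in seq_len(nrow(pp))) {
    s <- sense[i, ]
    a <- anti[i, ]
    s5 <- if (s$strand == "+") s$start else s$end - 1
    a5 <- if (a$strand == "+") a$start else a$end - 1
    expect_equal(abs(a5 - s5), 9)
    expect_true(s$strand != a$strand)
  }
  # relaxed is a strict superset containing the antisense partners
  expect_true(all(reads$strict$read_id %in% reads$relaxed$read_id))
  # strict re-alignments exist for every antisense partner here
  expect_setequal(reads$antisense_strict$read_id, anti$read_id)
})

test_that("somatic pair honours its construction guarantees", {
  cfg <- sim_config(seed = 17)
  ann <- simulate_annotation(cfg)
  pair <- simulate_somatic_pair(cfg, ann)
  man <- ann$manifest$somatic
  for (i in seq_len(nrow(man))) {
    cl <- man[i, ]
    n_ko <- sum(pair$ko$chrom == cl$chrom & pair$ko$start < cl$end &
                  pair$ko$end > cl$start)
    if (cl$label == "dependent") expect_equal(n_ko, 0L)
    else expect_gte(n_ko, 1L)
  }
  lens <- pair$wt$end - pair$wt$start
  expect_equal(as.integer(names(which.max(table(lens)))), 23L)
  # elevated 5' A
  frac_a <- mean(substr(pair$wt$sequence, 1, 1) == "A")
  tol <- 3 * sqrt(0.4 * 0.6 / nrow(pair$wt))
  expect_lt(abs(frac_a - cfg$somatic_5a_prob), tol + 0.02)
})

test_that("RNA-seq read totals and hidden-region sampling behave", {
  cfg <- sim_config(seed = 29)
  ann <- simulate_annotation(cfg)
  rna <- simulate_rnaseq(cfg, ann)
  expect_lt(abs(nrow(rna) - cfg$rnaseq_depth),
            5 * sqrt(cfg$rnaseq_depth))
  # zero isoform fraction leaves hidden regions empty
  cfg0 <- sim_config(seed = 29, xutr_isoform_fraction = 0)
  ann0 <- simulate_annotation(cfg0)
  rna0 <- simulate_rnaseq(cfg0, ann0)
  x <- ann0$manifest$xutrs
  n_hidden <- sum(vapply(seq_len(nrow(x)), function(i)
    sum(rna0$chrom == x$chrom[i] & rna0$start < x$end[i] &
          rna0$end > x$start[i]), numeric(1)))
  expect_equal(n_hidden, 0)
})
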