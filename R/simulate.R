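# Synthetic-data generator: toy genomes, gene annotations with hidden
# extended 3' UTRs, testis and somatic small-RNA read sets, RNA-seq reads,
# and WT/KO library pairs, all tied to a ground-truth manifest.

#' Simulation configuration
#'
#' Defaults emulate the empirical structure of adult-testis piRNA data
#' (29-nt length mode, 70% 5' U, clusters over 3' UTRs and intergenic
#' space, planted 10-bp ping-pong partners) and of somatic small-RNA data
#' (23-nt mode, elevated 5' A and U, MIWI2-dependent and -independent
#' clusters in a WT/KO pair).
#'
#' @param seed RNG seed; every generator is deterministic given the
#'   config.
#' @param n_chroms,chrom_length Genome geometry.
#' @param n_genes Number of annotated protein-coding genes.
#' @param n_xutr_genes Genes carrying a hidden extended-UTR isoform absent
#'   from the annotation but recorded in the manifest.
#' @param xutr_length_range Hidden extension length range (bp).
#' @param n_cluster_genes Genes receiving a planted testis 3' UTR cluster
#'   (xUTR genes are always among them).
#' @param n_intergenic_clusters Planted intergenic clusters.
#' @param intergenic_cluster_length Length range of intergenic clusters.
#' @param testis_read_length_mode,testis_length_range Testis read length
#'   mode (29 nt) and truncation range.
#' @param somatic_read_length_mode,somatic_length_range Somatic read
#'   length mode (23 nt) and truncation range.
#' @param testis_5u_prob Probability of a 5' U on testis reads (0.7).
#' @param somatic_5a_prob,somatic_5u_prob 5'-base probabilities of somatic
#'   reads (elevated A and U).
#' @param cluster_read_depth Reads planted per cluster.
#' @param background_rate Uniform background reads per Mb (testis).
#' @param pingpong_pair_count Planted sense/antisense pairs with exactly
#'   10-bp 5' overlap.
#' @param pingpong_5u_prob,pingpong_pos10a_prob 5'-U and position-10-A
#'   probabilities of the antisense partners.
#' @param antisense_same_prob Probability that an antisense partner's
#'   strict unique placement is its discovery site; otherwise it falls in
#'   a planted intergenic cluster.
#' @param n_dependent_clusters,n_independent_clusters Somatic planting.
#' @param dependent_density_range,independent_density_range Planted WT
#'   read densities (reads per kb of UTR); the dependent range sits above
#'   the independent one so dependent clusters exceed the bottom quartile.
#' @param ko_fraction KO read count of an independent cluster as a
#'   fraction of its WT count (at least 1 read).
#' @param somatic_background_rate Background reads per Mb in the somatic
#'   libraries, placed well clear of genes.
#' @param rnaseq_depth Expected RNA-seq read count.
#' @param rnaseq_read_length RNA-seq read length.
#' @param xutr_isoform_fraction Abundance of the hidden extended-UTR
#'   isoform relative to the annotated mRNA.
#' @param n_repeats,repeat_length_range Repeat track geometry.
#' @param copy_geom_p Copy counts are `1 + rgeom(copy_geom_p)`; most
#'   collapsed sequences are observed once.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 1e6,
                       n_genes = 20L, n_xutr_genes = 8L,
                       xutr_length_range = c(1500, 3000),
                       n_cluster_genes = 10L,
                       n_intergenic_clusters = 4L,
                       intergenic_cluster_length = c(1500, 3000),
                       testis_read_length_mode = 29L,
                       testis_length_range = c(24L, 32L),
                       somatic_read_length_mode = 23L,
                       somatic_length_range = c(18L, 28L),
                       testis_5u_prob = 0.7,
                       somatic_5a_prob = 0.4, somatic_5u_prob = 0.3,
                       cluster_read_depth = 150L,
                       background_rate = 50,
                       pingpong_pair_count = 20L,
                       pingpong_5u_prob = 0.61,
                       pingpong_pos10a_prob = 0.43,
                       antisense_same_prob = 0.3,
                       n_dependent_clusters = 6L,
                       n_independent_clusters = 12L,
                       dependent_density_range = c(50, 80),
                       independent_density_range = c(5, 30),
                       ko_fraction = 0.5,
                       somatic_background_rate = 20,
                       rnaseq_depth = 20000L,
                       rnaseq_read_length = 50L,
                       xutr_isoform_fraction = 0.25,
                       n_repeats = 30L,
                       repeat_length_range = c(200, 800),
                       copy_geom_p = 0.7) {
  cfg <- as.list(environment())
  probs <- c(testis_5u_prob, somatic_5a_prob, somatic_5u_prob,
             pingpong_5u_prob, pingpong_pos10a_prob, antisense_same_prob,
             xutr_isoform_fraction, copy_geom_p)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (somatic_5a_prob + somatic_5u_prob > 1)
    stop("somatic 5'-base probabilities exceed 1")
  if (chrom_length <= 0 || any(xutr_length_range <= 0))
    stop("lengths must be positive")
  if (n_xutr_genes > n_cluster_genes || n_cluster_genes > n_genes)
    stop("need n_xutr_genes <= n_cluster_genes <= n_genes")
  class(cfg) <- "sim_config"
  cfg
}

# Discretised, truncated skew-normal length distribution: location one
# base above the mode, scale 2, left skew (alpha = -3) so the tail runs
# toward smaller sizes; the discrete argmax lands on `mode`.
length_probs <- function(mode, range) {
  lens <- seq(range[1], range[2])
  z <- (lens - (mode + 1)) / 2
  w <- 2 * dnorm(z) * pnorm(-3 * z)
  w / sum(w)
}

draw_lengths <- function(n, mode, range) {
  lens <- seq(range[1], range[2])
  sample(lens, n, replace = TRUE, prob = length_probs(mode, range))
}

# Random read sequences with a categorical 5'-base distribution;
# remaining positions uniform over ACGT.
draw_sequences <- function(lens, base1_probs) {
  bases <- c("A", "C", "G", "T")
  vapply(lens, function(L) {
    s <- sample(bases, L, replace = TRUE)
    s[1] <- sample(names(base1_probs), 1L, prob = base1_probs)
    paste(s, collapse = "")
  }, character(1))
}

draw_copies <- function(n, p) 1L + stats::rgeom(n, p)

# Sample an interval of length `len` on `chrom` avoiding `blocked`
# intervals (with `pad` bp of clearance); bounded retries.
place_avoiding <- function(chrom, chrom_len, len, blocked, pad,
                           max_tries = 1000L) {
  b <- blocked[blocked$chrom == chrom, , drop = FALSE]
  for (i in seq_len(max_tries)) {
    s <- floor(runif(1, 0, chrom_len - len))
    if (!any(b$start - pad < s + len & b$end + pad > s))
      return(c(s, s + len))
  }
  stop("simulation geometry infeasible: cannot place a ", len,
       "-bp feature on ", chrom)
}

#' Simulate a toy genome annotation with ground truth
#'
#' Places non-overlapping protein-coding genes (three exons, CDS, 3' UTR)
#' on each chromosome, hides an extended-UTR region downstream of a subset
#' of genes (present only in the manifest, not in the annotation), plants
#' testis 3' UTR and intergenic cluster locations, ping-pong site
#' positions, somatic cluster labels with WT densities, per-gene RNA-seq
#' abundances, and scatters repeat elements in intergenic space.
#'
#' @param config A [sim_config()].
#' @return List with `tracks` (an [annotation_tracks()] set), `manifest`
#'   (planted features and labels), `chrom_lengths`, and the `config`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  chrom_lengths <- setNames(rep(config$chrom_length, config$n_chroms),
                            chroms)
  per_chrom <- diff(floor(seq(0, config$n_genes,
                              length.out = config$n_chroms + 1)))
  xmax <- max(config$xutr_length_range)
  gene_rows <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    ng <- per_chrom[ci]
    if (ng == 0L) next
    slot <- floor(config$chrom_length / ng)
    if (slot < 4200 + 4000 + xmax + 4000)
      stop("simulation geometry infeasible: genome too small for ",
           config$n_genes, " genes")
    for (k in seq_len(ng)) {
      gi <- gi + 1L
      slot_start <- (k - 1L) * slot
      strand <- sample(c("+", "-"), 1L)
      u <- round(runif(1, 1500, 4000))
      if (strand == "+") {
        s <- slot_start + 2000
        exon_s <- c(s, s + 1000, s + 2000)
        exon_e <- c(s + 400, s + 1400, s + 2200 + u)
        cds <- c(s + 100, s + 2200)
        utr3 <- c(s + 2200, s + 2200 + u)
        tx <- c(s, s + 2200 + u)
      } else {
        t0 <- slot_start + slot - 2000 - (2200 + u)
        exon_s <- c(t0, t0 + u + 800, t0 + u + 1800)
        exon_e <- c(t0 + u + 200, t0 + u + 1200, t0 + u + 2200)
        cds <- c(t0 + u, t0 + u + 2100)
        utr3 <- c(t0, t0 + u)
        tx <- c(t0, t0 + u + 2200)
      }
      gene_rows[[gi]] <- data.frame(
        gene_id = sprintf("g%03d", gi), tx_id = sprintf("t%03d", gi),
        chrom = chroms[ci], strand = strand,
        tx_start = tx[1], tx_end = tx[2],
        cds_start = cds[1], cds_end = cds[2],
        utr3_start = utr3[1], utr3_end = utr3[2],
        exon_starts = paste(exon_s, collapse = ","),
        exon_ends = paste(exon_e, collapse = ","),
        coding = TRUE, stringsAsFactors = FALSE)
    }
  }
  gdf <- do.call(rbind, gene_rows)
  genes <- gene_models(gdf$gene_id, gdf$tx_id, gdf$chrom, gdf$strand,
                       gdf$tx_start, gdf$tx_end, gdf$cds_start, gdf$cds_end,
                       gdf$utr3_start, gdf$utr3_end, gdf$exon_starts,
                       gdf$exon_ends, gdf$coding)

  cluster_genes <- sort(sample(genes$gene_id, config$n_cluster_genes))
  xutr_genes <- sort(sample(cluster_genes, config$n_xutr_genes))

  # hidden extended-UTR regions, downstream of the annotated UTR end
  xutrs <- NULL
  if (length(xutr_genes)) {
    xr <- genes[match(xutr_genes, genes$gene_id), ]
    xlen <- round(runif(nrow(xr), config$xutr_length_range[1],
                        config$xutr_length_range[2]))
    xs <- ifelse(xr$strand == "+", xr$utr3_end, xr$utr3_start - xlen)
    xutrs <- data.frame(gene_id = xr$gene_id, chrom = xr$chrom,
                        start = xs, end = xs + xlen, strand = xr$strand,
                        stringsAsFactors = FALSE)
  } else {
    xutrs <- data.frame(gene_id = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        strand = character(0))
  }

  # planted testis 3' UTR clusters: the annotated UTR, extended over the
  # hidden region for xUTR genes
  cg <- genes[match(cluster_genes, genes$gene_id), ]
  cl_start <- cg$utr3_start
  cl_end <- cg$utr3_end
  xm <- match(cg$gene_id, xutrs$gene_id)
  has_x <- !is.na(xm)
  cl_start[has_x & cg$strand == "-"] <- xutrs$start[xm[has_x & cg$strand == "-"]]
  cl_end[has_x & cg$strand == "+"] <- xutrs$end[xm[has_x & cg$strand == "+"]]
  beyond <- ifelse(has_x,
                   ifelse(cg$strand == "+", cl_end - cg$utr3_end,
                          cg$utr3_start - cl_start), 0)
  utr3_cl <- data.frame(cluster_name = sprintf("planted_utr3_%02d",
                                               seq_len(nrow(cg))),
                        chrom = cg$chrom, start = cl_start, end = cl_end,
                        strand = cg$strand, source_gene = cg$gene_id,
                        kind = "utr3", xutr = has_x,
                        beyond_fraction = beyond / (cl_end - cl_start),
                        stringsAsFactors = FALSE)

  spans <- gene_spans(genes)
  blocked <- rbind(spans[, c("chrom", "start", "end")],
                   xutrs[, c("chrom", "start", "end")])
  interg_cl <- NULL
  if (config$n_intergenic_clusters > 0L) {
    rows <- list()
    for (i in seq_len(config$n_intergenic_clusters)) {
      chrom <- chroms[1L + (i - 1L) %% config$n_chroms]
      len <- round(runif(1, config$intergenic_cluster_length[1],
                         config$intergenic_cluster_length[2]))
      iv <- place_avoiding(chrom, chrom_lengths[[chrom]], len, blocked,
                           pad = 1500)
      rows[[i]] <- data.frame(cluster_name = sprintf("planted_interg_%02d", i),
                              chrom = chrom, start = iv[1], end = iv[2],
                              strand = sample(c("+", "-"), 1L),
                              source_gene = NA_character_,
                              kind = "intergenic", xutr = FALSE,
                              beyond_fraction = 0, stringsAsFactors = FALSE)
      blocked <- rbind(blocked, rows[[i]][, c("chrom", "start", "end")])
    }
    interg_cl <- do.call(rbind, rows)
  }
  clusters <- rbind(utr3_cl, interg_cl)

  # repeats in the remaining intergenic space, clear of planted features
  rep_rows <- list()
  for (i in seq_len(config$n_repeats)) {
    chrom <- chroms[1L + (i - 1L) %% config$n_chroms]
    len <- round(runif(1, config$repeat_length_range[1],
                       config$repeat_length_range[2]))
    iv <- place_avoiding(chrom, chrom_lengths[[chrom]], len, blocked,
                         pad = 600)
    rep_rows[[i]] <- data.frame(chrom = chrom, start = iv[1], end = iv[2],
                                strand = "*", stringsAsFactors = FALSE)
    blocked <- rbind(blocked, rep_rows[[i]][, c("chrom", "start", "end")])
  }
  repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               strand = character(0))

  # ping-pong site plan: positions inside planted 3' UTR clusters where
  # both partners (max read length 32) fit
  pp <- NULL
  if (config$pingpong_pair_count > 0L && nrow(utr3_cl) > 0L) {
    idx <- 1L + (seq_len(config$pingpong_pair_count) - 1L) %% nrow(utr3_cl)
    p <- vapply(idx, function(j) {
      floor(runif(1, utr3_cl$start[j] + 22, utr3_cl$end[j] - 32))
    }, numeric(1))
    pp <- data.frame(cluster_name = utr3_cl$cluster_name[idx],
                     chrom = utr3_cl$chrom[idx], plus_5p = p,
                     minus_5p = p + 9,
                     cluster_strand = utr3_cl$strand[idx],
                     stringsAsFactors = FALSE)
  } else {
    pp <- data.frame(cluster_name = character(0), chrom = character(0),
                     plus_5p = numeric(0), minus_5p = numeric(0),
                     cluster_strand = character(0))
  }

  # somatic planting: labels and WT densities on gene 3' UTRs
  n_som <- config$n_dependent_clusters + config$n_independent_clusters
  if (n_som > nrow(genes))
    stop("simulation geometry infeasible: fewer genes than somatic clusters")
  som_genes <- sample(genes$gene_id, n_som)
  sg <- genes[match(som_genes, genes$gene_id), ]
  label <- rep(c("dependent", "independent"),
               c(config$n_dependent_clusters, config$n_independent_clusters))
  dens <- c(runif(config$n_dependent_clusters,
                  config$dependent_density_range[1],
                  config$dependent_density_range[2]),
            runif(config$n_independent_clusters,
                  config$independent_density_range[1],
                  config$independent_density_range[2]))
  somatic <- data.frame(gene_id = sg$gene_id, chrom = sg$chrom,
                        start = sg$utr3_start, end = sg$utr3_end,
                        strand = sg$strand, label = label,
                        planted_density = dens, stringsAsFactors = FALSE)

  rnaseq <- data.frame(gene_id = genes$gene_id,
                       weight = stats::rlnorm(nrow(genes), 0, 0.5),
                       stringsAsFactors = FALSE)

  manifest <- list(clusters = clusters, xutrs = xutrs, pingpong = pp,
                   somatic = somatic, rnaseq = rnaseq)
  class(manifest) <- "sim_manifest"
  list(tracks = annotation_tracks(genes, repeats), manifest = manifest,
       chrom_lengths = chrom_lengths, config = config)
}

# Draw reads inside one interval: 5' positions uniform, reads fully
# contained; returns coordinate/strand/length frame.
cluster_read_coords <- function(n, chrom, lo, hi, strand, lens) {
  lens <- pmin(lens, hi - lo)
  if (strand == "+") {
    s <- floor(runif(n, lo, hi - lens + 1))
    data.frame(chrom = chrom, start = s, end = s + lens, strand = strand,
               stringsAsFactors = FALSE)
  } else {
    p5 <- floor(runif(n, lo + lens - 1, hi))
    data.frame(chrom = chrom, start = p5 - lens + 1, end = p5 + 1,
               strand = strand, stringsAsFactors = FALSE)
  }
}

#' Simulate testis small-RNA reads
#'
#' Draws reads inside every planted cluster at the configured depth plus a
#' uniform genomic background, with the testis length distribution (mode
#' 29 nt) and 5' U bias, then adds the planned ping-pong partner pairs:
#' the sense partner joins the strict-mode set, the antisense partner only
#' the relaxed-mode set, with its 5' end overlapping the sense partner by
#' exactly 10 bases and an elevated A at position 10.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()] for the same
#'   config.
#' @return List with `strict` and `relaxed` [aligned_reads()] (the
#'   relaxed set is a superset of the strict set) and `antisense_strict`,
#'   the strict unique re-alignments of the antisense partners (reads
#'   without one are absent).
#' @export
simulate_testis_reads <- function(config, annotation) {
  set.seed(config$seed + 1L)
  man <- annotation$manifest
  t5 <- config$testis_5u_prob
  base1 <- c(A = (1 - t5) / 3, C = (1 - t5) / 3, G = (1 - t5) / 3, T = t5)
  coords <- list()
  for (i in seq_len(nrow(man$clusters))) {
    cl <- man$clusters[i, ]
    lens <- draw_lengths(config$cluster_read_depth,
                         config$testis_read_length_mode,
                         config$testis_length_range)
    coords[[length(coords) + 1L]] <-
      cluster_read_coords(config$cluster_read_depth, cl$chrom, cl$start,
                          cl$end, cl$strand, lens)
  }
  total_mb <- config$n_chroms * config$chrom_length / 1e6
  n_bg <- rpois(1, config$background_rate * total_mb)
  if (n_bg > 0L) {
    lens <- draw_lengths(n_bg, config$testis_read_length_mode,
                         config$testis_length_range)
    chrom <- sprintf("chr%d", sample.int(config$n_chroms, n_bg,
                                         replace = TRUE))
    s <- floor(runif(n_bg, 0, config$chrom_length - lens))
    coords[[length(coords) + 1L]] <-
      data.frame(chrom = chrom, start = s, end = s + lens,
                 strand = sample(c("+", "-"), n_bg, replace = TRUE),
                 stringsAsFactors = FALSE)
  }
  co <- do.call(rbind, coords)
  lens <- co$end - co$start
  strict <- aligned_reads(co$chrom, co$start, co$end, co$strand,
                          read_id = sprintf("t%06d", seq_len(nrow(co))),
                          sequence = draw_sequences(lens, base1),
                          copies = draw_copies(nrow(co),
                                               config$copy_geom_p))
  # ping-pong pairs
  relaxed_extra <- NULL
  antisense_strict <- NULL
  pp <- man$pingpong
  if (nrow(pp) > 0L) {
    n <- nrow(pp)
    ls <- draw_lengths(n, config$testis_read_length_mode,
                       config$testis_length_range)
    la <- draw_lengths(n, config$testis_read_length_mode,
                       config$testis_length_range)
    plus_start <- pp$plus_5p
    minus_end <- pp$minus_5p + 1
    # partner on the plus strand spans [p, p + L); on the minus strand
    # [m - L + 1, m + 1). sense = cluster strand.
    sense_plus <- pp$cluster_strand == "+"
    sense_len <- ls
    anti_len <- la
    sense <- data.frame(
      chrom = pp$chrom,
      start = ifelse(sense_plus, plus_start, minus_end - sense_len),
      end = ifelse(sense_plus, plus_start + sense_len, minus_end),
      strand = pp$cluster_strand, stringsAsFactors = FALSE)
    anti_strand <- ifelse(sense_plus, "-", "+")
    anti <- data.frame(
      chrom = pp$chrom,
      start = ifelse(sense_plus, minus_end - anti_len, plus_start),
      end = ifelse(sense_plus, minus_end, plus_start + anti_len),
      strand = anti_strand, stringsAsFactors = FALSE)
    sense_seq <- draw_sequences(sense_len, base1)
    p5a <- config$pingpong_5u_prob
    anti_base1 <- c(A = (1 - p5a) / 3, C = (1 - p5a) / 3, G = (1 - p5a) / 3,
                    T = p5a)
    anti_seq <- draw_sequences(anti_len, anti_base1)
    has_a10 <- runif(n) < config$pingpong_pos10a_prob
    substr(anti_seq[has_a10], 10, 10) <- "A"
    not_a <- which(!has_a10 & substr(anti_seq, 10, 10) == "A")
    for (j in not_a) substr(anti_seq[j], 10, 10) <-
      sample(c("C", "G", "T"), 1L)
    sense_ids <- sprintf("pps%04d", seq_len(n))
    anti_ids <- sprintf("ppa%04d", seq_len(n))
    sense_reads <- aligned_reads(sense$chrom, sense$start, sense$end,
                                 sense$strand, sense_ids,
                                 sequence = sense_seq,
                                 copies = draw_copies(n, config$copy_geom_p))
    anti_reads <- aligned_reads(anti$chrom, anti$start, anti$end,
                                anti$strand, anti_ids,
                                sequence = anti_seq,
                                copies = draw_copies(n, config$copy_geom_p),
                                mismatches = sample(0:2, n, replace = TRUE),
                                n_alignments = sample(1:25, n,
                                                      replace = TRUE))
    strict <- rbind(strict, sense_reads)
    class(strict) <- c("aligned_reads", "data.frame")
    relaxed_extra <- anti_reads
    # strict unique re-alignment of the antisense partners
    same <- runif(n) < config$antisense_same_prob
    interg <- man$clusters[man$clusters$kind == "intergenic", , drop = FALSE]
    if (nrow(interg) == 0L) same[] <- TRUE
    dest <- anti
    for (j in which(!same)) {
      tgt <- interg[1L + (j - 1L) %% nrow(interg), ]
      L <- anti_len[j]
      s <- floor(runif(1, tgt$start, tgt$end - L))
      dest$chrom[j] <- tgt$chrom
      dest$start[j] <- s
      dest$end[j] <- s + L
      dest$strand[j] <- sample(c("+", "-"), 1L)
    }
    antisense_strict <- aligned_reads(dest$chrom, dest$start, dest$end,
                                      dest$strand, anti_ids,
                                      sequence = anti_seq)
  }
  relaxed <- if (is.null(relaxed_extra)) strict else {
    r <- rbind(strict, relaxed_extra)
    class(r) <- c("aligned_reads", "data.frame")
    r
  }
  list(strict = strict, relaxed = relaxed,
       antisense_strict = antisense_strict)
}

#' Simulate a somatic WT/KO small-RNA library pair
#'
#' WT reads populate every planted somatic cluster (sense strand of the
#' host gene's 3' UTR) at the planted density, with the somatic length
#' distribution (mode 23 nt) and elevated 5' A/U; knockout reads populate
#' only MIWI2-independent clusters. Background reads for both libraries
#' fall in intergenic space well clear of genes, so dependent clusters
#' contain no KO reads by construction.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @return List with `wt` and `ko` [aligned_reads()].
#' @export
simulate_somatic_pair <- function(config, annotation) {
  set.seed(config$seed + 2L)
  som <- annotation$manifest$somatic
  a <- config$somatic_5a_prob
  u <- config$somatic_5u_prob
  base1 <- c(A = a, C = (1 - a - u) / 2, G = (1 - a - u) / 2, T = u)
  make_lib <- function(rows, counts, prefix) {
    coords <- list()
    for (i in seq_len(nrow(rows))) {
      n <- counts[i]
      if (n == 0L) next
      lens <- draw_lengths(n, config$somatic_read_length_mode,
                           config$somatic_length_range)
      coords[[length(coords) + 1L]] <-
        cluster_read_coords(n, rows$chrom[i], rows$start[i], rows$end[i],
                            rows$strand[i], lens)
    }
    # intergenic background, >= 5 kb clear of any gene span
    spans <- gene_spans(annotation$tracks$genes)
    total_mb <- config$n_chroms * config$chrom_length / 1e6
    n_bg <- rpois(1, config$somatic_background_rate * total_mb)
    if (n_bg > 0L) {
      lens <- draw_lengths(n_bg, config$somatic_read_length_mode,
                           config$somatic_length_range)
      for (j in seq_len(n_bg)) {
        chrom <- sprintf("chr%d", sample.int(config$n_chroms, 1L))
        iv <- place_avoiding(chrom, annotation$chrom_lengths[[chrom]],
                             lens[j], spans, pad = 5000)
        coords[[length(coords) + 1L]] <-
          data.frame(chrom = chrom, start = iv[1], end = iv[2],
                     strand = sample(c("+", "-"), 1L),
                     stringsAsFactors = FALSE)
      }
    }
    if (length(coords) == 0L)
      return(aligned_reads(character(0), numeric(0), numeric(0),
                           character(0)))
    co <- do.call(rbind, coords)
    aligned_reads(co$chrom, co$start, co$end, co$strand,
                  sprintf("%s%06d", prefix, seq_len(nrow(co))),
                  sequence = draw_sequences(co$end - co$start, base1),
                  copies = draw_copies(nrow(co), config$copy_geom_p))
  }
  len_kb <- (som$end - som$start) / 1000
  wt_counts <- pmax(3L, round(som$planted_density * len_kb))
  ko_counts <- ifelse(som$label == "independent",
                      pmax(1L, round(wt_counts * config$ko_fraction)), 0L)
  list(wt = make_lib(som, wt_counts, "w"),
       ko = make_lib(som, ko_counts, "k"))
}

#' Simulate RNA-seq reads over annotated genes and hidden xUTRs
#'
#' Reads are sampled over each gene's annotated exons in proportion to a
#' per-gene abundance from the manifest, and over the hidden extended-UTR
#' regions at `xutr_isoform_fraction` of the host gene's abundance, on the
#' sense strand of the host gene. The total read count is Poisson around
#' `rnaseq_depth`.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @return An [aligned_reads()] table (no sequences).
#' @export
simulate_rnaseq <- function(config, annotation) {
  set.seed(config$seed + 3L)
  man <- annotation$manifest
  genes <- annotation$tracks$genes
  ex <- exon_intervals(genes)
  w <- man$rnaseq$weight[match(ex$gene_id, man$rnaseq$gene_id)]
  regions <- data.frame(chrom = ex$chrom, start = ex$start, end = ex$end,
                        strand = ex$strand,
                        wt = w * (ex$end - ex$start),
                        stringsAsFactors = FALSE)
  if (nrow(man$xutrs) > 0L && config$xutr_isoform_fraction > 0) {
    xw <- man$rnaseq$weight[match(man$xutrs$gene_id, man$rnaseq$gene_id)]
    regions <- rbind(regions, data.frame(
      chrom = man$xutrs$chrom, start = man$xutrs$start,
      end = man$xutrs$end, strand = man$xutrs$strand,
      wt = config$xutr_isoform_fraction * xw *
        (man$xutrs$end - man$xutrs$start), stringsAsFactors = FALSE))
  }
  n <- rpois(1, config$rnaseq_depth)
  pick <- sample.int(nrow(regions), n, replace = TRUE,
                     prob = regions$wt)
  L <- config$rnaseq_read_length
  reg <- regions[pick, , drop = FALSE]
  rl <- pmin(L, reg$end - reg$start)
  s <- floor(runif(n, reg$start, reg$end - rl + 1))
  aligned_reads(reg$chrom, s, s + rl, reg$strand,
                sprintf("rna%06d", seq_len(n)))
}
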