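# End-to-end workflows wiring the stages together, file-based so a run
# can be driven from the command line, plus manifest-recovery scoring.

#' Jaccard index of two intervals
#'
#' @param a,b One-row interval data frames on the same chromosome.
#' @return `|a n b| / |a u b|`, 0 for different chromosomes.
#' @export
interval_jaccard <- function(a, b) {
  ov <- overlap_length(a, b)
  if (ov == 0) return(0)
  un <- (a$end - a$start) + (b$end - b$start) - ov
  ov / un
}

#' Score called clusters against a ground-truth manifest
#'
#' Matches each planted cluster to the called cluster with the highest
#' boundary Jaccard index and reports, per planted cluster, the match,
#' its Jaccard, and whether the source gene was assigned correctly.
#'
#' @param clusters A `pirna_clusters` table.
#' @param truth Manifest cluster table (columns `cluster_name`, `chrom`,
#'   `start`, `end`, `strand`, `source_gene`).
#' @param min_jaccard Jaccard at or above which a planted cluster counts
#'   as recovered, default 0.8.
#' @return List with per-cluster data frame `detail` and scalars
#'   `recall` and `gene_accuracy` (over recovered clusters).
#' @export
cluster_recovery <- function(clusters, truth, min_jaccard = 0.8) {
  n <- nrow(truth)
  best_id <- rep(NA_character_, n)
  best_j <- numeric(n)
  gene_ok <- rep(NA, n)
  for (i in seq_len(n)) {
    tr <- truth[i, ]
    if (nrow(clusters) == 0L) next
    j <- vapply(seq_len(nrow(clusters)), function(k)
      interval_jaccard(tr, clusters[k, ]), numeric(1))
    k <- which.max(j)
    best_j[i] <- j[k]
    best_id[i] <- clusters$cluster_id[k]
    if (!is.null(tr$source_gene) && !is.na(tr$source_gene))
      gene_ok[i] <- identical(clusters$source_gene[k], tr$source_gene)
  }
  recovered <- best_j >= min_jaccard
  detail <- data.frame(cluster_name = truth$cluster_name,
                       best_call = best_id, jaccard = best_j,
                       recovered = recovered, gene_correct = gene_ok,
                       stringsAsFactors = FALSE)
  list(detail = detail,
       recall = mean(recovered),
       gene_accuracy = if (any(recovered & !is.na(gene_ok)))
         mean(gene_ok[recovered & !is.na(gene_ok)]) else NA_real_)
}

default_params <- function() {
  list(feature_length = 1000, k_sd = 15, grid_step = 25,
       ext_step_utr3 = 1000, ext_min_reads_utr3 = 2,
       ext_step_other = 500, ext_min_reads_other = 1,
       repeat_gap = 50, growth_flag_frac = 0.2,
       strand_frac = 0.6, min_beyond_frac = 0.30,
       expression_q = 0.95,
       somatic_min_reads = 3, somatic_min_density = 7.5,
       somatic_ratio = 2.0, somatic_ext_step = 2000)
}

log_line <- function(con, ...) {
  msg <- sprintf(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run an end-to-end workflow
#'
#' Four file-based workflows over a run directory:
#' `"simulate"` writes a synthetic genome annotation, testis/somatic/
#' RNA-seq read sets and the ground-truth manifest; `"testis"` runs
#' annotation classification, seeding, both cluster callers, xUTR
#' selection/quantification and ping-pong detection on those files;
#' `"somatic"` calls somatic clusters on the WT library and classifies
#' MIWI2 dependence against the KO library; `"stats"` writes composition
#' summaries. When a manifest is present, the analysis workflows also
#' write recovery reports. All parameters default to the standard
#' settings of the method and are echoed into `run_metadata.tsv`.
#'
#' @param workflow One of `"simulate"`, `"testis"`, `"somatic"`,
#'   `"stats"`.
#' @param dir Run directory (created if needed); inputs are read from and
#'   outputs written to it.
#' @param config A [sim_config()] (used by `"simulate"`, and for the seed
#'   of the shuffled background in `"testis"`).
#' @param params Named list overriding entries of the default parameter
#'   set (feature_length, k_sd, strand_frac, ...).
#' @return Invisibly, a named list of the workflow's main result objects.
#' @export
run_pipeline <- function(workflow = c("simulate", "testis", "somatic",
                                      "stats"),
                         dir, config = sim_config(), params = list()) {
  workflow <- match.arg(workflow)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- utils::modifyList(default_params(), params)
  meta <- data.frame(key = c("workflow", "seed", names(p)),
                     value = c(workflow, config$seed,
                               vapply(p, format, character(1))))
  write_tsv(meta, file.path(dir, "run_metadata.tsv"))
  logf <- file(file.path(dir, paste0("log_", workflow, ".txt")), "w")
  on.exit(close(logf))
  fp <- function(f) file.path(dir, f)
  res <- switch(workflow,
    simulate = {
      ann <- simulate_annotation(config)
      reads <- simulate_testis_reads(config, ann)
      som <- simulate_somatic_pair(config, ann)
      rna <- simulate_rnaseq(config, ann)
      write_gene_models(ann$tracks$genes, fp("genes.tsv"))
      write_bed(ann$tracks$repeats, fp("repeats.bed"))
      write_tsv(data.frame(chrom = names(ann$chrom_lengths),
                           length = as.numeric(ann$chrom_lengths)),
                fp("chrom_lengths.tsv"))
      write_reads_bed(reads$strict, fp("testis_strict.bed"))
      write_reads_bed(reads$relaxed, fp("testis_relaxed.bed"))
      if (!is.null(reads$antisense_strict))
        write_reads_bed(reads$antisense_strict,
                        fp("testis_antisense_strict.bed"))
      write_collapsed_fasta(reads$strict$sequence, reads$strict$read_id,
                            reads$strict$copies, fp("testis_strict.fa"))
      write_reads_bed(som$wt, fp("somatic_wt.bed"))
      write_reads_bed(som$ko, fp("somatic_ko.bed"))
      write_reads_bed(rna, fp("rnaseq.bed"))
      man <- ann$manifest
      write_tsv(man$clusters, fp("manifest_clusters.tsv"))
      write_tsv(man$xutrs, fp("manifest_xutrs.tsv"))
      write_tsv(man$pingpong, fp("manifest_pingpong.tsv"))
      write_tsv(man$somatic, fp("manifest_somatic.tsv"))
      write_tsv(man$rnaseq, fp("manifest_rnaseq.tsv"))
      log_line(logf, "simulate: %d genes, %d planted clusters, %d strict reads, %d WT reads, %d RNA-seq reads",
               length(unique(ann$tracks$genes$gene_id)),
               nrow(man$clusters), nrow(reads$strict), nrow(som$wt),
               nrow(rna))
      list(annotation = ann, reads = reads, somatic = som, rnaseq = rna)
    },
    testis = {
      genes <- read_gene_models(fp("genes.tsv"))
      repeats <- read_bed(fp("repeats.bed"))
      cl_tab <- read_tsv(fp("chrom_lengths.tsv"))
      chrom_lengths <- setNames(cl_tab$length, cl_tab$chrom)
      strict <- read_reads_bed(fp("testis_strict.bed"))
      relaxed <- read_reads_bed(fp("testis_relaxed.bed"))
      tracks <- annotation_tracks(genes, repeats)
      ann_sum <- classify_all(strict, tracks)
      write_tsv(ann_sum, fp("annotation_summary.tsv"))
      log_line(logf, "annotate: %d reads classified", nrow(strict))
      seeds <- density_seeds(strict, chrom_lengths,
                             feature_length = p$feature_length,
                             k_sd = p$k_sd, grid_step = p$grid_step)
      log_line(logf, "seeding: %d seed regions", nrow(seeds))
      utr3 <- call_utr3_clusters(seeds, strict, genes, chrom_lengths,
                                 ext_step = p$ext_step_utr3,
                                 ext_min_reads = p$ext_min_reads_utr3,
                                 strand_frac = p$strand_frac)
      other <- call_other_clusters(seeds, strict, repeats, genes,
                                   chrom_lengths,
                                   ext_step = p$ext_step_other,
                                   ext_min_reads = p$ext_min_reads_other,
                                   repeat_gap = p$repeat_gap,
                                   growth_flag_frac = p$growth_flag_frac)
      write_tsv(as.data.frame(utr3), fp("clusters_utr3.tsv"))
      write_tsv(as.data.frame(other), fp("clusters_other.tsv"))
      write_bed(data.frame(chrom = utr3$chrom, start = utr3$start,
                           end = utr3$end,
                           name = paste(utr3$cluster_id, utr3$source_gene,
                                        sep = ";"),
                           score = utr3$n_sense, strand = utr3$strand),
                fp("clusters_utr3.bed"))
      log_line(logf, "clusters: %d 3'UTR, %d other", nrow(utr3),
               nrow(other))
      # xUTR selection and expression
      xrec <- select_extended(utr3, genes,
                              min_beyond_frac = p$min_beyond_frac)
      xutr_out <- xrec
      if (nrow(xrec) > 0L && file.exists(fp("rnaseq.bed"))) {
        rna <- read_reads_bed(fp("rnaseq.bed"))
        set.seed(config$seed + 10L)
        bg_n <- max(20L, nrow(xrec))
        bg_in <- xrec[rep(seq_len(nrow(xrec)), length.out = bg_n),
                      c("chrom", "start", "end", "strand")]
        bg <- shuffled_background(bg_in, tracks, chrom_lengths)
        bg_rpkm <- vapply(seq_len(nrow(bg)), function(i)
          region_rpkm(bg[i, ], rna, nrow(rna))$rpkm, numeric(1))
        cutoff <- expression_cutoff(bg_rpkm, q = p$expression_q)
        log_line(logf, "xutr: background cutoff %.4g RPKM", cutoff)
        xutr_out <- quantify_xutr(xrec, genes, rna, nrow(rna), cutoff)
        write_bed(bg, fp("xutr_background.bed"))
      }
      write_tsv(xutr_out, fp("xutr.tsv"))
      log_line(logf, "xutr: %d extended-UTR records", nrow(xutr_out))
      # ping-pong
      sites <- do.call(rbind, lapply(seq_len(nrow(utr3)), function(i)
        find_pingpong_sites(utr3[i, ], relaxed)))
      if (is.null(sites))
        sites <- find_pingpong_sites(utr3[0, ], relaxed)
      write_tsv(sites, fp("pingpong_sites.tsv"))
      log_line(logf, "pingpong: %d sites in %d clusters", nrow(sites),
               length(unique(sites$cluster_id)))
      if (nrow(sites) > 0L) {
        comp <- pingpong_composition(sites, relaxed, utr3)
        write_tsv(data.frame(frac_5u = comp$frac_5u,
                             frac_pos10_a = comp$frac_pos10_a,
                             n_antisense = comp$n_antisense_sequences),
                  fp("pingpong_composition.tsv"))
        if (file.exists(fp("testis_antisense_strict.bed"))) {
          anti_strict <- read_reads_bed(fp("testis_antisense_strict.bed"))
          anti_ids <- unlist(strsplit(sites$minus_reads, ",", fixed = TRUE))
          disc <- rep(sites$cluster_id,
                      lengths(strsplit(sites$minus_reads, ",",
                                       fixed = TRUE)))
          keep <- !duplicated(anti_ids)
          calls <- annotate_antisense_sources(anti_ids[keep], disc[keep],
                                              anti_strict, utr3, other)
          write_tsv(calls, fp("pingpong_sources.tsv"))
        }
      }
      # manifest recovery
      if (file.exists(fp("manifest_clusters.tsv"))) {
        man_cl <- read_tsv(fp("manifest_clusters.tsv"))
        rec <- cluster_recovery(utr3,
                                man_cl[man_cl$kind == "utr3", ,
                                       drop = FALSE])
        write_tsv(rec$detail, fp("recovery_utr3.tsv"))
        log_line(logf, "recovery: recall %.3f, gene accuracy %.3f",
                 rec$recall, rec$gene_accuracy)
      }
      list(seeds = seeds, utr3 = utr3, other = other, xutr = xutr_out,
           pingpong_sites = sites, annotation_summary = ann_sum)
    },
    somatic = {
      genes <- read_gene_models(fp("genes.tsv"))
      cl_tab <- read_tsv(fp("chrom_lengths.tsv"))
      chrom_lengths <- setNames(cl_tab$length, cl_tab$chrom)
      wt <- read_reads_bed(fp("somatic_wt.bed"))
      ko <- read_reads_bed(fp("somatic_ko.bed"))
      som <- call_somatic_clusters(wt, genes, nrow(wt),
                                   min_reads = p$somatic_min_reads,
                                   min_density = p$somatic_min_density,
                                   ratio = p$somatic_ratio,
                                   ext_step = p$somatic_ext_step,
                                   chrom_lengths = chrom_lengths)
      write_tsv(as.data.frame(som), fp("somatic_clusters.tsv"))
      log_line(logf, "somatic: %d clusters from %d WT reads", nrow(som),
               nrow(wt))
      dep <- classify_miwi2_dependence(som, wt, ko, nrow(wt), nrow(ko))
      write_tsv(as.data.frame(dep), fp("dependence_calls.tsv"))
      log_line(logf, "dependence: %d dependent, %d independent, %d filtered",
               sum(dep$verdict == "dependent"),
               sum(dep$verdict == "independent"),
               sum(dep$verdict == "filtered"))
      list(clusters = som, dependence = dep)
    },
    stats = {
      strict <- read_reads_bed(fp("testis_strict.bed"))
      cs <- composition_stats(strict)
      write_tsv(data.frame(length = as.integer(names(cs$length_histogram)),
                           count = as.integer(cs$length_histogram)),
                fp("length_histogram.tsv"))
      write_tsv(data.frame(base = names(cs$base_fraction_5p),
                           fraction = as.numeric(cs$base_fraction_5p)),
                fp("base_fraction_5p.tsv"))
      log_line(logf, "stats: %d unique sequences", cs$n_unique)
      list(composition = cs)
    })
  invisible(res)
}
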