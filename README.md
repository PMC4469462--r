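# pirclust

Discovery and characterisation of 3' UTR-associated piRNA clusters in
small-RNA sequencing data.

PIWI-interacting RNAs (piRNAs) are 24–32 nt small RNAs that, in the
adult mouse testis, align in dense genomic clusters, many of them over
the 3' UTRs of protein-coding genes. Some of these clusters run well
past the annotated transcript end; when the extension also shows polyA+
RNA-seq expression, the cluster marks an *extended 3' UTR* (xUTR) — a
rare, previously unannotated long 3' UTR isoform that is the likely
piRNA precursor. Somatic tissues carry shorter (≈23 nt, 5'A-biased)
small RNAs over the same regions, and a subset of somatic clusters
vanishes in *Miwi2* knockout animals.

`pirclust` implements this analysis end to end for researchers working
with small-RNA and RNA-seq alignment data:

* **Preprocessing** — 3' adapter trimming (≤ 25% mismatch),
  exact-duplicate collapsing, contaminant removal (≤ 3 mismatches,
  either strand), dataset similarity indices, and length/base
  composition summaries.
* **Classification** — each uniquely aligned read is placed in exactly
  one of repeat > mRNA > intron > intergenic, requiring ≥ 50% of the
  read length to overlap the track.
* **Cluster calling** — Gaussian kernel-density seeding of read pileups
  (feature length 1000 bp, threshold μ₀ + 15σ₀ over a uniform null),
  then two refinement chains: 3' UTR clusters (1-kb/2-read extension,
  merge, shrink-to-reads, > 60% unidirectionality, source-gene
  assignment, 5'-trim to the annotated UTR, adjacent-gene truncation)
  and intergenic/other clusters (500-bp/1-read extension, merging with
  repeats within 50 bp, strand-aware splitting of over-grown clusters).
* **xUTRs** — clusters extending > 30% of their length past the
  annotated UTR, quantified as RPKM = n·10⁹/(L·N) against a cutoff set
  at the 95th percentile of shuffled intergenic background regions.
* **Ping-pong signature** — sites where plus- and minus-strand 5' ends
  overlap by exactly 10 bp inside a cluster, with antisense composition
  (5' U, position-10 A) and best-genomic-source attribution.
* **Somatic clusters & MIWI2 dependence** — per-gene calls on the
  largest 3' UTR isoform (UTR density ≥ 2× CDS density, ≥ 3 reads,
  density > 7.5 reads/kb/million), classified against a knockout
  library: any KO read ⇒ independent; no KO reads and WT density above
  the bottom quartile ⇒ dependent; otherwise filtered.
* **Synthetic data** — a deterministic generator that plants clusters,
  hidden UTR extensions, ping-pong pairs and WT/KO dependence labels
  with a ground-truth manifest, so the whole pipeline is testable with
  no external downloads.

## Worked example

Simulate a toy study (two 1-Mb chromosomes, 20 genes, 10 planted 3' UTR
clusters, 8 hidden UTR extensions), call clusters, and score them
against the ground truth:

```r
library(pirclust)

cfg   <- sim_config(seed = 1)
ann   <- simulate_annotation(cfg)
reads <- simulate_testis_reads(cfg, ann)

seeds <- density_seeds(reads$strict, ann$chrom_lengths)
cl    <- call_utr3_clusters(seeds, reads$strict, ann$tracks$genes,
                            ann$chrom_lengths)
cl
#> piRNA clusters: 10 region(s)
#>   kinds: utr3=10
#>   median length: 4496 bp

rec <- cluster_recovery(cl, subset(ann$manifest$clusters, kind == "utr3"))
rec$recall          # 1       (all 10 planted clusters found)
mean(rec$detail$jaccard)  # 0.987 (boundary agreement with the truth)
rec$gene_accuracy   # 1       (every cluster assigned its true gene)

composition_stats(reads$strict$sequence)
#> Small-RNA composition summary
#>   unique sequences: 2224  total reads: 2224
#>   modal length: 29 nt
#>   5' U fraction: 0.691
#>   position-10 A fraction: 0.238

xr <- select_extended(cl, ann$tracks$genes)
nrow(xr)            # 7 clusters extend >30% past their annotated UTR
```

The recall of 1 and boundary Jaccard of 0.987 say the caller found every
planted cluster with near-exact boundaries; the modal length of 29 nt
and 69% 5' U are the piRNA hallmarks the simulator plants and the
composition module recovers. The same objects feed the downstream
stages: `quantify_xutr()` for expression, `find_pingpong_sites()` for
the 10-bp overlap signature, and `call_somatic_clusters()` /
`classify_miwi2_dependence()` for the WT/KO analysis.

File-based runs of the same workflows (useful from the shell) go through
`run_pipeline()`, or the thin CLI in `inst/scripts/pirclust`:

```sh
Rscript inst/scripts/pirclust simulate --dir run1 --seed 1
Rscript inst/scripts/pirclust testis   --dir run1
Rscript inst/scripts/pirclust somatic  --dir run1
```

## Package layout

| Path | Contents |
|---|---|
| `R/intervals.R` | coordinate conventions, interval arithmetic, read tables |
| `R/preprocess.R` | trimming, collapsing, contaminant filter, composition |
| `R/annotate.R` | exclusive genomic classification |
| `R/cluster-testis.R` | density seeding and both cluster-refinement chains |
| `R/xutr.R` | xUTR selection, RPKM, shuffled background, cutoff |
| `R/pingpong.R` | 10-bp overlap sites, composition, source attribution |
| `R/somatic.R` | somatic cluster calling and MIWI2 classification |
| `R/simulate.R` | synthetic genomes, reads and ground-truth manifest |
| `R/pipeline.R` | file-based workflows and recovery scoring |
| `vignettes/pirclust-methods.Rmd` | the methods write-up |

See the methods vignette for the model, every tunable parameter with its
default and rationale, and the generator's scope and limitations.
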