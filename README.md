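# tarseq

Annotation-free feature discovery for single-cell RNA-seq.

Standard scRNA-seq pipelines count reads only inside known gene models, so
any transcription missing from the annotation is invisible — a serious
loss for organisms with young or sparse annotations (non-model species,
early developmental stages). `tarseq` recovers that signal: it segments
the genome into **transcriptionally active regions (TARs)** directly from
the aligned reads, labels each TAR as **annotated (aTAR)** or
**unannotated (uTAR)** against whatever annotation exists, and then asks,
with ordinary single-cell statistics, which uTARs carry real cell-type
information.

It is aimed at anyone analyzing 10X-style (barcode + UMI) or Smart-seq2
scRNA-seq data in R who suspects their annotation is incomplete.

## The model

Reads are counted on each strand in fixed, non-overlapping windows
(default *w* = 50 bp). The window counts *x₁, …, x_T* of every
chromosome × strand are modeled with a two-state hidden Markov model —
state 0 untranscribed, state 1 transcribed — with gamma emissions:

    x_t + c | s_t = k  ~  Gamma(shape_k, scale_k),   k ∈ {0, 1}

where *c* = 0.25 is a pseudocount keeping zero counts inside the gamma
support. All parameters (two gamma laws, the 2×2 transition matrix, the
initial distribution) are estimated genome-wide by Baum–Welch EM with
scaled forward–backward recursions; the transcribed state is the one with
the larger emission mean. Viterbi decoding yields per-strand transcribed
intervals, which are then

1. merged when separated by ≤ 500 bp on the same strand,
2. filtered to regions with ≥ *n* same-strand overlapping reads, where
   *n* = max(1, ⌊unique reads / 10⁷⌋), and
3. labeled aTAR if they overlap any transcript span (either strand, in
   the default mode; same strand only in `directional` mode), else uTAR.

Downstream, a sparse cells × TARs UMI-deduplicated matrix feeds
log-normalization, PCA, silhouette comparison of embeddings, and
one-vs-rest Wilcoxon rank-sum tests (with min-pct and natural-log
fold-change pre-filters) to find cell-type-specific uTARs. Each
differential uTAR's coverage profile is LOESS-smoothed (span 0.25), the
full width at half maximum of its largest peak is extracted, and the peak
sequence is labeled from tabular homology hits (e ≤ 0.01, bit score ≥ 50,
highest bit score wins).

## Worked example

Everything below is self-contained: the built-in generator writes a
genome, an annotation with 30% of loci deliberately withheld, and a
tagged BAM sampled from cell-type-specific expression programs.

```r
library(tarseq)

cfg <- sim_config(n_chroms = 1, chrom_length = 2e5, n_loci = 12,
                  locus_length = c(1000, 3000), n_celltypes = 2,
                  cells_per_type = 50, reads_per_cell = 1000, seed = 42)
sim <- simulate_tar_data(cfg, tempfile("demo"))

aln   <- read_alignments(sim$bam)
annot <- read_refflat(sim$annotation_partial)
res   <- call_tars(aln, annot)
print(res$hmm)
#> Two-state gamma-emission HMM (Baum-Welch fit)
#>   windows: 8000   iterations: 4   converged: TRUE
#>   state 0 (untranscribed): mean 0.883  (shape 1.341, scale 0.658)
#>   state 1 (transcribed):   mean 182.728  (shape 2.065, scale 88.483)
#>   self-transitions: 0.99839 / 0.97701   log-likelihood: -9683.46

table(S4Vectors::mcols(res$tars)$label)
#> aTAR uTAR
#>    8    4
```

The HMM has found a sharp two-regime structure (window means 0.9 vs 183)
and calls 12 TARs — the 8 annotated loci as aTARs and the 4 withheld ones
as uTARs. Counting and testing show the uTARs alone separate the two cell
types:

```r
cfm    <- count_features(aln, res$tars)          # UMI-deduplicated
labels <- sim$cells$cell_type[match(cfm$barcodes, sim$cells$barcode)]
norm   <- lognormalize(cfm)
u      <- cfm$features$label == "uTAR"

pcs <- run_pca(norm[, u, drop = FALSE], 10)
silhouette_scores(pcs$embeddings, labels)$mean
#> [1] 0.686

de <- wilcoxon_de(norm[, u, drop = FALSE], labels,
                  min_pct = 0.25, logfc_threshold = 0.25)
head(de[, c("feature_id", "cluster_id", "p_adjusted", "avg_log_fc")], 3)
#>   feature_id cluster_id   p_adjusted avg_log_fc
#> 1     TAR_11      type1 1.410985e-17   2.025077
#> 2     TAR_10      type1 1.411622e-17   2.079421
#> 3      TAR_2      type2 7.061292e-18   2.042773
```

A mean silhouette of 0.69 on the uTAR-only embedding means the withheld
loci alone still cleanly separate the cell types, and the top
differential uTARs are exactly the planted markers, each with roughly a
2 natural-log fold change. `annotate_utar_peaks()` would then extract
each uTAR's coverage peak and label it from a BLAST-style hit table.

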