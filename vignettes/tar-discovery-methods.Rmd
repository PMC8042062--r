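---
title: "Methods: HMM-based TAR discovery and uTAR selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HMM-based TAR discovery and uTAR selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the model and
its assumptions, the parameters that matter, the numerical choices made
where conventions diverge, and what the synthetic validation does and
does not demonstrate.

## The segmentation model

`tarseq` treats transcription discovery as a two-state segmentation
problem on windowed read coverage. Reads are assigned — by the window
containing their 5'-most aligned base — to non-overlapping windows of
`window_size` bp on each chromosome and strand separately. A hidden
Markov model with states *untranscribed* (0) and *transcribed* (1) and
gamma-distributed emissions is fitted to all tracks jointly by Baum–Welch
EM, and each track is decoded by the Viterbi algorithm.

The modeling assumptions are:

* **Two regimes suffice.** Coverage within a transcription unit is
  roughly stationary around one mean, background around another, much
  lower one. There is no explicit duration model; run lengths are
  geometric, encoded in the self-transition probabilities.
* **Gamma emissions for both states.** The gamma family accommodates the
  overdispersed, right-skewed window counts of both background
  (near-zero mean, high skew) and transcribed windows. Because the gamma
  density is undefined at zero, emissions are evaluated on
  `counts + pseudocount` with `pseudocount = 0.25` by default. The
  pseudocount is a configuration knob; anything in (0, 1) behaves
  similarly because it only shifts the support, not the ordering of
  likelihoods.
* **Strand independence.** Sense and antisense transcription are
  segmented independently; a single parameter set is shared genome-wide
  (all chromosomes and strands enter EM as independent observation
  sequences), which mirrors how transcription-unit callers are used in
  practice and keeps the parameter count at seven.

### Numerical choices

* Forward–backward uses per-step scaling rather than log-space sums, so
  likelihood evaluation is O(T) with no underflow for tracks of many
  millions of windows; the log-likelihood is accumulated from the
  scaling constants.
* The gamma M-step maximizes the posterior-weighted likelihood exactly:
  the shape solves `log(k) − digamma(k) = log(w̄) − log-mean` by Newton
  iteration (50 steps, relative tolerance 1e-10), the scale follows as
  mean/shape. When the weighted data are essentially constant the shape
  is capped at 1e6, giving a near-point-mass state instead of a
  numerical failure.
* EM stops when the relative log-likelihood change drops below
  `tol = 1e-4` (default) or after `max_iter = 100` iterations. The trace
  is retained in the fit and is non-decreasing up to 1e-8 slack — a
  property the test suite asserts on every fitted object it builds.
* After convergence states are relabeled so that state 1 has the larger
  emission mean; a fit whose two means differ by less than 1% is flagged
  `degenerate` and warned about, because decoding it is meaningless.
* Viterbi decoding is used rather than posterior thresholding because it
  produces contiguous, reproducible segments consistent with the
  transition structure; log emission densities are floored at
  `log(1e-300)` so an extreme observation cannot produce a NaN path
  score. Ties are broken toward the untranscribed state, making decoding
  fully deterministic.
* Initialization (`init = "auto"`): windows at or below the 75th count
  percentile seed state 0, the rest seed state 1, both by the method of
  moments; self-transitions start at 0.999. The persistence prior
  matters more than the emission seed — transcription units span many
  consecutive windows, and a weak initial self-transition can let EM
  converge to a solution that toggles states on single-window noise.

## From decoded states to TAR features

Maximal runs of state 1 become half-open genomic intervals on window
boundaries. Then:

* **Merging**: same-strand intervals with a gap of at most `merge_gap`
  (default 500 bp) are unioned. The boundary semantics are exact: a gap
  of 500 merges, 501 does not. This is implemented on
  `GenomicRanges::reduce` with `min.gapwidth = merge_gap + 1` and is
  tested against a brute-force union oracle.
* **Depth filter**: each merged interval's read support is the number of
  same-strand reads whose *aligned blocks* overlap it by ≥ 1 bp (spliced
  gaps do not count; a read may support several intervals). Intervals
  with fewer than `n = max(1, floor(total_unique_reads / 1e7))` reads
  are dropped. The floor-then-clamp rounding is a package decision: the
  ratio alone would keep zero-read regions at shallow depth.
* **Labeling**: overlap is tested against *transcript spans*
  (transcription start to stop), not exon unions, with any-bp overlap
  counting. In the default `strand_agnostic` mode a TAR overlapping
  annotation on either strand is an aTAR — this is deliberately
  conservative about calling anything "unannotated", since antisense
  transcription near a gene is hard to distinguish from artifacts. The
  `directional` mode relaxes this: only same-strand overlap makes an
  aTAR, and antisense-only TARs become uTARs carrying an
  `antisense-overlap` flag. The flag is recorded in both modes so the
  two labelings can be compared without recomputation.

Coordinates are handled in the 1-based closed `GRanges` convention
internally — the native currency of the Bioconductor stack the package
is built on — and converted at format boundaries (BED and refFlat are
written and read 0-based half-open, GTF 1-based closed).

## Counting and single-cell statistics

The cells × TARs matrix counts, in `umi_10x` mode, one unit per distinct
(barcode, feature, UMI) triple whose read overlaps the feature on the
same strand. UMI collapse is exact-match; error-aware barcode/UMI
correction belongs upstream. A read overlapping several features counts
toward each — within one strand's decoded TARs overlaps are impossible
after merging, so double counting can only arise between feature sets
(e.g. genes vs TARs), which are counted separately. In `fragment_ss2`
mode each properly paired fragment (per-cell files, Smart-seq2 style)
counts once per overlapped same-strand feature, with no UMI step.

Downstream statistics follow the standard single-cell toolchain, with
these specific choices:

* **Log-normalization**: `ln(count / cell_total × 10⁴ + 1)`, sparse in,
  sparse out.
* **PCA**: features are centered, scaled to unit variance
  (zero-variance features contribute zeros rather than NaNs) and clipped
  at ±10 before SVD; clipping stops a handful of extreme standardized
  values in sparse features from dominating early components. Loadings
  are unit-norm right singular vectors, so the sign of a PC is
  arbitrary — every quantity derived from loadings uses absolute values.
* **Clustering is an input, not a step.** Cluster labels come from the
  caller (metadata, marker genes, or any community-detection method).
  This keeps the statistical core free of a graph-clustering dependency
  and matches how the comparison is meant to be read: labels derived
  from gene expression, evaluated on uTAR embeddings.
* **Silhouette**: the textbook per-cell formula with Euclidean distance
  on a caller-supplied 2-D embedding; singleton clusters score 0. Any
  2-D embedding is accepted (UMAP coordinates in a full analysis); the
  first two PCs are the dependency-free default used in the tests.
* **Wilcoxon DE**: one cluster versus all remaining cells, two-sided.
  Features are pre-filtered to `pct_in ≥ min_pct` and
  `avg_log_fc > logfc_threshold` — positive only, so results are
  up-regulated markers. The fold-change estimator is
  `ln(mean(expm1(x_in)) + 1) − ln(mean(expm1(x_out)) + 1)`, the de-facto
  convention for log-normalized data. P-values use the exact rank-sum
  distribution — computed by dynamic programming over the (possibly
  tied) rank multiset — whenever the pooled sample size is ≤ 30, and the
  tie-corrected normal approximation with continuity correction
  otherwise; the exact route is validated against full enumeration of
  all `choose(m+n, m)` assignments. Adjustment is Bonferroni over the
  features actually tested within each cluster, the conservative default
  of the toolchain this workflow follows.
* **Loading scores**: the sum of absolute loadings over the first
  `k = 5` PCs; the pseudo-bulk comparison classifies uTARs at cuts of
  10⁴ reads and 0.5 loading score ("high" means ≥ the cut) and reports
  Pearson r² between the two quantities.

## The peak workflow

For each differential uTAR the per-base, same-strand block coverage is
smoothed by LOESS — tricube weights, degree 1, no robustness
iterations, `span = 0.25` — evaluated at every base and clipped at zero.
Degree-1 LOESS reproduces constant and linear profiles exactly, which is
the property the tests pin down. Exact evaluation
(`surface = "direct"`) is used up to 5,000 bases; longer profiles fall
back to interpolated evaluation, whose error is negligible at that
scale. Profiles shorter than 10 bases, or spans covering fewer than 3
points, are rejected with advice to use the raw maximum.

The largest peak is the global maximum of the smoothed signal; on a
plateau the leftmost position is taken (a package decision — any point
of the plateau would be defensible). The FWHM interval extends to the
nearest positions on each side where the signal falls to half the
maximum, clamped to the uTAR ends when it never does. The peak's
*plus-strand* genomic sequence is extracted regardless of uTAR strand,
since nucleotide homology search scans both strands anyway. Hit tables
(tabular 12- or 13-column format) are filtered at e-value ≤ 0.01 and bit
score ≥ 50; the surviving hit with the highest bit score names the uTAR,
ties broken by lower e-value then input order, and an empty survivor set
leaves it `unknown`.

## What the synthetic generator emulates — and what it does not

`simulate_tar_data()` writes a complete, deterministic study: a random
genome, well-separated transcribed loci with per-cell-type expression
programs, an annotation from which a chosen fraction of loci is
withheld, and coordinate-sorted, barcode/UMI-tagged alignments with
uniform background noise. The default configuration — 2 chromosomes ×
500 kb, 30 loci of 1–5 kb separated by ≥ 2 kb, 3 cell types × 100 cells
× 2,000 reads, 30% of loci withheld, half the loci 8-fold up-regulated
in one cell type, 5% background reads, seed 42 — was chosen so that
post-merge TARs map 1:1 to loci and a full run takes about two minutes
on one CPU. Within-locus coverage is uniform; reads are written
pre-aligned with MAPQ 255 (plus optional low-MAPQ decoys), so positions
are ground truth. The UMI space (10⁶ per cell) makes collision-driven
undercounting negligible; a deliberately tiny UMI space is available to
exercise deduplication.

What it does **not** model: spliced reads, 3'-end coverage bias,
sequencing errors, barcode swapping, ambient RNA, doublets, overlapping
or nested genes, and annotation errors other than omission. Passing the
validation therefore shows that the implementation is correct under its
own assumptions — clean two-regime coverage and well-separated loci —
not that TAR calls on real tissue reach any particular accuracy. On real
data the practical failure modes are merged adjacent genes (gap ≤ 500
bp), fragmented calls in low-coverage transcripts, and uTARs caused by
annotation coordinate errors rather than missing transcription.

## Validation scale

The test suite and the acceptance script run at deliberately modest
sizes chosen to exercise every code path while keeping a full run in the
minutes range: the default fixture above for end-to-end recovery and
discriminability; 50,000 windows for HMM parameter recovery (state means
recovered within a few percent); exhaustive 2^n path enumeration up to
12 windows for Viterbi; 1,000 random interval sets for the merge oracle;
10⁴ reads for the counting oracle; and 500 cells for the silhouette
oracle. Larger inputs change runtimes, not the properties being
asserted.

## Known limitations

* Two states and geometric run lengths: long genes with internal
  coverage dips can fragment; a semi-Markov or multi-state model is out
  of scope.
* One parameter set genome-wide assumes depth homogeneity across
  chromosomes; strong copy-number structure would violate it.
* The depth threshold scales with total reads only; it does not adapt
  to local mappability.
* Exact Wilcoxon enumeration is limited to pooled sizes ≤ 30; beyond
  that the normal approximation's accuracy is the usual asymptotic one.
* Variable-feature selection before PCA is not implemented; all
  (filtered) features enter the decomposition.
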