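#' Configuration for the synthetic scRNA-seq fixture generator
#'
#' Bundles and validates the parameters of \code{\link{simulate_tar_data}}.
#' The defaults describe a small but realistic study: a two-chromosome
#' 1 Mb genome carrying 30 well-separated transcribed loci, three cell
#' types of 100 cells sequenced to 2,000 reads each, 30\% of loci withheld
#' from the partial annotation (so they surface as uTARs), half of the
#' loci 8-fold up-regulated in one cell type, and 5\% uniform background
#' reads.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_loci Number of transcribed loci across the genome.
#' @param locus_length Length range (min, max) in bp.
#' @param n_celltypes Number of cell types.
#' @param cells_per_type Cells per type.
#' @param reads_per_cell Reads per cell.
#' @param holdout_fraction Fraction of loci omitted from the partial
#'   annotation.
#' @param de_fold_change Expression multiplier of a marker locus in its
#'   cell type.
#' @param marker_fraction Fraction of loci that are cell-type markers
#'   (each assigned to one type, round-robin).
#' @param background_rate Fraction of reads drawn uniformly from the
#'   genome instead of a locus.
#' @param read_length Read length in bp.
#' @param umi_space Number of distinct UMIs available per cell (default
#'   1e6, so collisions are negligible; shrink deliberately to exercise
#'   deduplication).
#' @param low_mapq_reads Extra non-unique reads (MAPQ 3) added genome-wide,
#'   excluded from every ground-truth total.
#' @param min_gap Minimum gap enforced between loci on the same
#'   chromosome (default 2000 bp, keeping post-merge TARs 1:1 with loci).
#' @param seed Integer seed; the whole fixture is deterministic given it.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 5e5, n_loci = 30,
                       locus_length = c(1000, 5000), n_celltypes = 3,
                       cells_per_type = 100, reads_per_cell = 2000,
                       holdout_fraction = 0.3, de_fold_change = 8,
                       marker_fraction = 0.5, background_rate = 0.05,
                       read_length = 90, umi_space = 1e6,
                       low_mapq_reads = 0, min_gap = 2000, seed = 42) {
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    n_loci = as.integer(n_loci), locus_length = as.integer(locus_length),
    n_celltypes = as.integer(n_celltypes),
    cells_per_type = as.integer(cells_per_type),
    reads_per_cell = as.integer(reads_per_cell),
    holdout_fraction = holdout_fraction, de_fold_change = de_fold_change,
    marker_fraction = marker_fraction, background_rate = background_rate,
    read_length = as.integer(read_length), umi_space = as.integer(umi_space),
    low_mapq_reads = as.integer(low_mapq_reads),
    min_gap = as.integer(min_gap), seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_chroms >= 1, cfg$chrom_length >= 1, cfg$n_loci >= 1,
    length(cfg$locus_length) == 2, all(cfg$locus_length >= 1),
    cfg$locus_length[1] <= cfg$locus_length[2],
    cfg$n_celltypes >= 1, cfg$cells_per_type >= 1, cfg$reads_per_cell >= 1,
    cfg$holdout_fraction >= 0, cfg$holdout_fraction <= 1,
    cfg$de_fold_change > 0, cfg$marker_fraction >= 0, cfg$marker_fraction <= 1,
    cfg$background_rate >= 0, cfg$background_rate < 1,
    cfg$read_length >= 1, cfg$umi_space >= 1, cfg$seed >= 0
  )
  class(cfg) <- "sim_config"
  cfg
}

# base-4 encode an integer id as an ACGT string of fixed width
.dna_encode <- function(ids, width) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("A", nrow = length(ids), ncol = width)
  v <- as.integer(ids)
  for (k in seq_len(width)) {
    out[, width - k + 1] <- bases[v %% 4L + 1L]
    v <- v %/% 4L
  }
  apply(out, 1, paste, collapse = "")
}

#' Generate a self-contained synthetic scRNA-seq fixture
#'
#' Writes a random genome FASTA (with index), a full and a deliberately
#' incomplete refFlat/GTF annotation, and a coordinate-sorted,
#' barcode/UMI-tagged alignment file (SAM plus indexed BAM) sampled from
#' cell-type-specific expression programs, together with machine-readable
#' ground truth for every read, cell and locus. All randomness derives
#' from \code{config$seed}, so the same configuration reproduces the same
#' fixture byte for byte.
#'
#' Reads are written pre-aligned — their positions are the ground truth —
#' with MAPQ 255 and proper flags; there is no aligner, sequencing-error
#' or splicing model. Each read's origin (locus id or \code{background})
#' is recorded.
#'
#' @param config A \code{\link{sim_config}}.
#' @param out_dir Output directory (created if needed).
#' @return A list with the output paths (\code{genome}, \code{bam},
#'   \code{sam}, \code{annotation_full}, \code{annotation_partial},
#'   \code{annotation_full_gtf}, \code{annotation_partial_gtf}) and the
#'   ground truth (\code{loci} GRanges with expression metadata,
#'   \code{cells} and \code{reads} data frames), plus the \code{config}.
#' @export
simulate_tar_data <- function(config = sim_config(), out_dir = tempfile("tarsim")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cfg <- config

  ## genome ----------------------------------------------------------------
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  genome <- vapply(chroms, function(cm) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
      collapse = ""
    )
  }, "")
  genome_path <- file.path(out_dir, "genome.fa")
  gset <- Biostrings::DNAStringSet(genome)
  names(gset) <- chroms
  Biostrings::writeXStringSet(gset, genome_path)
  Rsamtools::indexFa(genome_path)

  ## loci ------------------------------------------------------------------
  per_chrom <- diff(round(seq(0, cfg$n_loci, length.out = cfg$n_chroms + 1)))
  slots <- list()
  for (ci in seq_len(cfg$n_chroms)) {
    k <- per_chrom[ci]
    if (k == 0) next
    slot_w <- cfg$chrom_length %/% k
    if (slot_w < cfg$locus_length[2] + cfg$min_gap + cfg$read_length) {
      stop(
        "cannot place ", k, " loci of up to ", cfg$locus_length[2],
        " bp with ", cfg$min_gap, " bp gaps on a ", cfg$chrom_length,
        " bp chromosome; use longer chromosomes or fewer loci"
      )
    }
    len <- sample(cfg$locus_length[1]:cfg$locus_length[2], k, replace = TRUE)
    margin <- slot_w - len - cfg$min_gap
    offset <- floor(stats::runif(k) * margin) + cfg$min_gap %/% 2
    start <- (seq_len(k) - 1L) * slot_w + offset + 1L # 1-based
    slots[[ci]] <- data.frame(
      chrom = chroms[ci], start = start, end = start + len - 1L,
      strand = sample(c("+", "-"), k, replace = TRUE)
    )
  }
  loci_df <- do.call(rbind, slots)
  loci_df$locus_id <- sprintf("locus_%02d", seq_len(nrow(loci_df)))

  n_loci <- nrow(loci_df)
  n_annot <- round((1 - cfg$holdout_fraction) * n_loci)
  annotated <- rep(FALSE, n_loci)
  annotated[sample.int(n_loci, n_annot)] <- TRUE
  loci_df$annotated <- annotated

  n_marker <- round(cfg$marker_fraction * n_loci)
  marker_type <- rep(NA_integer_, n_loci)
  if (n_marker > 0) {
    marker_idx <- sample.int(n_loci, n_marker)
    marker_type[marker_idx] <- rep_len(seq_len(cfg$n_celltypes), n_marker)
  }
  loci_df$marker_type <- marker_type

  base_expr <- stats::runif(n_loci, 0.5, 1.5)
  expr <- matrix(base_expr, n_loci, cfg$n_celltypes)
  for (i in which(!is.na(marker_type))) {
    expr[i, marker_type[i]] <- expr[i, marker_type[i]] * cfg$de_fold_change
  }

  ## annotations -----------------------------------------------------------
  make_annot <- function(df) {
    data.frame(
      gene_name = df$locus_id, transcript_name = paste0(df$locus_id, ".1"),
      chrom = df$chrom, strand = df$strand,
      tx_start = df$start - 1L, tx_end = df$end,
      cds_start = df$start - 1L, cds_end = df$end, exon_count = 1L,
      exon_starts = I(as.list(df$start - 1L)), exon_ends = I(as.list(df$end))
    )
  }
  full_annot <- make_annot(loci_df)
  part_annot <- make_annot(loci_df[loci_df$annotated, , drop = FALSE])
  ann_full <- file.path(out_dir, "annotation_full.refflat")
  ann_part <- file.path(out_dir, "annotation_partial.refflat")
  write_refflat(full_annot, ann_full)
  write_refflat(part_annot, ann_part)
  gtf_line <- function(df) {
    sprintf(
      '%s\ttarsim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.1";',
      df$chrom, df$start, df$end, df$strand, df$locus_id, df$locus_id
    )
  }
  ann_full_gtf <- file.path(out_dir, "annotation_full.gtf")
  ann_part_gtf <- file.path(out_dir, "annotation_partial.gtf")
  writeLines(gtf_line(loci_df), ann_full_gtf)
  writeLines(gtf_line(loci_df[loci_df$annotated, , drop = FALSE]), ann_part_gtf)

  ## cells and reads -------------------------------------------------------
  n_cells <- cfg$n_celltypes * cfg$cells_per_type
  cell_type <- rep(seq_len(cfg$n_celltypes), each = cfg$cells_per_type)
  barcodes <- .dna_encode(seq_len(n_cells) - 1L, 12L)
  cells_df <- data.frame(
    barcode = barcodes,
    cell_type = paste0("type", cell_type)
  )

  n_reads <- n_cells * cfg$reads_per_cell
  read_cell <- rep(seq_len(n_cells), each = cfg$reads_per_cell)
  is_bg <- stats::runif(n_reads) < cfg$background_rate

  origin <- rep(NA_integer_, n_reads)
  for (ct in seq_len(cfg$n_celltypes)) {
    sel <- which(!is_bg & cell_type[read_cell] == ct)
    origin[sel] <- sample.int(n_loci, length(sel),
      replace = TRUE,
      prob = expr[, ct]
    )
  }

  chrom_of <- character(n_reads)
  pos <- integer(n_reads) # 1-based leftmost
  strand_of <- character(n_reads)

  fg <- which(!is_bg)
  li <- origin[fg]
  span <- pmax(loci_df$end[li] - loci_df$start[li] + 1L - cfg$read_length, 1L)
  chrom_of[fg] <- loci_df$chrom[li]
  pos[fg] <- loci_df$start[li] + floor(stats::runif(length(fg)) * span)
  strand_of[fg] <- loci_df$strand[li]

  bg <- which(is_bg)
  if (length(bg)) {
    bchr <- sample.int(cfg$n_chroms, length(bg), replace = TRUE)
    chrom_of[bg] <- chroms[bchr]
    pos[bg] <- floor(stats::runif(length(bg)) *
      (cfg$chrom_length - cfg$read_length)) + 1L
    strand_of[bg] <- sample(c("+", "-"), length(bg), replace = TRUE)
  }

  umis <- .dna_encode(
    sample.int(cfg$umi_space, n_reads, replace = TRUE) - 1L, 10L
  )

  reads_df <- data.frame(
    qname = sprintf("read%07d", seq_len(n_reads)),
    barcode = barcodes[read_cell],
    umi = umis,
    chrom = chrom_of, pos = pos, strand = strand_of,
    mapq = 255L,
    origin = ifelse(is_bg, "background", loci_df$locus_id[origin])
  )

  if (cfg$low_mapq_reads > 0) {
    k <- cfg$low_mapq_reads
    lchr <- chroms[sample.int(cfg$n_chroms, k, replace = TRUE)]
    extra <- data.frame(
      qname = sprintf("multi%06d", seq_len(k)),
      barcode = barcodes[sample.int(n_cells, k, replace = TRUE)],
      umi = .dna_encode(sample.int(cfg$umi_space, k, replace = TRUE) - 1L, 10L),
      chrom = lchr,
      pos = floor(stats::runif(k) * (cfg$chrom_length - cfg$read_length)) + 1L,
      strand = sample(c("+", "-"), k, replace = TRUE),
      mapq = 3L,
      origin = "multimapped"
    )
    reads_df <- rbind(reads_df, extra)
  }

  ## SAM/BAM ---------------------------------------------------------------
  ord <- order(match(reads_df$chrom, chroms), reads_df$pos)
  sam_df <- reads_df[ord, ]
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chroms, cfg$chrom_length)
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tCB:Z:%s\tUB:Z:%s",
    sam_df$qname, ifelse(sam_df$strand == "+", 0L, 16L), sam_df$chrom,
    sam_df$pos, sam_df$mapq, cfg$read_length, sam_df$barcode, sam_df$umi
  )
  sam_path <- file.path(out_dir, "reads.sam")
  writeLines(c(header, body), sam_path)
  bam_path <- Rsamtools::asBam(sam_path,
    destination = file.path(out_dir, "reads"),
    overwrite = TRUE, indexDestination = TRUE
  )

  ## truth tables ----------------------------------------------------------
  loci_gr <- GenomicRanges::GRanges(
    seqnames = loci_df$chrom,
    ranges = IRanges::IRanges(start = loci_df$start, end = loci_df$end),
    strand = loci_df$strand,
    seqlengths = stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
  )
  S4Vectors::mcols(loci_gr) <- S4Vectors::DataFrame(
    locus_id = loci_df$locus_id, annotated = loci_df$annotated,
    marker_type = ifelse(is.na(loci_df$marker_type), NA_character_,
      paste0("type", loci_df$marker_type)
    )
  )
  utils::write.table(
    as.data.frame(loci_gr),
    file.path(out_dir, "truth_loci.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(cells_df, file.path(out_dir, "truth_cells.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(reads_df, file.path(out_dir, "truth_reads.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  list(
    genome = genome_path, sam = sam_path, bam = bam_path,
    annotation_full = ann_full, annotation_partial = ann_part,
    annotation_full_gtf = ann_full_gtf, annotation_partial_gtf = ann_part_gtf,
    loci = loci_gr, cells = cells_df, reads = reads_df,
    expression = expr, config = cfg, dir = out_dir
  )
}

#' Score pipeline output against the simulation ground truth
#'
#' Compares called TARs and differential-expression results with the
#' generator's records: (a) locus-level recall and precision of the TAR
#' calls at a reciprocal-overlap threshold (same strand), (b) the fraction
#' of held-out loci whose matching TAR is labeled uTAR, and (c) the
#' fraction of truly cell-type-specific held-out loci that appear among
#' the differential uTARs of their own cell type.
#'
#' @param tars Labeled \code{GRanges} from \code{\link{label_tars}} /
#'   \code{\link{call_tars}}.
#' @param truth The list returned by \code{\link{simulate_tar_data}} (or
#'   its \code{loci} element).
#' @param de_results Optional \code{\link{wilcoxon_de}} data frame whose
#'   \code{cluster_id} values are the true cell-type labels.
#' @param min_reciprocal Minimum reciprocal overlap fraction (default
#'   0.5).
#' @return A list with \code{recall}, \code{precision},
#'   \code{holdout_utar_fraction}, \code{de_recovery} (NA when no
#'   \code{de_results}), and a per-locus \code{matches} data frame.
#' @export
evaluate_recovery <- function(tars, truth, de_results = NULL,
                              min_reciprocal = 0.5) {
  loci <- if (methods::is(truth, "GRanges")) truth else truth$loci
  m <- S4Vectors::mcols(tars)

  hits <- GenomicRanges::findOverlaps(loci, tars, ignore.strand = FALSE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(loci)[qi], GenomicRanges::ranges(tars)[si]
  ))
  recip <- ov / GenomicRanges::width(loci)[qi] >= min_reciprocal &
    ov / GenomicRanges::width(tars)[si] >= min_reciprocal

  matched_locus <- unique(qi[recip])
  matched_tar <- unique(si[recip])
  recall <- length(matched_locus) / length(loci)
  precision <- if (length(tars)) length(matched_tar) / length(tars) else NA_real_

  # best-overlap TAR per locus (any overlap), for labeling/DE lookups
  best <- rep(NA_integer_, length(loci))
  if (length(qi)) {
    o <- order(qi, -ov)
    first <- !duplicated(qi[o])
    best[qi[o][first]] <- si[o][first]
  }
  lm <- S4Vectors::mcols(loci)
  held <- which(!lm$annotated)
  holdout_utar <- if (length(held)) {
    mean(!is.na(best[held]) & m$label[best[held]] == "uTAR")
  } else {
    NA_real_
  }

  de_recovery <- NA_real_
  if (!is.null(de_results)) {
    spec <- which(!lm$annotated & !is.na(lm$marker_type))
    if (length(spec)) {
      found <- vapply(spec, function(i) {
        if (is.na(best[i])) {
          return(FALSE)
        }
        any(de_results$feature_id == m$id[best[i]] &
          de_results$cluster_id == lm$marker_type[i])
      }, TRUE)
      de_recovery <- mean(found)
    }
  }

  matches <- data.frame(
    locus_id = lm$locus_id,
    annotated = lm$annotated,
    marker_type = lm$marker_type,
    tar_id = ifelse(is.na(best), NA_character_, m$id[best]),
    tar_label = ifelse(is.na(best), NA_character_, m$label[best]),
    recovered = seq_along(loci) %in% matched_locus
  )

  list(
    recall = recall, precision = precision,
    holdout_utar_fraction = holdout_utar, de_recovery = de_recovery,
    n_tars = length(tars), n_loci = length(loci), matches = matches
  )
}
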