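# In-memory and on-disk alignment fixtures shared across the suite.

# Build a GAlignments directly (no file round trip) from a record table.
make_aln <- function(chrom, pos, strand, cigar = NULL, mapq = 255,
                     qname = NULL, cb = NULL, ub = NULL,
                     seqlengths = c(chr1 = 10000, chr2 = 10000)) {
  n <- length(pos)
  if (is.null(cigar)) cigar <- rep("90M", n)
  if (is.null(qname)) qname <- sprintf("r%04d", seq_len(n))
  chrom <- rep_len(chrom, n)
  strand <- rep_len(strand, n)
  mapq <- rep_len(mapq, n)
  aln <- GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle(factor(chrom, levels = names(seqlengths))),
    pos = as.integer(pos),
    cigar = rep_len(cigar, n),
    strand = S4Vectors::Rle(factor(strand, levels = c("+", "-", "*"))),
    seqlengths = seqlengths
  )
  S4Vectors::mcols(aln) <- S4Vectors::DataFrame(
    qname = qname, flag = ifelse(strand == "+", 0L, 16L),
    mapq = as.integer(mapq),
    CB = if (is.null(cb)) NA_character_ else rep_len(cb, n),
    UB = if (is.null(ub)) NA_character_ else rep_len(ub, n)
  )
  aln
}

gr <- function(chrom, start, end, strand = "+", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand, ...)
}

# Minimal refFlat-style annotation data frame from transcript spans
# (0-based half-open tx coordinates).
make_annot <- function(chrom, tx_start, tx_end, strand, gene = NULL) {
  n <- length(tx_start)
  if (is.null(gene)) gene <- sprintf("gene_%d", seq_len(n))
  data.frame(
    gene_name = gene, transcript_name = paste0(gene, ".1"),
    chrom = rep_len(chrom, n), strand = rep_len(strand, n),
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    cds_start = as.integer(tx_start), cds_end = as.integer(tx_end),
    exon_count = 1L,
    exon_starts = I(as.list(as.integer(tx_start))),
    exon_ends = I(as.list(as.integer(tx_end)))
  )
}

# Write a paired-end SAM (one cell's Smart-seq2 alignments) and return the
# path. Each fragment is (chrom, start of mate1, start of mate2, strand of
# the fragment); mates are read_len long.
make_paired_sam <- function(frags, read_len = 50,
                            seqlengths = c(chr1 = 10000),
                            file = tempfile(fileext = ".sam")) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), seqlengths)
  )
  rows <- character(0)
  for (i in seq_len(nrow(frags))) {
    f <- frags[i, ]
    p1 <- min(f$pos1, f$pos2)
    p2 <- max(f$pos1, f$pos2)
    tlen <- p2 + read_len - p1
    if (f$strand == "+") {
      fl1 <- 99L; fl2 <- 147L # mate1 forward at p1, mate2 reverse at p2
    } else {
      fl1 <- 83L; fl2 <- 163L # mate1 reverse at p2, mate2 forward at p1
    }
    q <- sprintf("frag%03d", i)
    cig <- paste0(read_len, "M")
    if (f$strand == "+") {
      rows <- c(
        rows,
        sprintf("%s\t%d\t%s\t%d\t255\t%s\t=\t%d\t%d\t*\t*", q, fl1, f$chrom, p1, cig, p2, tlen),
        sprintf("%s\t%d\t%s\t%d\t255\t%s\t=\t%d\t%d\t*\t*", q, fl2, f$chrom, p2, cig, p1, -tlen)
      )
    } else {
      rows <- c(
        rows,
        sprintf("%s\t%d\t%s\t%d\t255\t%s\t=\t%d\t%d\t*\t*", q, fl1, f$chrom, p2, cig, p1, -tlen),
        sprintf("%s\t%d\t%s\t%d\t255\t%s\t=\t%d\t%d\t*\t*", q, fl2, f$chrom, p1, cig, p2, tlen)
      )
    }
  }
  # coordinate sort body by pos
  pos <- as.integer(sub("^[^\t]*\t[^\t]*\t[^\t]*\t([0-9]+).*", "\\1", rows))
  writeLines(c(header, rows[order(pos)]), file)
  file
}

# The default-scale fixture and its TAR calls are expensive; build once per
# suite run and share.
.fixture_env <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_env$sim)) {
    sim <- simulate_tar_data(sim_config(), file.path(tempdir(), "tarseq_default_fixture"))
    aln <- read_alignments(sim$bam)
    annot <- read_refflat(sim$annotation_partial)
    res <- call_tars(aln, annot)
    .fixture_env$sim <- sim
    .fixture_env$aln <- aln
    .fixture_env$annot <- annot
    .fixture_env$res <- res
  }
  list(
    sim = .fixture_env$sim, aln = .fixture_env$aln,
    annot = .fixture_env$annot, res = .fixture_env$res
  )
}
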