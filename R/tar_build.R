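#' Merge nearby intervals, strand-specifically
#'
#' Unions same-chromosome, same-strand intervals separated by at most
#' \code{max_gap} base pairs (the semantics of \code{bedtools merge -s -d
#' 500}). Opposite strands are never merged. Idempotent; output is sorted.
#'
#' @param intervals A stranded \code{GRanges}.
#' @param max_gap Maximum gap in bp to bridge (default 500).
#' @return A sorted \code{GRanges}.
#' @export
merge_intervals <- function(intervals, max_gap = 500) {
  stopifnot(max_gap >= 0)
  sort(GenomicRanges::reduce(intervals,
    min.gapwidth = max_gap + 1L,
    ignore.strand = FALSE
  ))
}

#' Strand-specific read coverage of intervals
#'
#' Counts, per interval, the reads on the same strand whose aligned blocks
#' overlap the interval by at least one base (the semantics of
#' \code{bedtools coverage -s -counts -split}: the gap a spliced read spans
#' does not count, and a read may count toward several intervals).
#'
#' @param intervals A stranded \code{GRanges}.
#' @param alignments A \code{GAlignments} object.
#' @return Integer vector of read counts, parallel to \code{intervals}.
#' @export
interval_coverage <- function(intervals, alignments) {
  if (!length(intervals)) {
    return(integer(0))
  }
  blocks <- GenomicAlignments::grglist(alignments) # one GRanges per read
  GenomicRanges::countOverlaps(intervals, blocks, ignore.strand = FALSE)
}

#' Read-depth threshold for keeping TARs
#'
#' Scales the minimum read support of a transcribed region with sequencing
#' depth: one read per ten million uniquely mapped reads in the combined
#' alignment file, floored and clamped to at least 1.
#'
#' @param total_unique_reads Total uniquely mapped reads (MAPQ-filtered).
#' @return An integer threshold \code{n >= 1}.
#' @export
compute_threshold <- function(total_unique_reads) {
  stopifnot(total_unique_reads >= 0)
  max(1L, as.integer(floor(total_unique_reads / 1e7)))
}

#' Filter intervals by read coverage
#'
#' @param intervals A \code{GRanges}.
#' @param counts Read counts parallel to \code{intervals}.
#' @param n Minimum count to keep (inclusive).
#' @return The surviving intervals, original order preserved, with the
#'   counts attached as metadata column \code{total_reads}.
#' @export
filter_by_coverage <- function(intervals, counts, n) {
  if (length(intervals) != length(counts)) {
    stop(
      "length mismatch: ", length(intervals), " intervals vs ",
      length(counts), " counts"
    )
  }
  keep <- counts >= n
  out <- intervals[keep]
  S4Vectors::mcols(out)$total_reads <- as.integer(counts[keep])
  out
}

#' Read a refFlat gene annotation
#'
#' Parses the 11-column tab-separated refFlat format (geneName, name,
#' chrom, strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds; transcript coordinates 0-based half-open).
#'
#' @param file Path to a refFlat file.
#' @return A data frame with one row per transcript; \code{exon_starts}
#'   and \code{exon_ends} are list columns of integer vectors.
#' @export
read_refflat <- function(file) {
  cols <- c(
    "gene_name", "transcript_name", "chrom", "strand", "tx_start",
    "tx_end", "cds_start", "cds_end", "exon_count", "exon_starts",
    "exon_ends"
  )
  df <- utils::read.table(file,
    sep = "\t", header = FALSE, quote = "",
    col.names = cols, colClasses = "character"
  )
  for (f in c("tx_start", "tx_end", "cds_start", "cds_end", "exon_count")) {
    df[[f]] <- as.integer(df[[f]])
  }
  split_ints <- function(s) {
    lapply(strsplit(s, ","), function(v) as.integer(v[nzchar(v)]))
  }
  df$exon_starts <- split_ints(df$exon_starts)
  df$exon_ends <- split_ints(df$exon_ends)
  df
}

#' Write a refFlat gene annotation
#'
#' @param annotation A data frame in the layout of
#'   \code{\link{read_refflat}}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_refflat <- function(annotation, file) {
  join <- function(l) vapply(l, function(v) paste0(paste(v, collapse = ","), ","), "")
  out <- data.frame(
    annotation$gene_name, annotation$transcript_name, annotation$chrom,
    annotation$strand, annotation$tx_start, annotation$tx_end,
    annotation$cds_start, annotation$cds_end, annotation$exon_count,
    join(annotation$exon_starts), join(annotation$exon_ends)
  )
  utils::write.table(out, file,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(file)
}

#' Transcript spans of an annotation as GRanges
#'
#' @param annotation A refFlat-style data frame.
#' @return A \code{GRanges} of [txStart, txEnd) spans (converted to the
#'   1-based closed convention of \code{GRanges}).
#' @export
transcript_spans <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(
      start = annotation$tx_start + 1L,
      end = annotation$tx_end
    ),
    strand = annotation$strand,
    gene_name = annotation$gene_name,
    transcript_name = annotation$transcript_name
  )
}

#' Label TARs as annotated (aTAR) or unannotated (uTAR)
#'
#' Classifies each merged, coverage-filtered interval against transcript
#' spans (transcription start to stop; exon structure is ignored). Any
#' overlap of at least one base counts.
#'
#' In the default \code{strand_agnostic} mode, overlap with a transcript on
#' either strand makes a TAR an aTAR — antisense overlap included. In
#' \code{directional} mode only same-strand overlap does; a TAR overlapping
#' annotation solely on the opposite strand becomes a uTAR with direction
#' flag \code{antisense-overlap}. The direction flag (\code{sense-overlap},
#' \code{antisense-overlap} or \code{no-overlap}) is recorded in both
#' modes.
#'
#' @param intervals A stranded \code{GRanges} (optionally carrying a
#'   \code{total_reads} metadata column from
#'   \code{\link{filter_by_coverage}}).
#' @param annotation A refFlat-style data frame (see
#'   \code{\link{read_refflat}}) or a \code{GRanges} of transcript spans.
#' @param mode \code{"strand_agnostic"} (default) or \code{"directional"}.
#' @return A \code{GRanges} of TAR features sorted by (chrom, start,
#'   strand), with metadata columns \code{id} (\code{TAR_i}), \code{label}
#'   (\code{"aTAR"}/\code{"uTAR"}), \code{direction_flag} and
#'   \code{total_reads}.
#' @export
label_tars <- function(intervals, annotation,
                       mode = c("strand_agnostic", "directional")) {
  mode <- match.arg(mode)
  tx <- if (methods::is(annotation, "GRanges")) annotation else transcript_spans(annotation)

  tars <- sort(intervals, ignore.strand = FALSE)
  missing_chr <- setdiff(
    as.character(unique(GenomicRanges::seqnames(tars))),
    as.character(unique(GenomicRanges::seqnames(tx)))
  )
  if (length(missing_chr)) {
    warning(
      "chromosome(s) absent from the annotation, treated as no-overlap: ",
      paste(missing_chr, collapse = ", ")
    )
  }

  # suppressWarnings: countOverlaps complains when the two objects carry
  # different seqlevels, which the explicit warning above already covers
  sense <- suppressWarnings(
    GenomicRanges::countOverlaps(tars, tx, ignore.strand = FALSE) > 0
  )
  any_ov <- suppressWarnings(
    GenomicRanges::countOverlaps(tars, tx, ignore.strand = TRUE) > 0
  )
  direction <- ifelse(sense, "sense-overlap",
    ifelse(any_ov, "antisense-overlap", "no-overlap")
  )
  label <- if (mode == "strand_agnostic") {
    ifelse(any_ov, "aTAR", "uTAR")
  } else {
    ifelse(sense, "aTAR", "uTAR")
  }

  tr <- S4Vectors::mcols(tars)$total_reads
  if (is.null(tr)) tr <- NA_integer_
  S4Vectors::mcols(tars) <- S4Vectors::DataFrame(
    id = paste0("TAR_", seq_along(tars)),
    label = label,
    direction_flag = direction,
    total_reads = tr
  )
  tars
}

.dir_code <- c("sense-overlap" = "s", "antisense-overlap" = "a", "no-overlap" = "n")

#' Write labeled TARs to BED, GTF or refFlat
#'
#' The feature name encodes the TAR id, label and direction flag (e.g.
#' \code{TAR_1_uTAR_n}); BED uses 0-based half-open coordinates, GTF
#' 1-based closed. GTF rows carry \code{tar_id}, \code{tar_label},
#' \code{tar_direction} and \code{reads} attributes so that
#' \code{\link{read_tar_annotation}} can reconstruct the feature list.
#'
#' @param tars A labeled \code{GRanges} from \code{\link{label_tars}}.
#' @param file Output path.
#' @param format \code{"BED"}, \code{"GTF"} or \code{"refFlat"}.
#' @return The path, invisibly.
#' @export
write_tar_annotation <- function(tars, file, format = c("BED", "GTF", "refFlat")) {
  format <- match.arg(format)
  m <- S4Vectors::mcols(tars)
  name <- paste(m$id, m$label, .dir_code[m$direction_flag], sep = "_")
  chrom <- as.character(GenomicRanges::seqnames(tars))
  strand <- as.character(GenomicRanges::strand(tars))
  score <- ifelse(is.na(m$total_reads), ".", as.character(m$total_reads))

  lines <- switch(format,
    BED = if (length(tars)) {
      paste(chrom, GenomicRanges::start(tars) - 1L, GenomicRanges::end(tars),
        name, score, strand,
        sep = "\t"
      )
    } else {
      character(0)
    },
    GTF = if (length(tars)) {
      attrs <- sprintf(
        'gene_id "%s"; transcript_id "%s"; tar_id "%s"; tar_label "%s"; tar_direction "%s"; reads "%s";',
        name, name, m$id, m$label, m$direction_flag, score
      )
      paste(chrom, "tarseq", "exon", GenomicRanges::start(tars),
        GenomicRanges::end(tars), score, strand, ".", attrs,
        sep = "\t"
      )
    } else {
      character(0)
    },
    refFlat = if (length(tars)) {
      s0 <- GenomicRanges::start(tars) - 1L
      e0 <- GenomicRanges::end(tars)
      paste(name, m$id, chrom, strand, s0, e0, s0, e0, 1L,
        paste0(s0, ","), paste0(e0, ","),
        sep = "\t"
      )
    } else {
      character(0)
    }
  )
  ok <- tryCatch(
    {
      writeLines(lines, file)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) stop("cannot write TAR annotation to: ", file)
  invisible(file)
}

#' Read labeled TARs back from BED or GTF
#'
#' @param file Path written by \code{\link{write_tar_annotation}}.
#' @param format \code{"BED"} or \code{"GTF"}.
#' @return A labeled \code{GRanges} in the layout of
#'   \code{\link{label_tars}}.
#' @export
read_tar_annotation <- function(file, format = c("BED", "GTF")) {
  format <- match.arg(format)
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  empty <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
    id = character(0), label = character(0),
    direction_flag = character(0), total_reads = integer(0)
  )
  if (!length(lines)) {
    return(empty)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "BED") {
    chrom <- vapply(f, `[`, "", 1)
    start <- as.integer(vapply(f, `[`, "", 2)) + 1L
    end <- as.integer(vapply(f, `[`, "", 3))
    name <- vapply(f, `[`, "", 4)
    score <- vapply(f, `[`, "", 5)
    strand <- vapply(f, `[`, "", 6)
  } else {
    chrom <- vapply(f, `[`, "", 1)
    start <- as.integer(vapply(f, `[`, "", 4))
    end <- as.integer(vapply(f, `[`, "", 5))
    strand <- vapply(f, `[`, "", 7)
    attr9 <- vapply(f, `[`, "", 9)
    get_attr <- function(key) {
      m <- regmatches(attr9, regexpr(sprintf('%s "[^"]*"', key), attr9))
      sub(sprintf('%s "([^"]*)"', key), "\\1", m)
    }
    name <- paste(get_attr("tar_id"), get_attr("tar_label"),
      .dir_code[get_attr("tar_direction")],
      sep = "_"
    )
    score <- get_attr("reads")
  }
  parts <- strsplit(name, "_", fixed = TRUE)
  id <- vapply(parts, function(p) paste(p[1], p[2], sep = "_"), "")
  label <- vapply(parts, `[`, "", 3)
  dircode <- vapply(parts, `[`, "", 4)
  direction <- names(.dir_code)[match(dircode, .dir_code)]
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    id = id, label = label, direction_flag = direction,
    total_reads = suppressWarnings(as.integer(score))
  )
  gr
}

#' Call TARs from an alignment file end to end
#'
#' Convenience wrapper running the full segmentation pipeline: windowed
#' binning per strand, joint Baum-Welch fitting across all tracks, Viterbi
#' decoding, strand-specific merging of transcribed intervals, read
#' coverage, depth thresholding and aTAR/uTAR labeling.
#'
#' @param alignments A \code{GAlignments} or BAM/SAM path.
#' @param annotation A refFlat-style data frame or transcript-span
#'   \code{GRanges}.
#' @param window_size HMM window width in bp (default 50).
#' @param mapq_threshold Unique-mapping MAPQ cutoff (default 255).
#' @param merge_gap Merge gap in bp (default 500).
#' @param mode Labeling mode, see \code{\link{label_tars}}.
#' @param subsample Optional fraction in (0, 1] of reads to keep before
#'   segmentation (binning and HMM only; coverage, thresholding and
#'   counting still see all reads).
#' @param seed Seed for the subsampling draw.
#' @param ... Passed to \code{\link{fit_baum_welch}}.
#' @return A list with \code{tars} (labeled \code{GRanges}), \code{hmm}
#'   (the \code{tar_hmm} fit), \code{threshold} and
#'   \code{total_unique_reads}.
#' @export
call_tars <- function(alignments, annotation, window_size = 50,
                      mapq_threshold = 255, merge_gap = 500,
                      mode = "strand_agnostic", subsample = NULL,
                      seed = 1L, ...) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  total <- count_unique_mapped(alignments, mapq_threshold)
  seg_aln <- alignments
  if (!is.null(subsample) && subsample < 1) {
    seg_aln <- subsample_alignments(alignments, subsample, seed = seed)
  }
  tracks <- bin_coverage(seg_aln, window_size, mapq_threshold)
  hmm <- fit_baum_welch(tracks, ...)
  lens <- GenomeInfoDb::seqlengths(alignments)
  paths <- lapply(tracks, decode, params = hmm)
  iv <- lapply(paths, states_to_intervals, seqlengths = lens)
  iv <- suppressWarnings(do.call(c, unname(iv)))
  merged <- merge_intervals(iv, max_gap = merge_gap)
  counts <- interval_coverage(merged, alignments)
  n <- compute_threshold(total)
  kept <- filter_by_coverage(merged, counts, n)
  tars <- label_tars(kept, annotation, mode = mode)
  list(
    tars = tars, hmm = hmm, threshold = n,
    total_unique_reads = total
  )
}
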