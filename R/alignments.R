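#' Read alignments for TAR analysis
#'
#' Loads a SAM/BAM file into a \code{GAlignments} object carrying the fields
#' the TAR pipeline needs: mapping quality, flags, read names and (when
#' present) the 10X-style cell-barcode (\code{CB}) and UMI (\code{UB}) tags.
#' Secondary, supplementary and unmapped records are always dropped, so every
#' retained record represents one read.
#'
#' @param file Path to a BAM file (or a SAM file, which is converted in a
#'   temporary directory first).
#' @param tags Character vector of BAM tags to load; defaults to the
#'   cell-barcode and UMI tags.
#' @return A \code{GAlignments} object with metadata columns \code{qname},
#'   \code{flag}, \code{mapq} and one column per requested tag.
#' @export
read_alignments <- function(file, tags = c("CB", "UB")) {
  if (!file.exists(file)) {
    stop("alignment file not found: ", file)
  }
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    file <- Rsamtools::asBam(file,
      destination = tempfile("aln"),
      overwrite = TRUE, indexDestination = FALSE
    )
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "mapq"),
    tag = tags
  )
  aln <- tryCatch(
    GenomicAlignments::readGAlignments(file, param = param),
    error = function(e) {
      stop("failed to read alignment file '", file, "': ", conditionMessage(e))
    }
  )
  aln
}

#' Count uniquely mapped reads
#'
#' Counts primary alignment records whose mapping quality is at or above a
#' threshold. With the conventional MAPQ threshold of 255 this reproduces
#' \code{samtools view -c -q 255} on aligners that reserve 255 for unique
#' alignments (e.g. STAR). The result drives the TAR read-depth threshold
#' (see \code{\link{compute_threshold}}).
#'
#' @param alignments A \code{GAlignments} object from
#'   \code{\link{read_alignments}}, or a path to a BAM/SAM file.
#' @param mapq_threshold Minimum mapping quality (default 255).
#' @return A single non-negative integer.
#' @export
count_unique_mapped <- function(alignments, mapq_threshold = 255) {
  if (is.character(alignments)) {
    alignments <- read_alignments(alignments)
  }
  stopifnot(mapq_threshold >= 0)
  mq <- S4Vectors::mcols(alignments)$mapq
  if (is.null(mq)) {
    stop("alignments carry no 'mapq' metadata column")
  }
  sum(!is.na(mq) & mq >= mapq_threshold)
}

#' Randomly subsample alignments
#'
#' Retains each read independently with probability \code{fraction}. The
#' draw is keyed on read name, so the two mates of a paired-end read are
#' always kept or dropped together. Used to thin very deep combined
#' alignment files (e.g. keeping 5\% of reads) before HMM segmentation.
#'
#' @param alignments A \code{GAlignments} object.
#' @param fraction Retention probability in (0, 1].
#' @param seed Integer seed making the subsample reproducible.
#' @return A \code{GAlignments} object with the retained records, in the
#'   original order.
#' @export
subsample_alignments <- function(alignments, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
    fraction <= 0 || fraction > 1) {
    stop("'fraction' must be a single value in (0, 1]")
  }
  if (fraction == 1) {
    return(alignments)
  }
  qn <- S4Vectors::mcols(alignments)$qname
  if (is.null(qn)) {
    stop("alignments carry no 'qname' metadata column; ",
         "read names are needed to keep mates together")
  }
  keys <- unique(qn)
  u <- withr::with_seed(as.integer(seed), stats::runif(length(keys)))
  keep_key <- keys[u < fraction]
  alignments[qn %in% keep_key]
}

#' A strand-specific windowed count track
#'
#' Constructs the HMM observation sequence for one chromosome and strand:
#' read counts in fixed, non-overlapping windows of \code{window_size} base
#' pairs. Window \code{i} (1-based) covers the 0-based half-open genomic
#' interval \code{[(i-1)*w, i*w)}.
#'
#' @param chrom Chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param window_size Window width in bp.
#' @param counts Non-negative integer vector, one entry per window.
#' @return An object of class \code{window_count_track}.
#' @export
window_count_track <- function(chrom, strand, window_size, counts) {
  stopifnot(strand %in% c("+", "-"), window_size >= 1, all(counts >= 0))
  structure(
    list(
      chrom = as.character(chrom), strand = strand,
      window_size = as.integer(window_size), counts = as.numeric(counts)
    ),
    class = "window_count_track"
  )
}

#' @export
print.window_count_track <- function(x, ...) {
  cat(sprintf(
    "<window_count_track> %s(%s)  %d windows x %d bp, %d reads\n",
    x$chrom, x$strand, length(x$counts), x$window_size, sum(x$counts)
  ))
  invisible(x)
}

#' Bin read coverage into fixed windows
#'
#' Scans the genome with non-overlapping windows (default 50 bp) and counts,
#' per chromosome and strand, the reads whose 5'-most aligned base falls in
#' each window. For minus-strand reads the 5' end is the rightmost aligned
#' base. Each read passing the MAPQ filter increments exactly one window, so
#' window totals are conserved:
#' \code{sum over tracks == count_unique_mapped(alignments, mapq_threshold)}.
#'
#' @param alignments A \code{GAlignments} object; its header must carry
#'   chromosome lengths.
#' @param window_size Window width in bp (default 50).
#' @param mapq_threshold Minimum mapping quality (default 255).
#' @return A named list of \code{\link{window_count_track}} objects, one per
#'   chromosome x strand, named \code{"chrom:strand"}. Every chromosome in
#'   the header gets both strand tracks, even if empty.
#' @export
bin_coverage <- function(alignments, window_size = 50, mapq_threshold = 255) {
  stopifnot(window_size >= 1)
  mq <- S4Vectors::mcols(alignments)$mapq
  keep <- !is.na(mq) & mq >= mapq_threshold
  aln <- alignments[keep]

  lens <- GenomeInfoDb::seqlengths(aln)
  if (any(is.na(lens))) {
    stop(
      "chromosome length unknown for: ",
      paste(names(lens)[is.na(lens)], collapse = ", ")
    )
  }
  chroms <- names(lens)

  chr <- as.character(GenomicAlignments::seqnames(aln))
  std <- as.character(GenomicAlignments::strand(aln))
  # 0-based 5' position: leftmost aligned base on +, rightmost on -
  pos0 <- ifelse(std == "+",
    GenomicAlignments::start(aln) - 1L,
    GenomicAlignments::end(aln) - 1L
  )
  win <- pos0 %/% window_size + 1L

  tracks <- list()
  for (cm in chroms) {
    nwin <- as.integer(ceiling(lens[[cm]] / window_size))
    for (st in c("+", "-")) {
      sel <- chr == cm & std == st
      counts <- tabulate(win[sel], nbins = nwin)
      tracks[[paste0(cm, ":", st)]] <-
        window_count_track(cm, st, window_size, counts)
    }
  }
  tracks
}

#' Write a count track as bedGraph
#'
#' Dumps one windowed count track in bedGraph format (0-based half-open)
#' for inspection in a genome browser; zero windows are omitted.
#'
#' @param track A \code{\link{window_count_track}}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, file) {
  w <- track$window_size
  idx <- which(track$counts > 0)
  df <- data.frame(
    chrom = track$chrom,
    start = (idx - 1L) * w,
    end = idx * w,
    value = track$counts[idx]
  )
  utils::write.table(df, file,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(file)
}
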