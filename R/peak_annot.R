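#' Per-base coverage profile of a uTAR
#'
#' Depth at every base of the interval, counting aligned blocks of reads
#' on the same strand (spliced gaps contribute nothing).
#'
#' @param utar A length-1 stranded \code{GRanges} (e.g. one row of a
#'   \code{\link{label_tars}} result).
#' @param alignments A \code{GAlignments} object.
#' @param mapq_threshold Minimum mapping quality (default 255).
#' @return An object of class \code{coverage_profile}: list with
#'   \code{utar_id}, \code{chrom}, \code{start} (1-based), \code{strand}
#'   and \code{depth} (numeric vector, one entry per base).
#' @export
coverage_profile <- function(utar, alignments, mapq_threshold = 255) {
  stopifnot(length(utar) == 1)
  m <- S4Vectors::mcols(alignments)
  keep <- !is.na(m$mapq) & m$mapq >= mapq_threshold &
    as.character(GenomicAlignments::strand(alignments)) ==
      as.character(GenomicRanges::strand(utar))
  blocks <- unlist(GenomicAlignments::grglist(alignments[keep]))
  cov <- GenomicRanges::coverage(blocks)
  chrom <- as.character(GenomicRanges::seqnames(utar))
  s <- GenomicRanges::start(utar)
  e <- GenomicRanges::end(utar)
  depth <- if (chrom %in% names(cov)) {
    v <- cov[[chrom]]
    if (length(v) < e) v <- c(v, S4Vectors::Rle(0L, e - length(v)))
    as.numeric(v[s:e])
  } else {
    numeric(e - s + 1)
  }
  id <- S4Vectors::mcols(utar)$id
  structure(
    list(
      utar_id = if (is.null(id)) NA_character_ else id,
      chrom = chrom, start = s,
      strand = as.character(GenomicRanges::strand(utar)),
      depth = depth
    ),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf(
    "<coverage_profile> %s %s:%d-%d(%s)  max depth %.0f\n",
    x$utar_id, x$chrom, x$start, x$start + length(x$depth) - 1L,
    x$strand, max(x$depth)
  ))
  invisible(x)
}

#' LOESS-smooth a coverage profile
#'
#' Locally weighted linear regression (tricube weights, degree 1, no
#' robustness iterations) of depth against position, evaluated at every
#' base and clipped at zero from below. Degree-1 LOESS reproduces constant
#' and linear signals exactly.
#'
#' @param profile A \code{coverage_profile} or bare numeric depth vector
#'   of length >= 10.
#' @param span LOESS span in (0, 1] (default 0.25); \code{span * length}
#'   must cover at least 3 points.
#' @return A numeric vector of smoothed depths, same length as the input.
#' @export
loess_smooth <- function(profile, span = 0.25) {
  y <- if (inherits(profile, "coverage_profile")) profile$depth else as.numeric(profile)
  n <- length(y)
  if (n < 10) {
    stop(
      "profile too short for LOESS (", n, " < 10 bases); ",
      "use the raw depth peak instead"
    )
  }
  stopifnot(span > 0, span <= 1)
  if (span * n < 3) {
    stop("span * length = ", span * n, " < 3 points; increase the span")
  }
  x <- seq_len(n)
  surface <- if (n <= 5000) "direct" else "interpolate"
  fit <- stats::loess(y ~ x,
    span = span, degree = 1, family = "gaussian",
    control = stats::loess.control(surface = surface)
  )
  unname(pmax(stats::predict(fit, newdata = data.frame(x = x)), 0))
}

#' Full width at half maximum of the largest peak
#'
#' Locates the global maximum of a smoothed signal (leftmost position on a
#' plateau) and walks outward to the nearest positions on each side where
#' the signal falls to half the maximum, clamping to the signal ends when
#' it never does. Offsets are 0-based within the signal; when the uTAR
#' interval is supplied the peak is also mapped back to genome
#' coordinates.
#'
#' @param smoothed Numeric signal (e.g. from \code{\link{loess_smooth}})
#'   with a positive maximum.
#' @param utar Optional length-1 \code{GRanges} the signal spans.
#' @return A list with \code{left} and \code{right} (0-based inclusive
#'   offsets), \code{peak} (0-based offset of the maximum),
#'   \code{half_max}, and, when \code{utar} is given, \code{interval} (a
#'   \code{GRanges} of the peak region).
#' @export
fwhm_peak <- function(smoothed, utar = NULL) {
  s <- as.numeric(smoothed)
  mx <- max(s)
  if (!is.finite(mx) || mx <= 0) stop("no peak: signal has no positive maximum")
  p <- which.max(s) # leftmost maximum
  half <- mx / 2
  left_cand <- which(s[seq_len(p)] <= half + 1e-12)
  left <- if (length(left_cand)) max(left_cand) else 1L
  right_cand <- which(s[p:length(s)] <= half + 1e-12)
  right <- if (length(right_cand)) p + min(right_cand) - 1L else length(s)
  out <- list(
    left = left - 1L, right = right - 1L, peak = p - 1L,
    half_max = half
  )
  if (!is.null(utar)) {
    stopifnot(length(utar) == 1)
    g0 <- GenomicRanges::start(utar)
    out$interval <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(utar),
      ranges = IRanges::IRanges(start = g0 + out$left, end = g0 + out$right),
      strand = GenomicRanges::strand(utar)
    )
  }
  out
}

#' Extract the genomic sequence of a peak interval
#'
#' Returns the plus-strand genomic sequence of the interval, uppercase,
#' regardless of the uTAR's strand (downstream homology search scans both
#' strands). The FASTA is indexed on first use.
#'
#' @param fasta Path to the genome FASTA.
#' @param interval A length-1 \code{GRanges} within the chromosome bounds.
#' @return A single character string.
#' @export
extract_peak_sequence <- function(fasta, interval) {
  stopifnot(length(interval) == 1)
  if (GenomicRanges::width(interval) < 1) {
    stop("empty interval: nothing to extract")
  }
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  fa <- Rsamtools::FaFile(fasta)
  lens <- Rsamtools::seqinfo(fa)
  chrom <- as.character(GenomicRanges::seqnames(interval))
  if (!chrom %in% GenomeInfoDb::seqnames(lens)) {
    stop("chromosome '", chrom, "' not in FASTA")
  }
  clen <- GenomeInfoDb::seqlengths(lens)[[chrom]]
  if (GenomicRanges::start(interval) < 1 || GenomicRanges::end(interval) > clen) {
    stop(sprintf(
      "interval %d-%d out of bounds for %s (length %d)",
      GenomicRanges::start(interval), GenomicRanges::end(interval),
      chrom, clen
    ))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    GenomicRanges::start(interval), GenomicRanges::end(interval)
  ))
  toupper(as.character(Rsamtools::getSeq(fa, q)[[1]]))
}

.blast6_cols <- c(
  "query_id", "subject_id", "percent_identity", "alignment_length",
  "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
  "e_value", "bit_score"
)

#' Read tabular homology hits (BLAST outfmt 6)
#'
#' Parses the standard 12-column tabular output, with an optional 13th
#' subject-title column.
#'
#' @param file Path to the TSV.
#' @return A data frame with typed columns; \code{subject_title} equals
#'   \code{subject_id} when no title column is present.
#' @export
read_blast_hits <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), 13), c(.blast6_cols, "subject_title")
    ))
    return(df)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  bad <- which(nf < 12)
  if (length(bad)) {
    stop(
      "malformed homology hit at line ", bad[1], ": expected >= 12 ",
      "tab-separated fields, got ", nf[bad[1]]
    )
  }
  df <- as.data.frame(do.call(rbind, lapply(f, `[`, 1:12)),
    stringsAsFactors = FALSE
  )
  names(df) <- .blast6_cols
  for (col in c(
    "percent_identity", "alignment_length", "mismatches", "gap_opens",
    "q_start", "q_end", "s_start", "s_end", "e_value", "bit_score"
  )) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$subject_title <- ifelse(nf >= 13, vapply(f, function(v) {
    if (length(v) >= 13) v[13] else NA_character_
  }, ""), df$subject_id)
  df
}

#' Label a uTAR from filtered homology hits
#'
#' Discards hits above the e-value cutoff or below the bit-score cutoff
#' and returns the subject title of the best survivor (highest bit score;
#' ties broken by lowest e-value, then input order). No survivor means the
#' uTAR stays \code{"unknown"}.
#'
#' @param hits A data frame from \code{\link{read_blast_hits}} (or with
#'   compatible \code{e_value}, \code{bit_score}, \code{subject_title}
#'   columns).
#' @param max_evalue Maximum e-value (default 0.01).
#' @param min_bitscore Minimum bit score (default 50).
#' @return A single character label.
#' @export
label_from_hits <- function(hits, max_evalue = 0.01, min_bitscore = 50) {
  if (is.null(hits) || !nrow(hits)) {
    return("unknown")
  }
  ok <- hits$e_value <= max_evalue & hits$bit_score >= min_bitscore
  surv <- hits[ok, , drop = FALSE]
  if (!nrow(surv)) {
    return("unknown")
  }
  ord <- order(-surv$bit_score, surv$e_value)
  title <- surv$subject_title
  if (is.null(title)) title <- surv$subject_id
  title[ord[1]]
}

#' Annotate differential uTAR peaks
#'
#' Runs the full peak workflow for each differential uTAR: per-base
#' coverage, LOESS smoothing, FWHM peak extraction, peak sequence lookup
#' and (when a hit table is supplied) homology labeling. uTARs too short
#' or too shallow for smoothing are labeled from their raw maximum.
#'
#' @param tars Labeled \code{GRanges} (only rows whose ids appear in
#'   \code{de_results} and whose label is \code{"uTAR"} are processed).
#' @param de_results A \code{\link{wilcoxon_de}} data frame.
#' @param alignments A \code{GAlignments}.
#' @param fasta Genome FASTA path.
#' @param hits Optional homology-hit data frame; its \code{query_id}
#'   column is matched against uTAR ids.
#' @param span LOESS span (default 0.25).
#' @param max_evalue,min_bitscore Hit filters (defaults 0.01 / 50).
#' @return A data frame with one row per differential uTAR: id, peak
#'   coordinates, peak width, sequence and label.
#' @export
annotate_utar_peaks <- function(tars, de_results, alignments, fasta,
                                hits = NULL, span = 0.25,
                                max_evalue = 0.01, min_bitscore = 50) {
  m <- S4Vectors::mcols(tars)
  sel <- which(m$label == "uTAR" & m$id %in% de_results$feature_id)
  rows <- lapply(sel, function(i) {
    u <- tars[i]
    prof <- coverage_profile(u, alignments)
    sm <- tryCatch(loess_smooth(prof, span), error = function(e) prof$depth)
    pk <- fwhm_peak(sm, u)
    seqs <- extract_peak_sequence(fasta, pk$interval)
    lbl <- if (!is.null(hits)) {
      label_from_hits(
        hits[hits$query_id == m$id[i], , drop = FALSE],
        max_evalue, min_bitscore
      )
    } else {
      "unknown"
    }
    data.frame(
      utar_id = m$id[i],
      chrom = as.character(GenomicRanges::seqnames(u)),
      peak_start = GenomicRanges::start(pk$interval),
      peak_end = GenomicRanges::end(pk$interval),
      strand = as.character(GenomicRanges::strand(u)),
      peak_width = GenomicRanges::width(pk$interval),
      sequence = seqs,
      label = lbl
    )
  })
  if (!length(rows)) {
    return(data.frame(
      utar_id = character(0), chrom = character(0),
      peak_start = integer(0), peak_end = integer(0), strand = character(0),
      peak_width = integer(0), sequence = character(0), label = character(0)
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
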