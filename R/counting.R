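#' Cells-by-features count matrix
#'
#' Container for the sparse UMI-deduplicated expression matrix: rows are
#' cell barcodes, columns are feature ids (genes, aTARs or uTARs), and each
#' feature carries a class label.
#'
#' @param counts A base or \pkg{Matrix} matrix, cells in rows, features in
#'   columns, with barcode rownames and feature-id colnames.
#' @param feature_labels Character vector of labels (\code{"gene"},
#'   \code{"aTAR"}, \code{"uTAR"}, ...) parallel to the columns.
#' @return An object of class \code{cell_feature_matrix}: list with
#'   \code{counts} (a \code{dgCMatrix}), \code{barcodes} and
#'   \code{features} (data frame with \code{id}, \code{label}).
#' @export
cell_feature_matrix <- function(counts, feature_labels = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry barcode rownames and feature-id colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate barcodes")
  if (anyDuplicated(colnames(counts))) stop("duplicate feature ids")
  if (any(counts@x < 0)) stop("negative counts")
  if (is.null(feature_labels)) feature_labels <- rep("feature", ncol(counts))
  stopifnot(length(feature_labels) == ncol(counts))
  structure(
    list(
      counts = counts,
      barcodes = rownames(counts),
      features = data.frame(
        id = colnames(counts),
        label = as.character(feature_labels)
      )
    ),
    class = "cell_feature_matrix"
  )
}

#' @export
print.cell_feature_matrix <- function(x, ...) {
  tab <- table(x$features$label)
  cat(sprintf(
    "<cell_feature_matrix> %d cells x %d features (%s); %.0f total counts\n",
    nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    sum(x$counts)
  ))
  invisible(x)
}

#' @export
dim.cell_feature_matrix <- function(x) dim(x$counts)

#' Subset a cell_feature_matrix
#'
#' @param x A \code{cell_feature_matrix}.
#' @param i,j Cell (row) and feature (column) indices.
#' @param ... Unused.
#' @param drop Ignored; dimensions are always kept.
#' @export
`[.cell_feature_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(j)) j <- match(j, x$features$id)
  cell_feature_matrix(x$counts[i, j, drop = FALSE], x$features$label[j])
}

.feature_granges <- function(features) {
  if (methods::is(features, "GRanges")) {
    ids <- S4Vectors::mcols(features)$id
    if (is.null(ids)) ids <- paste0("feature_", seq_along(features))
    labels <- S4Vectors::mcols(features)$label
    if (is.null(labels)) labels <- rep("feature", length(features))
    return(list(gr = features, ids = ids, labels = labels))
  }
  stop("features must be a GRanges (e.g. the output of label_tars)")
}

#' Count reads or fragments per cell and feature
#'
#' Builds the sparse cells-by-features expression matrix from tagged
#' alignments.
#'
#' In \code{umi_10x} mode each record must carry a cell barcode (\code{CB})
#' and UMI (\code{UB}) tag; a (barcode, feature) pair gains one count per
#' distinct UMI among the reads overlapping the feature on the same strand
#' (exact-match UMI collapse; spliced reads overlap through their aligned
#' blocks). A read overlapping several features contributes to each.
#'
#' In \code{fragment_ss2} mode input is one alignment file per cell
#' (Smart-seq2 style): \code{alignments} is a named character vector of
#' BAM/SAM paths, names giving the cell ids. Each properly paired fragment
#' counts once per same-strand feature it overlaps; there is no UMI
#' deduplication. Fragment strand is taken from the first mate.
#'
#' @param alignments A \code{GAlignments} (umi_10x) or a named character
#'   vector of per-cell BAM/SAM paths (fragment_ss2).
#' @param features A \code{GRanges} with \code{id} and \code{label}
#'   metadata columns (e.g. from \code{\link{label_tars}}).
#' @param mode \code{"umi_10x"} or \code{"fragment_ss2"}.
#' @param mapq_threshold Minimum mapping quality (default 255).
#' @return A \code{\link{cell_feature_matrix}}.
#' @export
count_features <- function(alignments, features,
                           mode = c("umi_10x", "fragment_ss2"),
                           mapq_threshold = 255) {
  mode <- match.arg(mode)
  fx <- .feature_granges(features)
  if (mode == "umi_10x") {
    .count_umi_10x(alignments, fx, mapq_threshold)
  } else {
    .count_fragment_ss2(alignments, fx, mapq_threshold)
  }
}

.count_umi_10x <- function(aln, fx, mapq_threshold) {
  m <- S4Vectors::mcols(aln)
  if (is.null(m$CB)) stop("umi_10x mode requires the cell-barcode tag 'CB'")
  if (is.null(m$UB)) stop("umi_10x mode requires the UMI tag 'UB'")
  keep <- !is.na(m$mapq) & m$mapq >= mapq_threshold &
    !is.na(m$CB) & !is.na(m$UB)
  aln <- aln[keep]
  m <- S4Vectors::mcols(aln)

  blocks <- GenomicAlignments::grglist(aln)
  hits <- GenomicRanges::findOverlaps(blocks, fx$gr, ignore.strand = FALSE)
  ri <- S4Vectors::queryHits(hits)
  fi <- S4Vectors::subjectHits(hits)

  barcodes <- sort(unique(m$CB))
  key <- paste(m$CB[ri], fi, m$UB[ri], sep = "\r")
  dedup <- !duplicated(key)
  ci <- match(m$CB[ri][dedup], barcodes)
  fj <- fi[dedup]

  counts <- Matrix::sparseMatrix(
    i = ci, j = fj, x = 1,
    dims = c(length(barcodes), length(fx$gr)),
    dimnames = list(barcodes, fx$ids)
  )
  cell_feature_matrix(counts, fx$labels)
}

.count_fragment_ss2 <- function(files, fx, mapq_threshold) {
  if (!is.character(files) || is.null(names(files)) || !all(nzchar(names(files)))) {
    stop("fragment_ss2 mode takes a named character vector of per-cell ",
         "alignment files (names = cell ids)")
  }
  rows <- lapply(names(files), function(cell) {
    f <- files[[cell]]
    if (grepl("\\.sam$", f, ignore.case = TRUE)) {
      f <- Rsamtools::asBam(f,
        destination = tempfile("ss2"),
        overwrite = TRUE, indexDestination = FALSE
      )
    }
    param <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(
        isProperPair = TRUE, isSecondaryAlignment = FALSE,
        isSupplementaryAlignment = FALSE
      ),
      what = "mapq"
    )
    pairs <- GenomicAlignments::readGAlignmentPairs(f,
      param = param, strandMode = 1
    )
    mq1 <- S4Vectors::mcols(GenomicAlignments::first(pairs))$mapq
    pairs <- pairs[!is.na(mq1) & mq1 >= mapq_threshold]
    frag <- GenomicRanges::granges(pairs) # fragment span, first-mate strand
    GenomicRanges::countOverlaps(fx$gr, frag, ignore.strand = FALSE)
  })
  counts <- do.call(rbind, rows)
  dimnames(counts) <- list(names(files), fx$ids)
  cell_feature_matrix(counts, fx$labels)
}

#' Per-cell fraction of reads in unannotated TARs
#'
#' For each cell, the fraction of its total counts carried by uTAR
#' features: how much of the cell's signal lies outside the gene
#' annotation.
#'
#' @param matrix A \code{\link{cell_feature_matrix}} whose features carry
#'   \code{"uTAR"} labels for unannotated TARs.
#' @return A named numeric vector in [0, 1], one entry per cell; cells
#'   with zero total counts get \code{NA}.
#' @export
utar_read_fraction <- function(matrix) {
  stopifnot(inherits(matrix, "cell_feature_matrix"))
  tot <- Matrix::rowSums(matrix$counts)
  u <- matrix$features$label == "uTAR"
  usum <- if (any(u)) Matrix::rowSums(matrix$counts[, u, drop = FALSE]) else rep(0, length(tot))
  frac <- ifelse(tot > 0, usum / tot, NA_real_)
  names(frac) <- matrix$barcodes
  frac
}

#' Write a count matrix as a 10X-style Matrix Market triplet
#'
#' Writes \code{matrix.mtx} (features x cells, the 10X convention),
#' \code{barcodes.tsv} and \code{features.tsv} (id and label columns) into
#' a directory.
#'
#' @param matrix A \code{\link{cell_feature_matrix}}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_matrix_10x <- function(matrix, dir) {
  stopifnot(inherits(matrix, "cell_feature_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(matrix$counts), file.path(dir, "matrix.mtx"))
  writeLines(matrix$barcodes, file.path(dir, "barcodes.tsv"))
  utils::write.table(matrix$features, file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(dir)
}

#' Read a 10X-style Matrix Market triplet directory
#'
#' @param dir Directory containing \code{matrix.mtx}, \code{barcodes.tsv}
#'   and \code{features.tsv}.
#' @return A \code{\link{cell_feature_matrix}}.
#' @export
read_matrix_10x <- function(dir) {
  mm <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feat <- utils::read.table(file.path(dir, "features.tsv"),
    sep = "\t",
    header = FALSE, colClasses = "character"
  )
  counts <- Matrix::t(mm)
  dimnames(counts) <- list(barcodes, feat[[1]])
  labels <- if (ncol(feat) >= 2) feat[[2]] else NULL
  cell_feature_matrix(counts, labels)
}
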