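#' Filter cells by detected features and mitochondrial fraction
#'
#' Keeps cells whose number of detected features (nonzero entries) lies in
#' \code{[min_features, max_features]} and, when a bound is given, whose
#' fraction of counts in mitochondrial features (identified by an id
#' prefix) does not exceed it.
#'
#' @param matrix A \code{\link{cell_feature_matrix}}.
#' @param min_features,max_features Detection-count bounds (inclusive).
#' @param max_mito_fraction Optional upper bound in [0, 1].
#' @param mito_prefix Feature-id prefix marking mitochondrial features
#'   (default \code{"MT-"}).
#' @return The filtered \code{cell_feature_matrix}.
#' @export
filter_cells <- function(matrix, min_features = 0, max_features = Inf,
                         max_mito_fraction = NULL, mito_prefix = "MT-") {
  stopifnot(inherits(matrix, "cell_feature_matrix"),
            min_features <= max_features)
  detected <- Matrix::rowSums(matrix$counts > 0)
  keep_n <- detected >= min_features & detected <= max_features
  keep_m <- rep(TRUE, length(keep_n))
  if (!is.null(max_mito_fraction)) {
    mito <- startsWith(matrix$features$id, mito_prefix)
    tot <- Matrix::rowSums(matrix$counts)
    mfrac <- if (any(mito)) {
      Matrix::rowSums(matrix$counts[, mito, drop = FALSE]) / pmax(tot, 1)
    } else {
      rep(0, length(tot))
    }
    keep_m <- mfrac <= max_mito_fraction
  }
  keep <- keep_n & keep_m
  if (!any(keep)) {
    stop(sprintf(
      "all %d cells removed (%d by feature bounds [%s, %s], %d by mito fraction)",
      length(keep), sum(!keep_n), format(min_features), format(max_features),
      sum(!keep_m)
    ))
  }
  matrix[which(keep), ]
}

#' Filter features by the number of expressing cells
#'
#' @param matrix A \code{\link{cell_feature_matrix}}.
#' @param min_cells Keep features detected (nonzero) in at least this many
#'   cells (default 2).
#' @return The filtered \code{cell_feature_matrix}.
#' @export
filter_features <- function(matrix, min_cells = 2) {
  stopifnot(inherits(matrix, "cell_feature_matrix"), min_cells >= 0)
  ncells <- Matrix::colSums(matrix$counts > 0)
  matrix[, which(ncells >= min_cells)]
}

#' Log-normalize a count matrix
#'
#' Scales each cell to a common library size and log-transforms:
#' \code{ln(count / cell_total * scale_factor + 1)}. Zeros stay zero and
#' the transform is monotone within a cell.
#'
#' @param matrix A \code{\link{cell_feature_matrix}} or a cells-by-features
#'   \code{dgCMatrix}/matrix.
#' @param scale_factor Target library size (default 10,000).
#' @return A sparse real-valued cells-by-features matrix.
#' @export
lognormalize <- function(matrix, scale_factor = 1e4) {
  stopifnot(scale_factor > 0)
  counts <- if (inherits(matrix, "cell_feature_matrix")) matrix$counts else methods::as(matrix, "CsparseMatrix")
  tot <- Matrix::rowSums(counts)
  tot[tot == 0] <- 1
  norm <- Matrix::Diagonal(x = scale_factor / tot) %*% counts
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  methods::as(norm, "CsparseMatrix")
}

#' Principal component analysis of a normalized matrix
#'
#' Center-and-scales each feature to unit variance (zero-variance features
#' contribute zeros), clips standardized values at +/- 10 to stabilize
#' sparse features, and decomposes by SVD.
#'
#' @param normalized A cells-by-features numeric matrix (dense or sparse),
#'   e.g. from \code{\link{lognormalize}}.
#' @param n_pcs Number of components to keep (default 10, truncated to
#'   what the data support).
#' @param clip Absolute bound on standardized values (default 10; NULL to
#'   disable).
#' @return An object of class \code{pc_summary}: list with
#'   \code{embeddings} (cells x k), \code{loadings} (features x k, columns
#'   unit-norm), \code{sdev} and \code{variance_explained}.
#' @export
run_pca <- function(normalized, n_pcs = 10, clip = 10) {
  x <- as.matrix(normalized)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- Inf # zero-variance feature -> all-zero column
  x <- sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
  if (!is.null(clip)) x <- pmin(pmax(x, -clip), clip)
  k <- min(n_pcs, nrow(x) - 1L, ncol(x))
  if (k < 1) stop("matrix too small for PCA")
  sv <- svd(x, nu = k, nv = k)
  emb <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(emb) <- rownames(normalized)
  colnames(emb) <- paste0("PC", seq_len(k))
  load <- sv$v
  rownames(load) <- colnames(normalized)
  colnames(load) <- paste0("PC", seq_len(k))
  varex <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  structure(
    list(
      embeddings = emb, loadings = load,
      sdev = sv$d[seq_len(k)] / sqrt(max(nrow(x) - 1, 1)),
      variance_explained = varex
    ),
    class = "pc_summary"
  )
}

#' @export
print.pc_summary <- function(x, ...) {
  cat(sprintf(
    "<pc_summary> %d cells x %d features, %d PCs (%.1f%% variance)\n",
    nrow(x$embeddings), nrow(x$loadings), ncol(x$embeddings),
    100 * sum(x$variance_explained)
  ))
  invisible(x)
}

#' Silhouette values on an embedding
#'
#' Computes, per cell, \code{s = (b - a) / max(a, b)} where \code{a} is the
#' mean Euclidean distance to the other cells of its own cluster and
#' \code{b} the smallest mean distance to any other cluster. Cells in
#' singleton clusters get \code{s = 0}. Used to quantify how consistently
#' an embedding (typically 2-D) separates predefined cell groups.
#'
#' @param embedding A cells-by-d numeric matrix of coordinates.
#' @param labels Cluster labels, one per cell (>= 2 distinct values).
#' @return A list with \code{widths} (per-cell values in [-1, 1]),
#'   \code{cluster_means} and \code{mean}.
#' @export
silhouette_scores <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  stopifnot(nrow(embedding) == length(labels))
  ulab <- unique(labels)
  if (length(ulab) < 2) stop("need >= 2 clusters")
  d <- as.matrix(stats::dist(embedding))
  n <- nrow(d)
  sizes <- table(labels)[ulab]
  # mean distance from each cell to each cluster (including own, self kept)
  msum <- vapply(ulab, function(g) rowSums(d[, labels == g, drop = FALSE]), numeric(n))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    g <- labels[i]
    ng <- sizes[[g]]
    if (ng == 1) {
      widths[i] <- 0
      next
    }
    a <- msum[i, g] / (ng - 1) # exclude self (distance 0)
    b <- min(msum[i, setdiff(ulab, g)] / sizes[setdiff(ulab, g)])
    widths[i] <- (b - a) / max(a, b)
  }
  cm <- vapply(ulab, function(g) mean(widths[labels == g]), 0)
  list(widths = widths, cluster_means = cm, mean = mean(widths))
}

# Two-sided Wilcoxon rank-sum p-value. Exact by dynamic programming over
# the (possibly tied) rank multiset when the combined sample is small;
# otherwise the tie-corrected normal approximation with continuity
# correction. Returns the p for 'x' vs 'y'.
.wilcox_p <- function(x, y, exact_max_n = 30) {
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  if (m + n <= exact_max_n) {
    # ranks doubled so tied midranks become integers
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    # dp[k+1, s+1] = number of k-subsets of r2 with sum s
    dp <- matrix(0, m + 1, total + 1)
    dp[1, 1] <- 1
    for (v in r2) {
      for (k in m:1) {
        # shift row k-1 by v
        nz <- which(dp[k, ] > 0)
        if (length(nz)) {
          dp[k + 1, nz + v] <- dp[k + 1, nz + v] + dp[k, nz]
        }
      }
    }
    probs <- dp[m + 1, ] / choose(m + n, m)
    sums <- (seq_len(total + 1) - 1) / 2
    lower <- sum(probs[sums <= w + 1e-9])
    upper <- sum(probs[sums >= w - 1e-9])
    min(1, 2 * min(lower, upper))
  } else {
    mu <- m * (m + n + 1) / 2
    ties <- table(r)
    sigma2 <- m * n / 12 *
      ((m + n + 1) - sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
    if (sigma2 <= 0) {
      return(1)
    }
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

# Seurat-style log-e fold change between two groups of log-normalized
# values: difference of ln(mean(expm1(.)) + 1).
.avg_log_fc <- function(x_in, x_out) {
  log(mean(expm1(x_in)) + 1) - log(mean(expm1(x_out)) + 1)
}

#' One-vs-rest Wilcoxon differential expression
#'
#' For every cluster, tests each feature against all remaining cells with
#' the two-sided Wilcoxon rank-sum test, after pre-filtering to features
#' detected in at least \code{min_pct} of in-cluster cells and showing a
#' positive log-e fold change above \code{logfc_threshold} (up-regulated
#' markers only). P-values are Bonferroni-adjusted over the features
#' actually tested within each cluster. The fold change is
#' \code{ln(mean(expm1(x_in)) + 1) - ln(mean(expm1(x_out)) + 1)}, the
#' standard estimator on log-normalized data.
#'
#' @param normalized Cells-by-features log-normalized matrix.
#' @param labels Cluster labels, one per cell.
#' @param min_pct Minimum in-cluster detection fraction (default 0.25).
#' @param logfc_threshold Minimum log-e fold change (default 0.25).
#' @param exact_max_n Use the exact rank-sum distribution when the
#'   combined group size is at most this (default 30).
#' @return A data frame with columns \code{feature_id}, \code{cluster_id},
#'   \code{p_value}, \code{p_adjusted}, \code{avg_log_fc}, \code{pct_in},
#'   \code{pct_out}, sorted within cluster by p-value then descending
#'   |fold change|.
#' @export
wilcoxon_de <- function(normalized, labels, min_pct = 0.25,
                        logfc_threshold = 0.25, exact_max_n = 30) {
  labels <- as.character(labels)
  stopifnot(nrow(normalized) == length(labels))
  ulab <- sort(unique(labels))
  if (length(ulab) < 2) stop("need >= 2 clusters")
  x <- as.matrix(normalized)
  fid <- colnames(x)
  if (is.null(fid)) fid <- paste0("feature_", seq_len(ncol(x)))

  res <- list()
  for (g in ulab) {
    inn <- labels == g
    if (sum(inn) < 3) {
      warning("cluster '", g, "' has fewer than 3 cells; skipped")
      next
    }
    xi <- x[inn, , drop = FALSE]
    xo <- x[!inn, , drop = FALSE]
    pct_in <- colMeans(xi > 0)
    pct_out <- colMeans(xo > 0)
    lfc <- vapply(seq_len(ncol(x)), function(j) .avg_log_fc(xi[, j], xo[, j]), 0)
    test <- which(pct_in >= min_pct & lfc > logfc_threshold)
    if (!length(test)) next
    p <- vapply(test, function(j) .wilcox_p(xi[, j], xo[, j], exact_max_n), 0)
    padj <- pmin(1, p * length(test))
    df <- data.frame(
      feature_id = fid[test], cluster_id = g,
      p_value = p, p_adjusted = padj,
      avg_log_fc = lfc[test], pct_in = pct_in[test], pct_out = pct_out[test]
    )
    df <- df[order(df$p_value, -abs(df$avg_log_fc)), ]
    res[[g]] <- df
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(
      feature_id = character(0), cluster_id = character(0),
      p_value = numeric(0), p_adjusted = numeric(0),
      avg_log_fc = numeric(0), pct_in = numeric(0), pct_out = numeric(0)
    )
  }
  rownames(out) <- NULL
  out
}

#' Sum of absolute PC loadings per feature
#'
#' Scores each feature by the sum of the absolute values of its loadings
#' on the first \code{k} principal components — large scores mark features
#' driving cell-to-cell variation.
#'
#' @param pcs A \code{pc_summary} from \code{\link{run_pca}}.
#' @param features Optional character vector restricting the result.
#' @param k Number of leading PCs to sum over (default 5).
#' @return A named non-negative numeric vector.
#' @export
pc_loading_score <- function(pcs, features = NULL, k = 5) {
  stopifnot(k >= 1, k <= ncol(pcs$loadings))
  s <- rowSums(abs(pcs$loadings[, seq_len(k), drop = FALSE]))
  if (!is.null(features)) {
    s <- s[match(features, rownames(pcs$loadings))]
    names(s) <- features
  }
  s
}

#' Pseudo-bulk coverage versus PC-loading comparison
#'
#' Classifies uTARs into four quadrants at a coverage cut and a loading
#' cut, and reports the Pearson r-squared between the two quantities —
#' the check that features selected by single-cell variation are not
#' simply the most covered ones.
#'
#' @param coverage Named numeric vector of pseudo-bulk read coverage per
#'   feature.
#' @param scores Named numeric vector of PC-loading scores (same names).
#' @param coverage_cut Vertical cut (default 1e4).
#' @param loading_cut Horizontal cut (default 0.5).
#' @return A list with \code{quadrants} (named counts: low_low, low_high,
#'   high_low, high_high; "high" means >= cut) and \code{r_squared}.
#' @export
pseudobulk_vs_loading <- function(coverage, scores,
                                  coverage_cut = 1e4, loading_cut = 0.5) {
  common <- intersect(names(coverage), names(scores))
  if (!length(common)) stop("no shared feature names")
  cv <- coverage[common]
  sc <- scores[common]
  hc <- cv >= coverage_cut
  hs <- sc >= loading_cut
  quadrants <- c(
    low_low = sum(!hc & !hs), low_high = sum(!hc & hs),
    high_low = sum(hc & !hs), high_high = sum(hc & hs)
  )
  r2 <- if (stats::sd(cv) > 0 && stats::sd(sc) > 0) {
    stats::cor(cv, sc)^2
  } else {
    NA_real_
  }
  list(quadrants = quadrants, r_squared = r2, n = length(common))
}
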