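make_cfm <- function(counts, labels = NULL) {
  cell_feature_matrix(counts, labels)
}

test_that("cell filtering applies detection bounds and the mitochondrial cap", {
  counts <- rbind(
    c(5, 3, 0, 0, 0), # 2 features detected
    c(2, 1, 4, 9, 0), # 4 features
    c(1, 1, 1, 1, 16) # 5 features, 80% mito
  )
  dimnames(counts) <- list(c("c1", "c2", "c3"), c("g1", "g2", "g3", "g4", "MT-1"))
  m <- make_cfm(counts)
  expect_equal(filter_cells(m, min_features = 3)$barcodes, c("c2", "c3"))
  expect_equal(filter_cells(m, min_features = 3, max_features = 4)$barcodes, "c2")
  expect_equal(
    filter_cells(m, max_mito_fraction = 0.05)$barcodes, c("c1", "c2")
  )
  expect_identical(filter_cells(m)$counts, m$counts) # no-op spec
  expect_error(filter_cells(m, min_features = 100), "removed")
})

test_that("feature filtering keeps features expressed in enough cells", {
  counts <- rbind(c(1, 0, 2), c(0, 0, 3))
  dimnames(counts) <- list(c("c1", "c2"), c("f1", "f2", "f3"))
  m <- make_cfm(counts)
  expect_equal(filter_features(m, 2)$features$id, "f3")
  expect_equal(filter_features(m, 0)$features$id, c("f1", "f2", "f3"))
  # brute-force check on a random matrix
  set.seed(3)
  cm <- matrix(rbinom(200, 2, 0.2), 20, 10,
    dimnames = list(sprintf("c%02d", 1:20), sprintf("f%02d", 1:10))
  )
  got <- filter_features(make_cfm(cm), 3)$features$id
  expect_equal(got, colnames(cm)[colSums(cm > 0) >= 3])
})

test_that("log-normalization hits the worked value and preserves structure", {
  counts <- rbind(c(10, 90), c(50, 50))
  dimnames(counts) <- list(c("c1", "c2"), c("f1", "f2"))
  norm <- lognormalize(make_cfm(counts), 1e4)
  expect_equal(norm["c1", "f1"], log(1001), tolerance = 1e-12)
  expect_equal(norm["c1", "f1"], 6.9088, tolerance = 1e-4)

  # zeros stay zero; monotone within a cell; equal totals reduce to log1p
  counts2 <- rbind(c(0, 3, 7, 9990), c(1, 2, 3, 9994))
  dimnames(counts2) <- list(c("a", "b"), paste0("f", 1:4))
  n2 <- lognormalize(make_cfm(counts2), 1e4)
  expect_equal(n2["a", "f1"], 0)
  expect_true(all(diff(as.numeric(n2["a", ])) >= 0))
  expect_equal(as.numeric(n2["b", ]), unname(log1p(counts2[2, ])),
    tolerance = 1e-12
  )
})

test_that("PCA matches a dense eigendecomposition and has unit-norm loadings", {
  set.seed(11)
  x <- matrix(rnorm(30 * 8), 30, 8,
    dimnames = list(sprintf("c%02d", 1:30), sprintf("f%d", 1:8))
  )
  pcs <- run_pca(x, n_pcs = 5, clip = NULL)
  expect_equal(apply(pcs$loadings, 2, function(v) sqrt(sum(v^2))),
    rep(1, 5),
    ignore_attr = TRUE, tolerance = 1e-8
  )
  # oracle: eigendecomposition of the covariance of the scaled matrix
  z <- scale(x)
  ev <- eigen(cov(z))
  expect_equal(pcs$sdev^2, ev$values[1:5], tolerance = 1e-8)
  expect_equal(abs(diag(t(pcs$loadings) %*% ev$vectors[, 1:5])),
    rep(1, 5),
    tolerance = 1e-8, ignore_attr = TRUE
  )

  # a rank-1 pattern puts essentially all variance on PC1
  u <- rnorm(40)
  r1 <- outer(u, c(1, 2, 3, 4)) + matrix(rnorm(160, sd = 1e-4), 40)
  dimnames(r1) <- list(sprintf("c%02d", 1:40), paste0("f", 1:4))
  p1 <- run_pca(r1, 2, clip = NULL)
  expect_gte(p1$variance_explained[1], 0.999)
})

test_that("silhouette values match the dense textbook formula and its limits", {
  # coincident clusters far apart: a = 0 -> s = 1
  emb <- rbind(
    matrix(0, 5, 2), matrix(100, 5, 2)
  )
  s <- silhouette_scores(emb, rep(c("a", "b"), each = 5))
  expect_equal(s$widths, rep(1, 10))

  # 6-point hand-computable configuration
  pts <- rbind(c(0, 0), c(0, 1), c(1, 0), c(10, 0), c(10, 1), c(11, 0))
  lab <- rep(c("L", "R"), each = 3)
  s6 <- silhouette_scores(pts, lab)
  d <- as.matrix(dist(pts))
  ref <- sapply(1:6, function(i) {
    own <- setdiff(which(lab == lab[i]), i)
    oth <- which(lab != lab[i])
    a <- mean(d[i, own])
    b <- mean(d[i, oth])
    (b - a) / max(a, b)
  })
  expect_equal(s6$widths, ref, tolerance = 1e-12)

  # against the reference implementation on random data
  set.seed(21)
  emb2 <- matrix(rnorm(400), 200, 2)
  lab2 <- sample(letters[1:4], 200, replace = TRUE)
  s2 <- silhouette_scores(emb2, lab2)
  ref2 <- cluster::silhouette(as.integer(factor(lab2)), dist(emb2))
  expect_equal(s2$widths, as.numeric(ref2[, "sil_width"]), tolerance = 1e-10)

  # random labels carry no cluster structure
  set.seed(22)
  emb3 <- matrix(rnorm(600), 300, 2)
  s3 <- silhouette_scores(emb3, sample(c("x", "y"), 300, TRUE))
  expect_lt(abs(s3$mean), 0.05)

  # singleton clusters are defined as zero
  s4 <- silhouette_scores(rbind(c(0, 0), c(1, 1), c(2, 2)), c("a", "a", "b"))
  expect_equal(s4$widths[3], 0)
})

test_that("rank-sum p-values match exact enumeration, with and without ties", {
  # the worked small case
  expect_equal(tarseq:::.wilcox_p(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)

  set.seed(41)
  for (i in 1:25) {
    m <- sample(2:8, 1)
    n <- sample(2:8, 1)
    x <- if (i %% 2 == 0) {
      sample(1:4, m, replace = TRUE) # heavy ties
    } else {
      rnorm(m)
    }
    y <- if (i %% 2 == 0) sample(1:4, n, replace = TRUE) else rnorm(n)
    expect_equal(tarseq:::.wilcox_p(x, y), enum_wilcox_p(x, y),
      tolerance = 1e-10,
      info = sprintf("case %d (m=%d, n=%d)", i, m, n)
    )
  }
  # large-sample route agrees with the tie-corrected normal approximation
  set.seed(42)
  x <- rnorm(40)
  y <- rnorm(45, 0.5)
  expect_equal(
    tarseq:::.wilcox_p(x, y),
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
    tolerance = 1e-9
  )
})

test_that("differential testing finds the planted marker and filters correctly", {
  set.seed(55)
  n_per <- 20
  labels <- rep(c("k1", "k2"), each = n_per)
  counts <- matrix(rpois(2 * n_per * 10, 5), 2 * n_per, 10)
  counts[labels == "k1", 3] <- rpois(n_per, 40) # 8x up in k1
  dimnames(counts) <- list(sprintf("c%02d", 1:(2 * n_per)), sprintf("f%02d", 1:10))
  norm <- lognormalize(make_cfm(counts))
  de <- wilcoxon_de(norm, labels, min_pct = 0.25, logfc_threshold = 0.25)
  top_k1 <- de[de$cluster_id == "k1", ][1, ]
  expect_equal(top_k1$feature_id, "f03")
  expect_gt(top_k1$avg_log_fc, 0.25)
  expect_gte(top_k1$pct_in, 0.25)
  expect_true(all(de$p_adjusted >= de$p_value))
  expect_true(all(de$avg_log_fc > 0.25)) # up-only pre-filter

  # identical distributions: nothing passes the fold-change filter
  half <- matrix(rpois(200, 5), 20, 10)
  same <- rbind(half, half) # group k2 repeats k1 exactly
  dimnames(same) <- list(sprintf("c%02d", 1:40), sprintf("f%02d", 1:10))
  de0 <- wilcoxon_de(lognormalize(make_cfm(same)), labels,
    min_pct = 0, logfc_threshold = 0.25
  )
  expect_equal(nrow(de0), 0)
  # ... and with no filters, p-values are near 1 for equal distributions
  de1 <- wilcoxon_de(lognormalize(make_cfm(same)), labels,
    min_pct = 0, logfc_threshold = -Inf
  )
  expect_gt(min(de1$p_value), 0.001)

  # tiny clusters are skipped with a warning
  expect_warning(
    wilcoxon_de(norm, c(rep("k1", 2), rep("k2", 38)), min_pct = 0),
    "fewer than 3"
  )
})

test_that("PC loading scores sum absolute loadings and ignore PC sign", {
  pcs <- structure(
    list(loadings = matrix(
      c(
        0.1, -0.2, 0.05, 0.3, -0.1,
        0, 0, 0, 0, 0
      ),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("fa", "fb"), paste0("PC", 1:5))
    )),
    class = "pc_summary"
  )
  s <- pc_loading_score(pcs, k = 5)
  expect_equal(unname(s), c(0.75, 0))
  pcs$loadings[1, ] <- -pcs$loadings[1, ]
  expect_equal(unname(pc_loading_score(pcs, k = 5)), c(0.75, 0))
  expect_equal(unname(pc_loading_score(pcs, features = "fb", k = 5)), 0)
})

test_that("the coverage-versus-loading comparison classifies quadrants and reports r2", {
  cov <- c(a = 2e4, b = 5e3, c = 2e4, d = 100)
  sc <- c(a = 0.6, b = 0.6, c = 0.1, d = 0.1)
  q <- pseudobulk_vs_loading(cov, sc)
  expect_equal(
    q$quadrants,
    c(low_low = 1, low_high = 1, high_low = 1, high_high = 1)
  )
  # perfectly correlated pairs
  x <- seq(100, 1e5, length.out = 50)
  names(x) <- paste0("u", 1:50)
  y <- 2 * x + 5
  names(y) <- names(x)
  expect_equal(pseudobulk_vs_loading(x, y)$r_squared, 1, tolerance = 1e-12)
  # independent pairs decorrelate
  set.seed(77)
  a <- stats::setNames(runif(1000, 0, 1e5), paste0("u", 1:1000))
  b <- stats::setNames(runif(1000), paste0("u", 1:1000))
  expect_lt(pseudobulk_vs_loading(a, b)$r_squared, 0.01)
})
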