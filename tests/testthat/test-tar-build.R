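test_that("merge bridges gaps up to the limit, never across strands, and is idempotent", {
  a <- gr("chr1", c(101, 651), c(200, 700), "+") # gap 450 (0-based coords 100-200, 650-700)
  m <- merge_intervals(a, 450)
  expect_length(m, 1)
  expect_equal(GenomicRanges::start(m), 101)
  expect_equal(GenomicRanges::end(m), 700)

  b <- gr("chr1", c(101, 751), c(200, 800), "+") # gap 550 > 500
  expect_length(merge_intervals(b, 500), 2)

  # the exact boundary: gap == max_gap merges, max_gap + 1 does not
  edge <- gr("chr1", c(101, 701), c(200, 750), "+") # gap of 500 bases
  expect_length(merge_intervals(edge, 500), 1)
  edge2 <- gr("chr1", c(101, 702), c(200, 750), "+") # gap of 501 bases
  expect_length(merge_intervals(edge2, 500), 2)

  # opposite strands never merge
  c2 <- c(gr("chr1", 101, 200, "+"), gr("chr1", 151, 250, "-"))
  expect_length(merge_intervals(c2, 500), 2)

  m2 <- merge_intervals(m, 450)
  expect_identical(GenomicRanges::ranges(m2), GenomicRanges::ranges(m))
})

test_that("merge equals a brute-force union over random interval sets", {
  set.seed(4)
  for (rep in 1:60) {
    n <- sample(2:20, 1)
    start <- sample(1:5000, n, replace = TRUE)
    width <- sample(10:800, n, replace = TRUE)
    df <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, TRUE),
      start = start, end = start + width - 1,
      strand = sample(c("+", "-"), n, TRUE)
    )
    gap <- sample(c(0, 100, 500), 1)
    got <- merge_intervals(
      gr(df$chrom, df$start, df$end, df$strand), gap
    )
    ref <- brute_merge(df, gap)
    expect_equal(length(got), nrow(ref))
    got_df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(got)),
      start = GenomicRanges::start(got), end = GenomicRanges::end(got),
      strand = as.character(GenomicRanges::strand(got))
    )
    o <- order(got_df$chrom, got_df$start, got_df$strand)
    ro <- order(ref$chrom, ref$start, ref$strand)
    expect_equal(got_df$start[o], ref$start[ro])
    expect_equal(got_df$end[o], ref$end[ro])
    expect_equal(got_df$strand[o], ref$strand[ro])
  }
})

test_that("interval coverage follows split-read, same-strand, any-overlap semantics", {
  spliced <- make_aln("chr1", 101, "+", cigar = "50M150N50M") # blocks [101,150], [301,350]
  expect_equal(interval_coverage(gr("chr1", 201, 260, "+"), spliced), 0) # gap only
  expect_equal(interval_coverage(gr("chr1", 121, 130, "+"), spliced), 1)
  expect_equal(interval_coverage(gr("chr1", 121, 130, "-"), spliced), 0)
  # one read may count toward multiple intervals
  both <- gr("chr1", c(121, 311), c(130, 320), "+")
  expect_equal(interval_coverage(both, spliced), c(1, 1))
  expect_equal(interval_coverage(GenomicRanges::GRanges(), spliced), integer(0))
})

test_that("the depth threshold is total/1e7, floored and clamped at 1", {
  expect_equal(compute_threshold(20000000), 2)
  expect_equal(compute_threshold(5000000), 1)
  expect_equal(compute_threshold(0), 1)
  expect_equal(compute_threshold(19999999), 1)
  expect_equal(compute_threshold(3.7e8), 37)
})

test_that("coverage filtering keeps intervals at or above n, in order", {
  iv <- gr("chr1", c(1, 101, 201), c(50, 150, 250), "+")
  kept <- filter_by_coverage(iv, c(5, 1, 2), 2)
  expect_equal(GenomicRanges::start(kept), c(1, 201))
  expect_equal(S4Vectors::mcols(kept)$total_reads, c(5L, 2L))
  expect_length(filter_by_coverage(iv, c(5, 1, 2), 1), 3)
  expect_error(filter_by_coverage(iv, c(1, 2), 1), "mismatch")

  set.seed(2)
  counts <- sample(0:10, 3, replace = TRUE)
  n <- 4
  expect_equal(
    GenomicRanges::start(filter_by_coverage(iv, counts, n)),
    GenomicRanges::start(iv)[counts >= n]
  )
})

test_that("labeling covers the full overlap-by-mode truth table", {
  annot <- make_annot("chr1", 1500 - 1, 3000, "-", "geneA") # gene -[1499,3000)
  cases <- list(
    # tar strand, tar span, expected: direction, agnostic label, directional label
    list("+", c(1001, 2000), "antisense-overlap", "aTAR", "uTAR"),
    list("-", c(1001, 2000), "sense-overlap", "aTAR", "aTAR"),
    list("+", c(10, 20), "no-overlap", "uTAR", "uTAR"),
    list("-", c(10, 20), "no-overlap", "uTAR", "uTAR")
  )
  for (cs in cases) {
    tar <- gr("chr1", cs[[2]][1], cs[[2]][2], cs[[1]])
    ag <- label_tars(tar, annot, "strand_agnostic")
    di <- label_tars(tar, annot, "directional")
    expect_equal(S4Vectors::mcols(ag)$direction_flag, cs[[3]])
    expect_equal(S4Vectors::mcols(di)$direction_flag, cs[[3]])
    expect_equal(S4Vectors::mcols(ag)$label, cs[[4]])
    expect_equal(S4Vectors::mcols(di)$label, cs[[5]])
  }
  # a TAR overlapping both a sense and an antisense transcript is sense
  annot2 <- rbind(annot, make_annot("chr1", 900, 1200, "+", "geneB"))
  tar <- gr("chr1", 1001, 2000, "+")
  expect_equal(
    S4Vectors::mcols(label_tars(tar, annot2, "directional"))$direction_flag,
    "sense-overlap"
  )
})

test_that("every TAR gets exactly one label and ids are stable under input order", {
  set.seed(6)
  n <- 40
  start <- sample(1:9000, n)
  tars <- gr(
    sample(c("chr1", "chr2"), n, TRUE), start, start + 199,
    sample(c("+", "-"), n, TRUE)
  )
  annot <- make_annot("chr1", c(1000, 5000), c(3000, 7000), c("+", "-"))
  lab <- suppressWarnings(label_tars(tars, annot))
  m <- S4Vectors::mcols(lab)
  expect_true(all(m$label %in% c("aTAR", "uTAR")))
  expect_equal(sum(m$label == "aTAR") + sum(m$label == "uTAR"), n)
  expect_equal(m$id, paste0("TAR_", seq_len(n)))
  lab2 <- suppressWarnings(label_tars(tars[sample(n)], annot))
  expect_identical(as.data.frame(lab), as.data.frame(lab2))
})

test_that("a chromosome absent from the annotation warns and yields no-overlap", {
  annot <- make_annot("chr1", 100, 500, "+")
  expect_warning(
    lab <- label_tars(gr("chr9", 101, 200, "+"), annot),
    "chr9"
  )
  expect_equal(S4Vectors::mcols(lab)$label, "uTAR")
})

test_that("TAR annotations round-trip through BED and GTF", {
  tars <- gr(
    c("chr1", "chr1", "chr2"), c(101, 1001, 51), c(200, 2000, 500),
    c("+", "-", "+")
  )
  annot <- suppressWarnings(label_tars(
    tars, make_annot("chr1", 900, 2100, "+")
  ))
  for (fmt in c("BED", "GTF")) {
    f <- tempfile(fileext = paste0(".", tolower(fmt)))
    write_tar_annotation(annot, f, fmt)
    back <- read_tar_annotation(f, fmt)
    expect_equal(as.data.frame(back), as.data.frame(annot), info = fmt)
  }
  # the documented BED line layout, with missing read counts as "."
  one <- gr("chr1", 101, 200, "+")
  lab <- suppressWarnings(label_tars(one, make_annot("chr2", 1, 2, "+")))
  S4Vectors::mcols(lab)$total_reads <- NA_integer_
  f <- tempfile(fileext = ".bed")
  write_tar_annotation(lab, f, "BED")
  expect_equal(readLines(f), "chr1\t100\t200\tTAR_1_uTAR_n\t.\t+")
  # empty set -> valid empty file
  empty <- annot[0]
  f2 <- tempfile(fileext = ".bed")
  write_tar_annotation(empty, f2, "BED")
  expect_length(read_tar_annotation(f2, "BED"), 0)
  # refFlat output parses back through the gene-annotation reader
  f3 <- tempfile(fileext = ".refflat")
  write_tar_annotation(annot, f3, "refFlat")
  rf <- read_refflat(f3)
  expect_equal(nrow(rf), 3)
  expect_equal(rf$tx_start, GenomicRanges::start(annot) - 1L)
})

test_that("refFlat annotations round-trip through write and read", {
  annot <- make_annot("chr1", c(100, 5000), c(2000, 9000), c("+", "-"))
  annot$exon_count <- c(2L, 1L)
  annot$exon_starts <- I(list(c(100L, 1500L), 5000L))
  annot$exon_ends <- I(list(c(800L, 2000L), 9000L))
  f <- tempfile(fileext = ".refflat")
  write_refflat(annot, f)
  back <- read_refflat(f)
  expect_equal(back$gene_name, annot$gene_name)
  expect_equal(back$tx_start, annot$tx_start)
  expect_equal(back$exon_starts, unclass(annot$exon_starts))
  spans <- transcript_spans(back)
  expect_equal(GenomicRanges::start(spans), annot$tx_start + 1L)
  expect_equal(GenomicRanges::end(spans), annot$tx_end)
})
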