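# Readers/writers, coordinate conventions, interval arithmetic.

test_that("narrowPeak records parse with column-7 scores and summit offsets", {
  p <- write_np_lines(
    "chr9\t21960000\t21998000\tp1\t850\t.\t12.5\t-1\t-1\t2100")
  pk <- read_peaks(p, format = "narrowPeak", factor = "CBX7",
                   sample = "BF", replicate = "1")
  expect_length(pk, 1L)
  # 0-based half-open on disk -> 1-based closed internally
  expect_equal(start(pk) - 1L, 21960000L)
  expect_equal(end(pk), 21998000L)
  expect_equal(pk$score, 12.5)
  expect_equal(pk$summit, 2100L)
  expect_equal(pk$factor, "CBX7")

  # absent summit is encoded as -1
  p2 <- write_np_lines(
    "chr1\t100\t200\tp1\t10\t.\t3.25\t-1\t-1\t-1")
  expect_true(is.na(read_peaks(p2, "narrowPeak")$summit))
})

test_that("empty and malformed peak files are handled per contract", {
  empty <- write_np_lines(character())
  expect_length(read_peaks(empty, "narrowPeak"), 0L)

  degenerate <- write_np_lines(c(
    "chr1\t100\t200\tp1\t10\t.\t3\t-1\t-1\t-1",
    "chr1\t500\t500\tp2\t10\t.\t3\t-1\t-1\t-1"))
  expect_error(read_peaks(degenerate, "narrowPeak"), "line 2.*start >= end")

  short <- write_np_lines("chr1\t100\t200\tp1\t10\t.")
  expect_error(read_peaks(short, "narrowPeak"), "line 1.*columns")
  expect_silent(read_peaks(short, "bed6"))

  noninteger <- write_np_lines("chr1\t10.5\t200\tp\t1\t.\t1\t-1\t-1\t-1")
  expect_error(read_peaks(noninteger, "narrowPeak"), "non-integer")
})

test_that("peak write/read round trip preserves coordinates, scores, summits", {
  withr::with_seed(11, {
    n <- 50L
    st <- sample.int(1e6, n)
    pk <- peak_track("chrT", st, st + sample(50:5000, n, TRUE),
                     score = round(runif(n, 0, 60), 3),
                     summit = sample(0:49, n, TRUE),
                     factor = "CBX6", sample = "A", replicate = "2")
  })
  f <- tempfile(fileext = ".narrowPeak")
  write_peaks(pk, f, format = "narrowPeak")
  back <- read_peaks(f, "narrowPeak", factor = "CBX6", sample = "A",
                     replicate = "2")
  expect_equal(start(back), start(pk))
  expect_equal(end(back), end(pk))
  expect_equal(back$score, pk$score)
  expect_equal(back$summit, pk$summit)

  f2 <- tempfile(fileext = ".bed")
  write_peaks(pk, f2, format = "bed6")
  back2 <- read_peaks(f2, "bed6")
  expect_equal(start(back2), start(pk))
  expect_equal(back2$score, pk$score)
})

test_that("GTF genes convert coordinates and derive TSS/TES from strand", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr2\tsrc\tgene\t100001\t105000\t.\t-\t.\t",
           "gene_id \"gm\"; gene_biotype \"protein_coding\";"),
    paste0("chr2\tsrc\tgene\t201\t300\t.\t+\t.\t",
           "gene_id \"gp\"; gene_biotype \"lincRNA\";")), gtf)
  g <- read_genes(gtf, "gtf")
  gm <- g[g$gene_id == "gm"]
  # 1-based inclusive GTF 100001..105000 is 0-based half-open 100000..105000
  expect_equal(start(gm) - 1L, 100000L)
  expect_equal(end(gm), 105000L)
  # minus strand: TSS at the right edge (0-based 104999), TES at the left
  expect_equal(gm$tss - 1L, 104999L)
  expect_equal(gm$tes - 1L, 100000L)
  expect_equal(gm$biotype, "coding")
  gp <- g[g$gene_id == "gp"]
  expect_equal(gp$tss - 1L, 200L)
  expect_equal(gp$tes - 1L, 299L)
  expect_equal(gp$biotype, "noncoding")
})

test_that("GTF involution and gene-validation errors", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\tgene\t5001\t60000\t.\t+\t.\t",
           "gene_id \"a\"; gene_biotype \"protein_coding\";"),
    paste0("chr1\tsrc\tgene\t90001\t140000\t.\t-\t.\t",
           "gene_id \"b\"; gene_biotype \"protein_coding\";")), gtf)
  g <- read_genes(gtf, "gtf")
  out <- tempfile(fileext = ".gtf")
  write_genes_gtf(g, out)
  g2 <- read_genes(out, "gtf")
  expect_equal(start(g2), start(g))
  expect_equal(end(g2), end(g))
  expect_equal(as.character(strand(g2)), as.character(strand(g)))

  nostrand <- tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\tsrc\tgene\t1\t100\t.\t.\t.\tgene_id \"x\";"),
             nostrand)
  expect_error(read_genes(nostrand, "gtf"), "without strand")

  dup <- tempfile(fileext = ".gtf")
  writeLines(rep(paste0("chr1\tsrc\tgene\t1\t100\t.\t+\t.\tgene_id \"x\";"),
                 2), dup)
  expect_error(read_genes(dup, "gtf"), "x")
})

test_that("merge_intervals joins by gap and matches the per-base oracle", {
  # {[0,10), [5,20)} gap 0 -> {[0,20)} (1-based: 1..10, 6..20 -> 1..20)
  gr <- GRanges("c", IRanges(c(1, 6), c(10, 20)))
  m <- merge_intervals(gr, gap = 0)
  expect_equal(gr_df(m), data.frame(start = 1L, end = 20L))

  # {[0,10), [12,20)}: gap 1 keeps them apart, gap 2 joins
  gr2 <- GRanges("c", IRanges(c(1, 13), c(10, 20)))
  expect_equal(nrow(gr_df(merge_intervals(gr2, gap = 1))), 2L)
  expect_equal(gr_df(merge_intervals(gr2, gap = 2)),
               data.frame(start = 1L, end = 20L))

  expect_equal(gr_df(merge_intervals(GRanges("c", IRanges(5, 9)), 3)),
               data.frame(start = 5L, end = 9L))
  expect_error(merge_intervals(gr, gap = -1), ">= 0")

  withr::with_seed(42, {
    for (trial in 1:40) {
      n <- sample(1:60, 1)
      st <- sample.int(5000, n, replace = TRUE)
      en <- st + sample.int(300, n, replace = TRUE)
      gap <- sample(0:200, 1)
      got <- gr_df(merge_intervals(GRanges("c", IRanges(st, en)), gap))
      expect_equal(got, ora_merge(st, en, gap), info = paste("trial", trial))
    }
  })
})

test_that("nearest_feature matches exhaustive scan and applies the tie rule", {
  # query at 100, features at 90 and 250 -> feature@90, distance -10
  f <- data.frame(chrom = "c", pos = c(90, 250))
  r <- nearest_feature("c", 100, f)
  expect_equal(r$feature, 1L)
  expect_equal(r$distance, -10)

  # equidistant: coding preferred, then lexicographically smallest id
  f2 <- data.frame(chrom = "c", pos = c(80, 120),
                   coding = c(FALSE, TRUE), id = c("a", "b"))
  expect_equal(nearest_feature("c", 100, f2)$feature, 2L)
  f3 <- data.frame(chrom = "c", pos = c(80, 120),
                   coding = c(TRUE, TRUE), id = c("zz", "aa"))
  expect_equal(nearest_feature("c", 100, f3)$feature, 2L)

  # no feature on the query chromosome -> unassigned sentinel
  expect_true(is.na(nearest_feature("chrZ", 5, f)$feature))

  withr::with_seed(7, {
    feats <- data.frame(
      chrom = sample(c("c1", "c2"), 1000, TRUE),
      pos = sample.int(2e5, 1000, replace = TRUE),
      coding = sample(c(TRUE, FALSE), 1000, TRUE),
      id = sprintf("g%04d", sample.int(5000, 1000)))
    qc <- sample(c("c1", "c2"), 100, TRUE)
    qp <- sample.int(2e5, 100, replace = TRUE)
    expect_equal(nearest_feature(qc, qp, feats)$feature,
                 ora_nearest(qc, qp, feats))
  })
})
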