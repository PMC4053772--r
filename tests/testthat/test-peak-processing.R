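# Replicate merging, co-occupancy calling, foothill filtering.

test_that("merge_replicates union and intersection behave per contract", {
  pk <- c(mk_peaks(100, 200, replicate = "1"),
          mk_peaks(150, 300, replicate = "2"))
  u <- merge_replicates(pk, mode = "union", gap = 0)
  expect_equal(gr_df(u), data.frame(start = 100L, end = 300L))
  expect_equal(u$support, 2L)
  expect_equal(u$factor, "CBX7")

  far <- c(mk_peaks(100, 200, replicate = "1"),
           mk_peaks(400, 500, replicate = "2"))
  expect_length(merge_replicates(far, mode = "intersection"), 0L)

  mixed <- c(mk_peaks(1, 10, factor = "CBX7"),
             mk_peaks(1, 10, factor = "CBX8"))
  expect_error(merge_replicates(mixed), "single factor")
})

test_that("replicate merging matches per-base oracles on random fixtures", {
  withr::with_seed(99, {
    for (trial in 1:25) {
      len <- 50000L
      reps <- lapply(1:3, function(r) {
        n <- sample(5:50, 1)
        st <- sample.int(len - 400L, n, replace = TRUE)
        data.frame(start = st, end = st + sample.int(400, n, replace = TRUE))
      })
      gap <- sample(c(0L, 10L, 100L), 1)
      pk <- do.call(c, lapply(seq_along(reps), function(r)
        mk_peaks(reps[[r]]$start, reps[[r]]$end, replicate = as.character(r))))
      u <- merge_replicates(pk, "union", gap = gap)
      expect_equal(gr_df(u),
                   ora_merge(unlist(lapply(reps, `[[`, "start")),
                             unlist(lapply(reps, `[[`, "end")), gap,
                             len = len + 1000L),
                   info = paste("union trial", trial))
      it <- merge_replicates(pk, "intersection", gap = gap)
      expect_equal(gr_df(it),
                   ora_multi_cover(reps, gap, 2L, len + 1000L),
                   info = paste("intersection trial", trial))
      # support counts replicates, not peaks
      expect_true(all(u$support >= 1L & u$support <= 3L))
      expect_true(all(it$support >= 2L))
    }
  })
})

test_that("co-occupancy requires one CBX, one RING and the histone mark", {
  tr <- mk_tracks(list(CBX7 = c(100, 200), RING1 = c(150, 250),
                       H3K27me3 = c(120, 260)))
  s <- call_cooccupancy(tr, link_gap = 0)
  expect_length(s, 1L)
  expect_equal(gr_df(s), data.frame(start = 100L, end = 260L))
  expect_setequal(unlist(s$factors_present), c("CBX7", "RING1", "H3K27me3"))
  expect_equal(s$n_prc1_factors, 2L)
  expect_true(s$has_h3k27me3)

  no_mark <- mk_tracks(list(CBX7 = c(100, 200), RING1 = c(150, 250),
                            H3K27me3 = c(5000, 5100)))
  expect_length(call_cooccupancy(no_mark, link_gap = 0), 0L)
  expect_error(call_cooccupancy(mk_tracks(list(CBX7 = c(1, 10)))),
               "required mark")
  expect_error(
    call_cooccupancy(mk_tracks(list(XXX = c(1, 10), H3K27me3 = c(1, 10)))),
    "not in registry")
  expect_length(call_cooccupancy(list()), 0L)
})

test_that("co-occupancy matches the per-base criterion oracle and is
           permutation invariant", {
  reg <- default_factor_registry()
  withr::with_seed(31, {
    for (trial in 1:20) {
      len <- 80000L
      facs <- c("CBX6", "CBX7", "CBX8", "RING1", "RING2", "H3K27me3")
      tracks <- lapply(setNames(facs, facs), function(f) {
        n <- sample(2:20, 1)
        st <- sample.int(len - 2000L, n, replace = TRUE)
        data.frame(start = st, end = st + sample.int(2000, n, replace = TRUE))
      })
      link_gap <- sample(c(0L, 500L, 1000L), 1)
      rbf <- lapply(tracks, function(d)
        GRanges("c", IRanges(d$start, d$end), score = 1))
      got <- call_cooccupancy(rbf, registry = reg, link_gap = link_gap)
      ora <- ora_cooccupancy(tracks, link_gap, reg, "H3K27me3",
                             len + 3000L)
      expect_equal(gr_df(got), ora, info = paste("trial", trial))
      # invariant: every site satisfies the criterion by construction
      expect_true(all(lengths(got$cbx_members) >= 1L))
      expect_true(all(lengths(got$ring_members) >= 1L))
      expect_true(all(got$has_h3k27me3))
      # factor-order permutation invariance
      perm <- sample(names(rbf))
      got2 <- call_cooccupancy(rbf[perm], registry = reg,
                               link_gap = link_gap)
      expect_equal(gr_df(got2), gr_df(got))
      expect_equal(sort(unlist(got2$factors_present)),
                   sort(unlist(got$factors_present)))
    }
  })
})

test_that("adding a peak never removes an existing co-occupancy site", {
  withr::with_seed(55, {
    for (trial in 1:10) {
      len <- 50000L
      facs <- c("CBX7", "RING1", "H3K27me3")
      rbf <- lapply(setNames(facs, facs), function(f) {
        st <- sample.int(len, sample(3:12, 1), replace = TRUE)
        GRanges("c", IRanges(st, st + sample.int(1500, length(st),
                                                 replace = TRUE)),
                score = 1)
      })
      before <- call_cooccupancy(rbf, link_gap = 1000)
      extra_st <- sample.int(len, 1)
      f <- sample(facs, 1)
      rbf[[f]] <- c(rbf[[f]],
                    GRanges("c", IRanges(extra_st, extra_st + 800),
                            score = 1))
      after <- call_cooccupancy(rbf, link_gap = 1000)
      # every previous site is contained in some current site
      ok <- countOverlaps(before, after, type = "within",
                          ignore.strand = TRUE) >= 1L
      expect_true(all(ok), info = paste("trial", trial))
    }
  })
})

test_that("foothill filtering drops weak members and flags broken sites", {
  tr <- mk_tracks(list(CBX7 = c(100, 200), RING1 = c(150, 250),
                       H3K27me3 = c(120, 260)))
  tr$CBX7$score <- 10; tr$RING1$score <- 9; tr$H3K27me3$score <- 2
  s <- call_cooccupancy(tr, link_gap = 0)

  expect_identical(filter_foothills(s, 0), s)

  half <- filter_foothills(s, 0.5)
  expect_setequal(unlist(half$factors_present), c("CBX7", "RING1"))
  expect_true(half$rejected) # mark lost -> criterion broken, flagged not dropped

  top <- filter_foothills(s, 1.0)
  expect_equal(unlist(top$factors_present), "CBX7")

  expect_error(filter_foothills(s, 1.5), "min_fraction")
})
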