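# Site-to-gene assignment and peak-architecture classification.

test_that("a distant downstream site is assigned to its only neighbour", {
  # MEIS1-like: simple peak ~150 kb beyond the TES, no other gene nearby
  genes <- mk_genes(500000, 640000, strand = "+")
  sites <- mk_sites(789000, 791500) # midpoint 150 kb past the TES
  calls <- assign_targets(sites, genes)
  expect_equal(calls$gene_id, "g01")
  expect_equal(calls$category, "TES_ASSOCIATED")
  expect_length(attr(calls, "unassigned"), 0L)
  # distance is reported even though far beyond any promoter window
  expect_lt(calls$distance_to_tss, -290000)
})

test_that("coding genes win over noncoding ones regardless of TSS distance", {
  genes <- c(mk_genes(100000, 150000, gene_id = "coding1"),
             mk_genes(140000, 160000, gene_id = "nc1", biotype = "noncoding"))
  # site overlaps both bodies; the noncoding TSS (140000) is nearer
  sites <- mk_sites(139000, 143000)
  calls <- assign_targets(sites, genes,
                          architecture_config(end_window = 1000))
  expect_true("coding1" %in% calls$gene_id)
  expect_false("nc1" %in% calls$gene_id)
})

test_that("sites on chromosomes without genes land in the unassigned sink", {
  genes <- mk_genes(1000, 40000)
  sites <- mk_sites(c(2000, 500), c(3000, 900), chrom = c("chrT", "chrZ"))
  calls <- assign_targets(sites, genes)
  expect_equal(attr(calls, "unassigned"), 2L)
  expect_equal(sum(lengths(calls$owned_sites)), 1L)
})

test_that("assignment equals the exhaustive scan on random fixtures", {
  cfg <- architecture_config()
  withr::with_seed(77, {
    for (trial in 1:5) {
      ng <- 50L
      gst <- sort(sample.int(5e6, ng))
      gen <- mk_genes(gst, gst + sample(20000:60000, ng, TRUE),
                      strand = sample(c("+", "-"), ng, TRUE),
                      biotype = sample(c("coding", "noncoding"), ng, TRUE,
                                       prob = c(0.8, 0.2)))
      ns <- 200L
      sst <- sample.int(5e6, ns)
      sites <- mk_sites(sst, sst + sample(500:5000, ns, TRUE))
      calls <- suppressMessages(assign_targets(sites, gen, cfg))

      # oracle: nearest TSS, coding-overlap exception, linked-pair ambiguity
      tssd <- data.frame(chrom = "chrT", pos = gen$tss,
                         coding = gen$biotype == "coding",
                         id = gen$gene_id)
      mid <- floor((start(sites) + end(sites)) / 2)
      owner <- ora_nearest(rep("chrT", ns), mid, tssd)
      amb <- rep(FALSE, ng)
      for (i in seq_len(ns)) {
        ovg <- which(start(gen) <= end(sites)[i] &
                       end(gen) >= start(sites)[i])
        if (length(ovg) && any(gen$biotype[ovg] == "coding") &&
            any(gen$biotype[ovg] == "noncoding")) {
          gc <- ovg[gen$biotype[ovg] == "coding"]
          d <- abs(gen$tss[gc] - mid[i])
          owner[i] <- gc[order(d, gen$gene_id[gc])][1L]
        }
        if (any(gen$biotype[ovg] == "coding") &&
            any(gen$biotype[ovg] == "noncoding"))
          ovg <- ovg[gen$biotype[ovg] == "coding"]
        if (length(ovg) >= 2L) {
          for (a in seq_along(ovg)[-length(ovg)])
            for (b in seq(a + 1L, length(ovg))) {
              ga <- ovg[a]; gb <- ovg[b]
              gp <- max(start(gen)[ga], start(gen)[gb]) -
                min(end(gen)[ga], end(gen)[gb]) - 1L
              if (gp <= 2L * cfg$end_window) amb[c(ga, gb)] <- TRUE
            }
        }
      }
      got_owner <- rep(NA_integer_, ns)
      for (r in seq_len(nrow(calls)))
        got_owner[calls$owned_sites[[r]]] <-
          match(calls$gene_id[r], gen$gene_id)
      expect_equal(got_owner, owner, info = paste("trial", trial))
      amb_called <- calls$gene_id[calls$category == "AMBIGUOUS"]
      expect_setequal(amb_called, gen$gene_id[amb])
      # conservation: every site owned exactly once or unassigned
      expect_setequal(c(unlist(calls$owned_sites),
                        attr(calls, "unassigned")), seq_len(ns))
      expect_equal(anyDuplicated(unlist(calls$owned_sites)), 0L)
    }
  })
})

test_that("architecture categories follow the end-window cluster rule", {
  cfg <- architecture_config(end_window = 5000)
  g <- mk_genes(100000, 160000, strand = "+")

  # single site 500 bp upstream of the TSS
  tssite <- mk_sites(99000, 100000) # midpoint 99500
  expect_equal(classify_architecture(tssite, g, cfg)$category,
               "TSS_ASSOCIATED")

  # discrete flanking peaks at both ends, none across the body (UNCX-like)
  flank <- mk_sites(c(96000, 162000), c(98000, 164000))
  cl <- classify_architecture(flank, g, cfg)
  expect_equal(cl$category, "BOTH_ENDS")
  expect_equal(cl$subcategory, "FLANKING_DISCRETE")

  # upstream, internal and downstream sites (ZIC1/ZIC4-like)
  dist <- mk_sites(c(96000, 125000, 162000), c(98000, 129000, 164000))
  cl2 <- classify_architecture(dist, g, cfg)
  expect_equal(cl2$category, "BOTH_ENDS")
  expect_equal(cl2$subcategory, "DISTRIBUTED")

  # far downstream only -> TES side despite no cluster within the window
  tes <- mk_sites(180000, 182000)
  expect_equal(classify_architecture(tes, g, cfg)$category,
               "TES_ASSOCIATED")

  # genes shorter than twice the window shrink it (and say so)
  short <- mk_genes(100000, 107000, strand = "+")
  expect_message(
    cl3 <- classify_architecture(mk_sites(99800, 100400), short, cfg),
    "shrunk")
  expect_equal(cl3$category, "TSS_ASSOCIATED")
})

test_that("classification is invariant under strand mirror of the locus", {
  cfg <- architecture_config()
  M <- 10000000L
  withr::with_seed(13, {
    for (trial in 1:25) {
      gs <- sample.int(4e6, 1) + 1e6
      gl <- sample(21000:80000, 1)
      g <- mk_genes(gs, gs + gl, strand = sample(c("+", "-"), 1))
      k <- sample(1:4, 1)
      ss <- gs + sample((-30000):(gl + 30000), k)
      sites <- mk_sites(ss, ss + sample(800:4000, k, TRUE))
      cl <- suppressMessages(classify_architecture(sites, g, cfg))
      # reflect every coordinate and flip the strand
      gm <- mk_genes(M - end(g), M - start(g),
                     strand = if (as.character(strand(g)) == "+") "-"
                     else "+")
      sm <- mk_sites(M - end(sites), M - start(sites))
      clm <- suppressMessages(classify_architecture(sm, gm, cfg))
      expect_equal(clm$category, cl$category, info = paste("trial", trial))
      expect_equal(clm$subcategory, cl$subcategory)
    }
  })
})

test_that("category proportions cover non-ambiguous calls and sum to one", {
  expect_equal(category_proportions(data.frame(category = character()))$n, 0L)
  calls <- data.frame(category = c("TSS_ASSOCIATED", "TSS_ASSOCIATED",
                                   "TES_ASSOCIATED", "BOTH_ENDS",
                                   "AMBIGUOUS"))
  cp <- category_proportions(calls)
  expect_equal(unname(cp$proportions),
               c(0.5, 0.25, 0.25))
  expect_equal(cp$n_ambiguous, 1L)
  expect_equal(sum(cp$proportions), 1, tolerance = 1e-9)

  all_tss <- data.frame(category = rep("TSS_ASSOCIATED", 10))
  expect_equal(category_proportions(all_tss)$proportions[["TSS_ASSOCIATED"]],
               1.0)
})

test_that("spacing regularity scores even arrays as 1 and applies min_peaks", {
  even <- peak_track("c", c(1, 1001, 2001, 3001), c(10, 1010, 2010, 3010),
                     summit = 0)
  r <- spacing_regularity(even)
  expect_equal(r$mean_gap, 1000)
  expect_equal(r$regularity, 1.0)

  unev <- peak_track("c", c(1, 801, 2001, 3201), c(5, 805, 2005, 3205),
                     summit = 0)
  r2 <- spacing_regularity(unev)
  g <- c(800, 1200, 1200)
  expect_equal(r2$mean_gap, mean(g))
  expect_equal(r2$regularity, 1 - sd(g) / mean(g))

  expect_null(spacing_regularity(even[1:3], min_peaks = 4))
})
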