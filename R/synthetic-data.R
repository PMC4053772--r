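# Fully labelled synthetic peak-landscape generator. Emulates the structure
# of the study design -- 5 PRC1 factor tracks (CBX6/7/8, RING1/RING2) x 2
# replicates x 2 fibroblast strains, H3K27me3/H3K4me3 tracks, duplicate RNA
# count tables per strain, plus a senescent condition -- with planted target
# labels, architecture categories and activity flags for recovery testing.

#' Generator configuration
#'
#' Defaults encode the study conditions: the architecture-category mix
#' (about 66% TSS-associated, 15.5% TES-associated, 18% both ends, the
#' remainder ambiguous constructs), a shared/strain-specific split of target
#' loci echoing 685 shared / 301 A-unique / 414 B-unique, a 28% active
#' fraction among targets against a 47% genome-wide active rate, a 38%
#' H3K4me3-at-TSS fraction among targets, and a global senescence score
#' scale of 0.6 applied to the second strain's peaks.
#'
#' @param n_genes number of annotated genes.
#' @param n_targets number of distinct planted target loci (union over the
#'   two strains).
#' @param category_mix named fractions for `TSS_ASSOCIATED`,
#'   `TES_ASSOCIATED`, `BOTH_ENDS`; the remainder of 1 becomes ambiguous
#'   closely-linked gene-pair constructs.
#' @param both_ends_distributed_fraction fraction of `BOTH_ENDS` loci with
#'   peaks upstream, downstream and within the transcription unit
#'   (`DISTRIBUTED`); the rest are `FLANKING_DISCRETE`.
#' @param shared_fraction,unique_a_fraction,unique_b_fraction split of
#'   target loci into shared and strain-specific sets (must sum to 1).
#' @param active_target_fraction probability that a target locus is
#'   transcriptionally active in a strain.
#' @param background_active_fraction genome-wide active fraction; the
#'   non-target activity rate is solved from it.
#' @param h3k4me3_target_fraction fraction of a strain's targets flagged
#'   with an H3K4me3 promoter peak (all active targets plus enough silent
#'   ones).
#' @param foothill_rate fraction of target loci receiving a weak flanking
#'   "foothill" peak (score below 30% of the local maximum).
#' @param periodic_array_rate fraction of `DISTRIBUTED` loci whose internal
#'   peaks form an evenly spaced array.
#' @param jitter_sd per-replicate summit jitter (bp, normal sd).
#' @param score_cv coefficient of variation of peak scores around the
#'   per-locus, per-factor mean (gamma noise).
#' @param senescence_scale global score multiplier for the senescent
#'   condition (locations unchanged).
#' @param count_threshold,count_dispersion,silent_mean,active_mean
#'   negative-binomial read-count model: silent genes draw counts with mean
#'   `silent_mean` (below threshold in at least one replicate, enforced),
#'   active genes with mean `active_mean` (at or above threshold in every
#'   replicate, enforced).
#' @param noncoding_fraction fraction of non-target genes annotated as
#'   noncoding.
#' @param decoy_rate per-class rate of decoy non-target loci carrying
#'   incomplete factor combinations (CBX only, RING only, CBX+RING without
#'   H3K27me3, H3K27me3 only) that must not be called.
#' @param samples two strain labels.
#' @param n_replicates ChIP replicates per track.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 2000L,
                             n_targets = 1000L,
                             category_mix = c(TSS_ASSOCIATED = 0.66,
                                              TES_ASSOCIATED = 0.155,
                                              BOTH_ENDS = 0.18),
                             both_ends_distributed_fraction = 0.6,
                             shared_fraction = 685 / 1400,
                             unique_a_fraction = 301 / 1400,
                             unique_b_fraction = 414 / 1400,
                             active_target_fraction = 0.28,
                             background_active_fraction = 0.47,
                             h3k4me3_target_fraction = 0.38,
                             foothill_rate = 0.1,
                             periodic_array_rate = 0.25,
                             jitter_sd = 50,
                             score_cv = 0.2,
                             senescence_scale = 0.6,
                             count_threshold = 10L,
                             count_dispersion = 0.1,
                             silent_mean = 1,
                             active_mean = 100,
                             noncoding_fraction = 0.05,
                             decoy_rate = 0.05,
                             samples = c("BF", "Hs68"),
                             n_replicates = 2L) {
  cfg <- as.list(environment())
  fr <- c(category_mix, shared_fraction, unique_a_fraction, unique_b_fraction,
          active_target_fraction, background_active_fraction,
          h3k4me3_target_fraction, foothill_rate, periodic_array_rate,
          both_ends_distributed_fraction, noncoding_fraction, decoy_rate)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (sum(category_mix) > 1 + 1e-9) stop("category_mix must sum to <= 1")
  if (abs(shared_fraction + unique_a_fraction + unique_b_fraction - 1) > 1e-6)
    stop("shared/unique fractions must sum to 1")
  if (n_targets > n_genes) stop("infeasible config: n_targets > n_genes")
  if (length(samples) != 2L) stop("exactly two strain labels are required")
  if (n_replicates < 2L) stop("the design uses >= 2 replicates")
  if (senescence_scale <= 0) stop("senescence_scale must be > 0")
  structure(cfg, class = "generator_config")
}

safe_sample <- function(x, k) x[sample.int(length(x), k)]

SLOT <- 100000L        # per-gene genomic slot
GENE_OFFSET <- 30000L  # gene start within its slot
PRC1_FACTORS <- list(CBX = c("CBX6", "CBX7", "CBX8"),
                     RING = c("RING1", "RING2"))

#' Generate a synthetic labelled dataset
#'
#' Writes a complete dataset directory -- narrowPeak files per
#' factor/replicate/strain (plus a senescent condition of the second
#' strain), H3K27me3/H3K4me3 tracks, duplicate count tables per strain, a
#' GTF gene annotation, a peak-file manifest, a factor registry and a truth
#' table -- and returns the planted ground truth. Deterministic given
#' `seed`; rerunning with the same seed reproduces every file byte for
#' byte.
#'
#' @param config a [generator_config()].
#' @param seed integer RNG seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list of class `synthetic_truth`: `config`, `seed`,
#'   `genes` (`GRanges`), `labels` (per-gene truth `data.frame`), `clusters`
#'   (planted cluster table), `arrays` (planted periodic-array summits),
#'   `manifest` (peak-file table), `files` (named paths).
#' @export
generate_dataset <- function(config = generator_config(), seed, dir) {
  stopifnot(inherits(config, "generator_config"))
  truth <- withr::with_seed(as.integer(seed), plan_truth(config))
  truth$seed <- as.integer(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- withr::with_seed(as.integer(seed) + 1L,
                            write_dataset(truth, config, dir))
  invisible(truth)
}

# ---- planning ---------------------------------------------------------------

plan_truth <- function(cfg) {
  n <- cfg$n_genes
  # counts per category (TSS absorbs rounding); ambiguous pairs need 2 genes
  n_amb <- 2L * floor((1 - sum(cfg$category_mix)) * cfg$n_targets / 2)
  n_tes <- round(cfg$category_mix[["TES_ASSOCIATED"]] * cfg$n_targets)
  n_both <- round(cfg$category_mix[["BOTH_ENDS"]] * cfg$n_targets)
  n_tss <- cfg$n_targets - n_tes - n_both - n_amb
  if (n_tss < 0) stop("infeasible config: category_mix incompatible with n_targets")

  # gene layout on 3 chromosomes; ambiguous pairs live in consecutive slots
  per_chr <- diff(round(seq(0, n, length.out = 4)))
  chrom <- rep(paste0("chrS", 1:3), per_chr)
  slot_idx <- unlist(lapply(per_chr, seq_len))
  slot_start <- (slot_idx - 1L) * SLOT
  glen <- as.integer(round(runif(n, 24000, 40000)))
  gstart <- slot_start + GENE_OFFSET + 1L # 1-based
  strand <- sample(c("+", "-"), n, replace = TRUE)

  # choose target genes: ambiguous pairs occupy consecutive same-chromosome
  # slots; all targets are coding
  ord <- sample.int(n)
  pair_first <- ord[which(chrom[ord] == chrom[pmin(ord + 1L, n)] &
                            (ord + 1L) <= n)]
  pair_first <- pair_first[!duplicated(pmin(pair_first, pair_first + 1L))]
  amb_first <- integer()
  if (n_amb > 0) {
    # greedily pick non-adjacent pair starts
    taken <- logical(n)
    for (p in pair_first) {
      if (length(amb_first) * 2L >= n_amb) break
      if (!taken[p] && !taken[p + 1L]) {
        amb_first <- c(amb_first, p)
        taken[pmax(1L, p - 1L):pmin(n, p + 2L)] <- TRUE
      }
    }
    if (length(amb_first) * 2L < n_amb)
      stop("infeasible config: cannot place ambiguous gene pairs")
  }
  amb_genes <- sort(c(amb_first, amb_first + 1L))
  remaining <- setdiff(ord, amb_genes)
  n_plain <- n_tss + n_tes + n_both
  if (length(remaining) < n_plain)
    stop("infeasible config: planted loci cannot fit the gene layout")
  plain <- remaining[seq_len(n_plain)]
  category <- rep(NA_character_, n)
  category[plain] <- rep(c("TSS_ASSOCIATED", "TES_ASSOCIATED", "BOTH_ENDS"),
                         c(n_tss, n_tes, n_both))
  category[amb_genes] <- "AMBIGUOUS"
  targets <- sort(c(plain, amb_genes))

  # ambiguous pairs: shorten genes and butt the second against the first
  for (p in amb_first) {
    glen[c(p, p + 1L)] <- 24000L
    gstart[p + 1L] <- gstart[p] + glen[p] + 4000L
  }
  gend <- gstart + glen - 1L

  is_target <- seq_len(n) %in% targets
  biotype <- rep("coding", n)
  nt <- which(!is_target)
  biotype[safe_sample(nt, round(cfg$noncoding_fraction * length(nt)))] <-
    "noncoding"

  subcategory <- rep(NA_character_, n)
  both_idx <- which(category == "BOTH_ENDS")
  n_dist <- round(cfg$both_ends_distributed_fraction * length(both_idx))
  dist_idx <- safe_sample(both_idx, n_dist)
  subcategory[both_idx] <- "FLANKING_DISCRETE"
  subcategory[dist_idx] <- "DISTRIBUTED"
  periodic <- rep(FALSE, n)
  periodic[dist_idx] <- runif(length(dist_idx)) < cfg$periodic_array_rate
  foothill <- rep(FALSE, n)
  foothill[targets] <- runif(length(targets)) < cfg$foothill_rate

  # shared / strain-specific split (pairs kept together in the shared set)
  n_sh <- round(cfg$shared_fraction * cfg$n_targets)
  n_ua <- round(cfg$unique_a_fraction * cfg$n_targets)
  n_ub <- cfg$n_targets - n_sh - n_ua
  pool <- setdiff(targets, amb_genes)
  pool <- pool[sample.int(length(pool))]
  n_sh_plain <- n_sh - n_amb
  if (n_sh_plain < 0 || n_ua < 0 || n_ub < 0)
    stop("infeasible config: shared/unique split incompatible with n_targets")
  shared <- c(amb_genes, pool[seq_len(n_sh_plain)])
  ua <- pool[n_sh_plain + seq_len(n_ua)]
  ub <- pool[n_sh_plain + n_ua + seq_len(n_ub)]
  in_a <- seq_len(n) %in% c(shared, ua)
  in_b <- seq_len(n) %in% c(shared, ub)

  # per-strain PRC1 factor membership at each target locus
  memb <- list()
  for (s in 1:2) {
    inx <- if (s == 1) in_a else in_b
    memb[[s]] <- lapply(seq_len(n), function(g) {
      if (!inx[g]) return(character())
      ncbx <- sample(1:3, 1, prob = c(0.1, 0.2, 0.7))
      nring <- sample(1:2, 1, prob = c(0.25, 0.75))
      c(sort(sample(PRC1_FACTORS$CBX, ncbx)),
        sort(sample(PRC1_FACTORS$RING, nring)))
    })
  }

  # activity labels and H3K4me3 flags per strain
  active <- h3k4 <- matrix(FALSE, n, 2)
  for (s in 1:2) {
    inx <- if (s == 1) in_a else in_b
    n_t <- sum(inx)
    q <- (cfg$background_active_fraction * n -
            cfg$active_target_fraction * n_t) / (n - n_t)
    if (q < 0 || q > 1)
      stop("infeasible config: background_active_fraction unattainable ",
           "given the target activity rate (solved non-target rate ",
           round(q, 3), ")")
    active[inx, s] <- runif(n_t) < cfg$active_target_fraction
    active[!inx, s] <- runif(n - n_t) < q
    tg <- which(inx)
    n_flag <- round(cfg$h3k4me3_target_fraction * n_t)
    act_t <- tg[active[tg, s]]
    sil_t <- tg[!active[tg, s]]
    extra <- max(0L, n_flag - length(act_t))
    h3k4[c(act_t, safe_sample(sil_t, min(extra, length(sil_t)))), s] <- TRUE
  }

  # decoy loci with incomplete factor combinations
  decoy <- rep(NA_character_, n)
  dpool <- which(!is_target & biotype == "coding")
  dpool <- dpool[sample.int(length(dpool))]
  n_dec <- round(cfg$decoy_rate * length(nt))
  kinds <- c("CBX_ONLY", "RING_ONLY", "NO_MARK", "MARK_ONLY")
  take <- seq_len(min(4L * n_dec, length(dpool)))
  decoy[dpool[take]] <- rep(kinds, length.out = length(take))

  # planted site clusters (positions shared between strains)
  clusters <- plan_clusters(cfg, seq_len(n), category, subcategory, periodic,
                            foothill, gstart, gend, strand, chrom, amb_first)

  genes <- GRanges(chrom, IRanges(gstart, gend), strand = strand)
  mcols(genes) <- DataFrame(
    gene_id = sprintf("G%05d", seq_len(n)),
    name = sprintf("G%05d", seq_len(n)),
    biotype = biotype
  )
  plus <- strand == "+"
  genes$tss <- ifelse(plus, gstart, gend)
  genes$tes <- ifelse(plus, gend, gstart)

  labels <- data.frame(
    gene_id = genes$gene_id, name = genes$name, biotype = biotype,
    is_target = is_target, category = category, subcategory = subcategory,
    in_a = in_a, in_b = in_b,
    n_prc1_a = vapply(memb[[1]], length, 1L),
    n_prc1_b = vapply(memb[[2]], length, 1L),
    active_a = active[, 1], active_b = active[, 2],
    h3k4_a = h3k4[, 1], h3k4_b = h3k4[, 2],
    periodic = periodic, foothill = foothill, decoy = decoy,
    stringsAsFactors = FALSE
  )
  structure(list(config = cfg, genes = genes, labels = labels,
                 clusters = clusters$clusters, arrays = clusters$arrays,
                 members_a = memb[[1]], members_b = memb[[2]]),
            class = "synthetic_truth")
}

# plant cluster centers per locus; returns a cluster table plus periodic
# array summits
plan_clusters <- function(cfg, gidx, category, subcategory, periodic,
                          foothill, gstart, gend, strand, chrom, amb_first) {
  rows <- list()
  arrays <- list()
  dirn <- ifelse(strand == "+", 1L, -1L)
  tss <- ifelse(strand == "+", gstart, gend)
  tes <- ifelse(strand == "+", gend, gstart)
  add <- function(g, center, width, kind, mark_pad = 1500L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = g, chrom = chrom[g], center = as.integer(round(center)),
      width = as.integer(width), kind = kind, mark_pad = mark_pad)
  }
  for (g in gidx) {
    cat <- category[g]
    if (is.na(cat)) next
    d <- dirn[g]
    if (cat == "TSS_ASSOCIATED") {
      add(g, tss[g] + round(runif(1, -8000, 8000)), round(runif(1, 1800, 3000)),
          "main")
    } else if (cat == "TES_ASSOCIATED") {
      add(g, tes[g] + round(runif(1, -8000, 8000)), round(runif(1, 1800, 3000)),
          "main")
    } else if (cat == "BOTH_ENDS") {
      add(g, tss[g] - d * round(runif(1, 2500, 6000)), round(runif(1, 1600, 2000)),
          "flank")
      add(g, tes[g] + d * round(runif(1, 2500, 6000)), round(runif(1, 1600, 2000)),
          "flank")
      if (identical(subcategory[g], "DISTRIBUTED")) {
        L <- gend[g] - gstart[g] + 1L
        c3 <- tss[g] + d * round(L * runif(1, 0.42, 0.58))
        if (periodic[g]) {
          k <- sample(4:5, 1)
          gap <- round(runif(1, 1700, 2100))
          summits <- as.integer(round(c3 + (seq_len(k) - (k + 1) / 2) * gap))
          arrays[[length(arrays) + 1L]] <-
            data.frame(gene = g, chrom = chrom[g], summit = summits)
          add(g, c3, max(summits) - min(summits) + 1000L, "array", 2000L)
        } else {
          add(g, c3, round(runif(1, 1800, 3000)), "internal")
        }
      }
    } else if (cat == "AMBIGUOUS" && g %in% amb_first) {
      mid <- (gend[g] + gstart[g + 1L]) / 2
      add(g, mid, (gstart[g + 1L] - gend[g] - 1L) + 4000L, "ambiguous")
    }
    if (foothill[g] && cat != "AMBIGUOUS") {
      first <- rows[[length(rows)]] # attach to the locus's last cluster
      add(g, first$center + sample(c(-1L, 1L), 1) * 2400L, 1600L, "foothill",
          0L)
    }
  }
  empty_cl <- data.frame(gene = integer(), chrom = character(),
                         center = integer(), width = integer(),
                         kind = character(), mark_pad = integer())
  list(clusters = if (length(rows)) do.call(rbind, rows) else empty_cl,
       arrays = if (length(arrays)) do.call(rbind, arrays) else
         data.frame(gene = integer(), chrom = character(), summit = integer()))
}

# ---- realization: peaks, counts, files --------------------------------------

write_dataset <- function(truth, cfg, dir) {
  genes <- truth$genes
  lab <- truth$labels
  cl <- truth$clusters
  n <- length(genes)
  samples <- cfg$samples
  shape <- 1 / cfg$score_cv^2

  # per (gene, factor) score means, shared across strains and replicates
  all_factors <- unlist(PRC1_FACTORS, use.names = FALSE)
  mu <- matrix(runif(n * length(all_factors), 8, 40), n,
               dimnames = list(NULL, all_factors))
  muv <- function(g, facs) mu[cbind(g, match(facs, colnames(mu)))]

  peak_rows <- list()
  emit <- function(df) peak_rows[[length(peak_rows) + 1L]] <<- df

  for (si in 1:2) {
    s <- samples[si]
    memb <- if (si == 1) truth$members_a else truth$members_b
    inx <- if (si == 1) lab$in_a else lab$in_b
    # PRC1 peaks at planted clusters
    tcl <- cl[inx[cl$gene], , drop = FALSE]
    for (r in seq_len(cfg$n_replicates)) {
      for (ci in seq_len(nrow(tcl))) {
        g <- tcl$gene[ci]
        facs <- memb[[g]]
        if (tcl$kind[ci] == "foothill")
          facs <- facs[seq_len(min(2L, length(facs)))]
        if (!length(facs)) next
        if (tcl$kind[ci] == "array") {
          ar <- truth$arrays[truth$arrays$gene == g, , drop = FALSE]
          kpos <- rep(ar$summit, each = length(facs))
          kfac <- rep(facs, times = nrow(ar))
          w <- round(runif(length(kpos), 900, 1200))
          summ <- round(kpos + rnorm(length(kpos), 0, cfg$jitter_sd))
          sc <- rgamma(length(kpos), shape, shape / muv(g, kfac))
        } else {
          kfac <- facs
          w <- round(runif(length(kfac), 0.8 * tcl$width[ci],
                           1.1 * tcl$width[ci]))
          summ <- round(tcl$center[ci] + rnorm(length(kfac), 0, cfg$jitter_sd))
          base <- muv(g, kfac)
          if (tcl$kind[ci] == "foothill")
            base <- base * runif(length(kfac), 0.05, 0.2)
          sc <- rgamma(length(kfac), shape, shape / base)
        }
        st <- as.integer(summ - floor(w / 2))
        emit(data.frame(sample = s, factor = kfac, replicate = r,
                        chrom = tcl$chrom[ci], start = st,
                        end = as.integer(st + w - 1L),
                        score = sc, summit = as.integer(floor(w / 2))))
      }
    }
    # decoy peaks: incomplete factor combinations near non-target TSSs
    dec <- which(!is.na(lab$decoy))
    if (length(dec)) {
      dfacs <- list(CBX_ONLY = "CBX7", RING_ONLY = "RING1",
                    NO_MARK = c("CBX7", "RING1"), MARK_ONLY = character())
      for (r in seq_len(cfg$n_replicates)) {
        for (g in dec) {
          facs <- dfacs[[lab$decoy[g]]]
          if (!length(facs)) next
          w <- round(runif(length(facs), 1500, 2500))
          summ <- round(genes$tss[g] + rnorm(length(facs), 0, cfg$jitter_sd))
          st <- as.integer(summ - floor(w / 2))
          emit(data.frame(sample = s, factor = facs, replicate = r,
                          chrom = as.character(seqnames(genes))[g],
                          start = st, end = as.integer(st + w - 1L),
                          score = rgamma(length(facs), shape,
                                         shape / muv(g, facs)),
                          summit = as.integer(floor(w / 2))))
        }
      }
    }
    # H3K27me3: one domain per planted cluster (skip foothills), plus
    # mark-only decoys
    mcl <- tcl[tcl$kind != "foothill", , drop = FALSE]
    mark_only <- which(!is.na(lab$decoy) & lab$decoy == "MARK_ONLY")
    for (r in seq_len(cfg$n_replicates)) {
      if (nrow(mcl)) {
        half <- floor(mcl$width / 2) + mcl$mark_pad
        st <- as.integer(mcl$center - half + round(rnorm(nrow(mcl), 0, 25)))
        en <- as.integer(mcl$center + half + round(rnorm(nrow(mcl), 0, 25)))
        emit(data.frame(sample = s, factor = "H3K27me3", replicate = r,
                        chrom = mcl$chrom, start = st, end = en,
                        score = rgamma(nrow(mcl), shape, shape / 15),
                        summit = as.integer(floor((en - st) / 2))))
      }
      if (length(mark_only)) {
        w <- round(runif(length(mark_only), 3000, 5000))
        st2 <- as.integer(genes$tss[mark_only] - floor(w / 2))
        emit(data.frame(
          sample = s, factor = "H3K27me3", replicate = r,
          chrom = as.character(seqnames(genes))[mark_only],
          start = st2, end = as.integer(st2 + w - 1L),
          score = rgamma(length(mark_only), shape, shape / 15),
          summit = as.integer(floor(w / 2))))
      }
    }
    # H3K4me3 at flagged target TSSs and active non-target TSSs
    flag <- if (si == 1) lab$h3k4_a else lab$h3k4_b
    act <- if (si == 1) lab$active_a else lab$active_b
    k4 <- which(flag | (act & !inx))
    for (r in seq_len(cfg$n_replicates)) {
      if (!length(k4)) break
      w <- round(runif(length(k4), 1600, 2200))
      st <- as.integer(genes$tss[k4] - floor(w / 2) +
                         round(rnorm(length(k4), 0, 25)))
      emit(data.frame(sample = s, factor = "H3K4me3", replicate = r,
                      chrom = as.character(seqnames(genes))[k4],
                      start = st, end = as.integer(st + w - 1L),
                      score = rgamma(length(k4), shape, shape / 20),
                      summit = as.integer(floor(w / 2))))
    }
  }
  peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else
    data.frame(sample = character(), factor = character(),
               replicate = integer(), chrom = character(), start = integer(),
               end = integer(), score = numeric(), summit = integer())
  peaks$start <- pmax(1L, peaks$start)

  # senescent condition: second strain's peaks, scores scaled, locations kept
  sen <- peaks[peaks$sample == samples[2], , drop = FALSE]
  sen$sample <- paste0(samples[2], "_senescent")
  sen$score <- sen$score * cfg$senescence_scale
  peaks <- rbind(peaks, sen)

  # write peak files + manifest
  peak_dir <- file.path(dir, "peaks")
  dir.create(peak_dir, showWarnings = FALSE)
  registry <- default_factor_registry()
  man <- unique(peaks[, c("sample", "factor", "replicate")])
  man <- man[order(man$sample, man$factor, man$replicate), , drop = FALSE]
  man$class <- unname(registry[man$factor])
  man$path <- file.path("peaks", sprintf("%s_%s_rep%d.narrowPeak",
                                         man$sample, man$factor,
                                         man$replicate))
  for (i in seq_len(nrow(man))) {
    sel <- peaks$sample == man$sample[i] & peaks$factor == man$factor[i] &
      peaks$replicate == man$replicate[i]
    p <- peaks[sel, , drop = FALSE]
    p <- p[order(p$chrom, p$start, p$end), , drop = FALSE]
    gr <- peak_track(p$chrom, p$start, p$end, score = p$score,
                     summit = p$summit, factor = man$factor[i],
                     sample = man$sample[i],
                     replicate = as.character(man$replicate[i]))
    write_peaks(gr, file.path(dir, man$path[i]), format = "narrowPeak")
  }
  manifest <- man[, c("path", "factor", "class", "sample", "replicate")]
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(factor = names(registry),
                         class = unname(registry)),
              file.path(dir, "registry.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # annotation
  write_genes_gtf(genes, file.path(dir, "genes.gtf"))

  # duplicate count tables per strain, honouring the planted activity labels
  for (si in 1:2) {
    act <- if (si == 1) lab$active_a else lab$active_b
    cnt <- sapply(seq_len(cfg$n_replicates), function(r)
      draw_counts(act, cfg))
    for (r in seq_len(cfg$n_replicates)) { # enforce label consistency
      low <- act & cnt[, r] < cfg$count_threshold
      cnt[low, r] <- cfg$count_threshold + rpois(sum(low), 2)
    }
    viol <- !act & rowSums(cnt >= cfg$count_threshold) == ncol(cnt)
    cnt[viol, 1] <- cfg$count_threshold - 1L
    tab <- data.frame(gene_id = lab$gene_id, cnt)
    names(tab)[-1] <- paste0("rep", seq_len(cfg$n_replicates))
    write.table(tab, file.path(dir, sprintf("counts_%s.tsv", samples[si])),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  truth$manifest <- manifest
  truth$files <- c(
    manifest = file.path(dir, "manifest.tsv"),
    registry = file.path(dir, "registry.tsv"),
    genes = file.path(dir, "genes.gtf"),
    setNames(file.path(dir, sprintf("counts_%s.tsv", samples)),
             paste0("counts_", samples)),
    truth = file.path(dir, "truth.json"),
    truth_table = file.path(dir, "truth_table.tsv")
  )
  truth$dir <- dir

  jsonlite::write_json(
    list(seed = truth$seed,
         samples = samples,
         labels = truth$labels,
         clusters = truth$clusters,
         arrays = truth$arrays),
    file.path(dir, "truth.json"), dataframe = "columns", auto_unbox = TRUE,
    digits = NA, na = "null")
  truth_table(truth, file.path(dir, "truth_table.tsv"))
  truth
}

draw_counts <- function(active, cfg) {
  mu <- ifelse(active, cfg$active_mean, cfg$silent_mean)
  rnbinom(length(mu), size = 1 / cfg$count_dispersion, mu = mu)
}

#' Planted-truth table in the per-locus output schema
#'
#' One row per planted target locus, alphabetical by gene name: the number
#' of PRC1 proteins planted at the locus in each strain, the architecture
#' category/subcategory and TRUE/FALSE transcriptional-activity flags per
#' strain. Enables exact diffing against the pipeline's output table.
#'
#' @param truth a `synthetic_truth` from [generate_dataset()].
#' @param path optional TSV output path.
#' @return The table (`data.frame`); invisibly when written.
#' @export
truth_table <- function(truth, path = NULL) {
  lab <- truth$labels
  s <- truth$config$samples
  t <- lab[lab$is_target, , drop = FALSE]
  out <- data.frame(
    gene_id = t$gene_id, name = t$name,
    stringsAsFactors = FALSE
  )
  out[[paste0("n_prc1_factors_", s[1])]] <- t$n_prc1_a
  out[[paste0("n_prc1_factors_", s[2])]] <- t$n_prc1_b
  out$category <- t$category
  out$subcategory <- t$subcategory
  out[[paste0("active_", s[1])]] <- toupper(as.character(t$active_a))
  out[[paste0("active_", s[2])]] <- toupper(as.character(t$active_b))
  out <- out[order(out$name, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
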