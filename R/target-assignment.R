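# Assign co-occupancy sites to candidate target genes by nearest TSS (with a
# coding-gene preference) and classify each target's peak architecture
# relative to the TSS and TES of the transcription unit.

CATEGORIES <- c("TSS_ASSOCIATED", "TES_ASSOCIATED", "BOTH_ENDS", "AMBIGUOUS")
SUBCATEGORIES <- c("FLANKING_DISCRETE", "INTERNAL", "DISTRIBUTED")

#' Architecture-classification configuration
#'
#' @param end_window bp within which a site counts as "at" the TSS or TES.
#'   Default 10 kb, the conventional promoter-proximal range in this type of
#'   analysis; kept configurable because observed peak-to-TSS distances reach
#'   hundreds of kb.
#' @param body_overlap_fraction minimum fraction of a site's span inside the
#'   gene body for the site to count as internal; default 0.5.
#' @param max_assignment_distance cap (bp) on the site-to-TSS distance for
#'   assignment; default `Inf` (unbounded) -- distances are always reported
#'   so users can filter downstream.
#' @param reference_point `"midpoint"` (default) or `"summit"`: the point of
#'   a site used for distance computation. Co-occupancy sites aggregate many
#'   antibodies' peaks, so the midpoint is the default.
#' @return A list of class `architecture_config`.
#' @export
architecture_config <- function(end_window = 10000L,
                                body_overlap_fraction = 0.5,
                                max_assignment_distance = Inf,
                                reference_point = c("midpoint", "summit")) {
  if (end_window <= 0) stop("end_window must be > 0")
  if (body_overlap_fraction <= 0 || body_overlap_fraction > 1)
    stop("body_overlap_fraction must be in (0, 1]")
  structure(list(end_window = as.integer(end_window),
                 body_overlap_fraction = body_overlap_fraction,
                 max_assignment_distance = max_assignment_distance,
                 reference_point = match.arg(reference_point)),
            class = "architecture_config")
}

site_refpoints <- function(sites, config) {
  # summit mode falls back to the midpoint: co-occupancy sites have no
  # single summit; midpoint of the merged span in either mode
  as.integer(floor((start(sites) + end(sites)) / 2))
}

#' Assign co-occupancy sites to candidate target genes
#'
#' Each site is assigned to the gene whose TSS is nearest to the site
#' reference point (midpoint), with two exceptions: (a) when a site overlaps
#' both a coding and a noncoding gene body, the coding gene wins regardless
#' of TSS distance; (b) when a site overlaps the bodies of two or more
#' closely linked genes (bodies within `2 * end_window` of each other), the
#' peaks cannot be attributed to a specific locus and every involved gene is
#' classified `AMBIGUOUS` -- genes already resolved by the coding preference
#' (noncoding genes under a mixed overlap) do not participate. Sites assigned to the same gene are grouped into
#' one target call and the peak architecture of each call is classified (see
#' Details). Sites on chromosomes without any annotated gene are reported in
#' the `"unassigned"` attribute, not dropped silently.
#'
#' @details
#' Architecture categories, per target gene: sites within `end_window` of
#' the TSS (TES) form the TSS (TES) cluster. Both clusters non-empty gives
#' `BOTH_ENDS`; a TES cluster only, or no cluster at all but the TES
#' strictly nearer than the TSS, gives `TES_ASSOCIATED`; everything else is
#' `TSS_ASSOCIATED`. `BOTH_ENDS` calls are sub-classified:
#' `FLANKING_DISCRETE` when no site overlaps the gene body by at least
#' `body_overlap_fraction`; `INTERNAL` when all sites lie inside the body
#' and none within `end_window` of either end; otherwise `DISTRIBUTED`.
#' Genes shorter than `2 * end_window` are classified with the window shrunk
#' to half the gene length (flagged in the `end_window_shrunk` column).
#'
#' @param sites a `GRanges` of co-occupancy sites ([call_cooccupancy()]).
#' @param genes a `GRanges` of gene models ([read_genes()]).
#' @param config an [architecture_config()].
#' @return A `data.frame` with one row per target gene: `gene_id`, `name`,
#'   `category`, `subcategory` (`NA` unless `BOTH_ENDS`), `distance_to_tss`,
#'   `distance_to_tes` (signed bp, TSS/TES minus site reference point, `NA`
#'   for `AMBIGUOUS`), `n_prc1_factors`, `n_sites`, `end_window_shrunk`, and
#'   a list column `sites` of owned site indices into `sites`. Attribute
#'   `"unassigned"`: integer indices of unassignable sites.
#' @export
assign_targets <- function(sites, genes, config = architecture_config()) {
  if (length(genes) == 0L) stop("genes must be non-empty")
  if (length(sites) == 0L) {
    out <- empty_calls()
    attr(out, "unassigned") <- integer()
    return(out)
  }
  ref <- site_refpoints(sites, config)
  schrom <- as.character(seqnames(sites))
  tss_tab <- data.frame(chrom = as.character(seqnames(genes)),
                        pos = genes$tss,
                        coding = genes$biotype == "coding",
                        id = genes$gene_id)
  nf <- nearest_feature(schrom, ref, tss_tab)
  gene_of <- nf$feature

  # exception (a): body overlap with both a coding and a noncoding gene
  ov <- findOverlaps(sites, genes, ignore.strand = TRUE)
  ov_genes <- splitAsList(subjectHits(ov),
                          factor(queryHits(ov), levels = seq_along(sites)))
  coding <- genes$biotype == "coding"
  for (i in seq_along(sites)) {
    g <- ov_genes[[i]]
    if (length(g) && any(coding[g]) && any(!coding[g])) {
      gc <- g[coding[g]]
      d <- abs(genes$tss[gc] - ref[i])
      o <- order(d, genes$gene_id[gc])
      gene_of[i] <- gc[o[1L]]
    }
  }

  # distance cap and unassigned sink
  dist_tss <- genes$tss[gene_of] - ref
  unassigned <- which(is.na(gene_of) |
                        abs(dist_tss) > config$max_assignment_distance)
  gene_of[unassigned] <- NA_integer_

  # exception (c): sites overlapping >= 2 closely linked gene bodies
  ambiguous_genes <- integer()
  amb_extra <- list() # gene index -> triggering site indices
  ew2 <- 2L * config$end_window
  for (i in seq_along(sites)) {
    g <- ov_genes[[i]]
    # genes resolved by the coding preference do not create ambiguity
    if (any(coding[g]) && any(!coding[g])) g <- g[coding[g]]
    if (length(g) < 2L) next
    # pairwise body gap within 2 * end_window
    gs <- start(genes)[g]; ge <- end(genes)[g]
    for (a in seq_along(g)[-length(g)]) for (b in seq((a + 1L), length(g))) {
      gapab <- max(gs[a], gs[b]) - min(ge[a], ge[b]) - 1L
      if (gapab <= ew2) {
        pair <- g[c(a, b)]
        ambiguous_genes <- union(ambiguous_genes, pair)
        for (gg in pair)
          amb_extra[[as.character(gg)]] <-
            union(amb_extra[[as.character(gg)]], i)
      }
    }
  }

  assigned <- which(!is.na(gene_of))
  by_gene <- split(assigned, gene_of[assigned])
  call_genes <- union(as.integer(names(by_gene)), ambiguous_genes)
  rows <- lapply(sort(call_genes), function(gi) {
    owned <- by_gene[[as.character(gi)]]
    if (is.null(owned)) owned <- integer()
    shown <- union(owned, amb_extra[[as.character(gi)]])
    g <- genes[gi]
    if (gi %in% ambiguous_genes) {
      cls <- list(category = "AMBIGUOUS", subcategory = NA_character_,
                  distance_to_tss = NA_real_, distance_to_tes = NA_real_,
                  end_window_shrunk = FALSE)
    } else {
      cls <- classify_architecture(sites[shown], g, config)
    }
    nf_fac <- length(unique(unlist(
      c(as.list(sites$cbx_members[shown]), as.list(sites$ring_members[shown])))))
    data.frame(gene_id = g$gene_id, name = g$name,
               category = cls$category, subcategory = cls$subcategory,
               distance_to_tss = cls$distance_to_tss,
               distance_to_tes = cls$distance_to_tes,
               n_prc1_factors = nf_fac,
               n_sites = length(shown),
               end_window_shrunk = cls$end_window_shrunk,
               sites = I(list(sort(shown))),
               owned_sites = I(list(sort(owned))),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty_calls()
  rownames(out) <- NULL
  attr(out, "unassigned") <- sort(unassigned)
  out
}

empty_calls <- function() {
  data.frame(gene_id = character(), name = character(),
             category = character(), subcategory = character(),
             distance_to_tss = numeric(), distance_to_tes = numeric(),
             n_prc1_factors = integer(), n_sites = integer(),
             end_window_shrunk = logical(),
             sites = I(list()), owned_sites = I(list()),
             stringsAsFactors = FALSE)
}

#' Classify the peak architecture of one target call
#'
#' See [assign_targets()] for the classification rule.
#'
#' @param call_sites `GRanges` of the sites assigned to the gene (non-empty).
#' @param gene a length-1 `GRanges` gene model.
#' @param config an [architecture_config()].
#' @return A list with `category`, `subcategory`, `distance_to_tss`,
#'   `distance_to_tes`, `end_window_shrunk`.
#' @export
classify_architecture <- function(call_sites, gene,
                                  config = architecture_config()) {
  stopifnot(length(call_sites) >= 1L, length(gene) == 1L)
  ref <- site_refpoints(call_sites, config)
  tss <- gene$tss
  tes <- gene$tes
  ew <- config$end_window
  glen <- width(gene)
  shrunk <- FALSE
  if (glen < 2L * ew) {
    ew <- as.integer(floor(glen / 2))
    shrunk <- TRUE
    message("gene ", gene$gene_id, " shorter than 2*end_window; ",
            "end_window shrunk to ", ew, " bp")
  }
  d_tss_all <- abs(ref - tss)
  d_tes_all <- abs(ref - tes)
  i_tss <- which.min(d_tss_all)
  i_tes <- which.min(d_tes_all)
  tss_cluster <- any(d_tss_all <= ew)
  tes_cluster <- any(d_tes_all <= ew)
  if (tss_cluster && tes_cluster) {
    category <- "BOTH_ENDS"
  } else if (tes_cluster ||
             (!tss_cluster && d_tes_all[i_tes] < d_tss_all[i_tss])) {
    category <- "TES_ASSOCIATED"
  } else {
    category <- "TSS_ASSOCIATED"
  }
  subcategory <- NA_character_
  if (category == "BOTH_ENDS") {
    ov_w <- pmax(0L, pmin(end(call_sites), end(gene)) -
                   pmax(start(call_sites), start(gene)) + 1L)
    frac <- ov_w / width(call_sites)
    inside <- start(call_sites) >= start(gene) & end(call_sites) <= end(gene)
    near_end <- d_tss_all <= ew | d_tes_all <= ew
    if (!any(frac >= config$body_overlap_fraction)) {
      subcategory <- "FLANKING_DISCRETE"
    } else if (all(inside) && !any(near_end)) {
      subcategory <- "INTERNAL"
    } else {
      subcategory <- "DISTRIBUTED"
    }
  }
  list(category = category, subcategory = subcategory,
       distance_to_tss = as.numeric(tss - ref[i_tss]),
       distance_to_tes = as.numeric(tes - ref[i_tes]),
       end_window_shrunk = shrunk)
}

#' Category proportions over a set of target calls
#'
#' Fractions are computed over non-`AMBIGUOUS` calls (they sum to 1);
#' `AMBIGUOUS` calls are counted separately.
#'
#' @param calls a target-call `data.frame` from [assign_targets()].
#' @return A list with `proportions` (named numeric over the three
#'   architecture categories), `n` (non-ambiguous call count) and
#'   `n_ambiguous`. Empty input gives an empty proportions table.
#' @export
category_proportions <- function(calls) {
  if (nrow(calls) == 0L)
    return(list(proportions = setNames(numeric(), character()),
                n = 0L, n_ambiguous = 0L))
  amb <- calls$category == "AMBIGUOUS"
  tab <- table(factor(calls$category[!amb],
                      levels = setdiff(CATEGORIES, "AMBIGUOUS")))
  n <- sum(!amb)
  list(proportions = if (n) setNames(as.numeric(tab) / n, names(tab))
       else setNames(numeric(3), names(tab)),
       n = n, n_ambiguous = sum(amb))
}

#' Spacing regularity of a peak array
#'
#' Peaks at some loci resolve into evenly spaced arrays suggesting
#' periodicity. This summary sorts the peaks by summit (falling back to the
#' midpoint when no summit is recorded), computes the successive summit
#' gaps, and scores regularity as `max(0, 1 - CV(gaps))` where `CV` is the
#' coefficient of variation; a perfectly even array scores 1.
#'
#' @param peaks a `GRanges` of peaks within one site/locus.
#' @param min_peaks minimum number of peaks for the statistic (default 4).
#' @return `NULL` when fewer than `min_peaks` peaks, else a list with
#'   `mean_gap` (bp) and `regularity` (in `[0, 1]`).
#' @export
spacing_regularity <- function(peaks, min_peaks = 4L) {
  if (length(peaks) < min_peaks) return(NULL)
  summit <- mcols(peaks)$summit
  if (is.null(summit)) summit <- rep(NA_integer_, length(peaks))
  pos <- ifelse(!is.na(summit),
                start(peaks) + as.integer(summit),
                as.integer(floor((start(peaks) + end(peaks)) / 2)))
  gaps <- diff(sort(pos))
  cv <- sd(gaps) / mean(gaps)
  list(mean_gap = mean(gaps), regularity = max(0, 1 - cv))
}

#' Write the per-locus target table
#'
#' One row per locus, sorted alphabetically by gene name, with the number of
#' PRC1 proteins identified at the locus in each sample, the architecture
#' category, distances, and (when expression flags are supplied) TRUE/FALSE
#' transcriptional-activity columns per sample.
#'
#' @param calls_by_sample named list (sample -> target-call `data.frame`).
#' @param active_by_sample optional named list (sample -> named logical
#'   vector of activity flags indexed by `gene_id`).
#' @param path output TSV path (`NULL` to return the table only).
#' @return The assembled `data.frame`, invisibly when written.
#' @export
write_target_table <- function(calls_by_sample, active_by_sample = NULL,
                               path = NULL) {
  all_ids <- sort(unique(unlist(lapply(calls_by_sample, `[[`, "gene_id"))))
  tab <- data.frame(gene_id = all_ids, stringsAsFactors = FALSE)
  nm <- character()
  for (cs in calls_by_sample) nm[cs$gene_id] <- cs$name
  tab$name <- unname(nm[tab$gene_id])
  for (s in names(calls_by_sample)) {
    cs <- calls_by_sample[[s]]
    m <- match(tab$gene_id, cs$gene_id)
    tab[[paste0("n_prc1_factors_", s)]] <-
      ifelse(is.na(m), 0L, cs$n_prc1_factors[m])
  }
  # category/subcategory/distances from the first sample carrying the locus
  pick <- rep(NA_integer_, nrow(tab)); pick_s <- rep(NA_integer_, nrow(tab))
  for (si in seq_along(calls_by_sample)) {
    m <- match(tab$gene_id, calls_by_sample[[si]]$gene_id)
    take <- is.na(pick) & !is.na(m)
    pick[take] <- m[take]; pick_s[take] <- si
  }
  get_field <- function(field) mapply(function(p, s)
    if (is.na(p)) NA else calls_by_sample[[s]][[field]][p], pick, pick_s)
  tab$category <- as.character(get_field("category"))
  tab$subcategory <- as.character(get_field("subcategory"))
  tab$distance_to_tss <- as.numeric(get_field("distance_to_tss"))
  tab$distance_to_tes <- as.numeric(get_field("distance_to_tes"))
  if (!is.null(active_by_sample)) {
    for (s in names(active_by_sample)) {
      fl <- active_by_sample[[s]]
      tab[[paste0("active_", s)]] <-
        toupper(as.character(ifelse(is.na(fl[tab$gene_id]), FALSE,
                                    fl[tab$gene_id])))
    }
  }
  tab <- tab[order(tab$name, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
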