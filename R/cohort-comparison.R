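# Compare target-gene sets between two samples (shared vs strain-specific
# targets) and quantify binding-profile concordance between two conditions
# (proliferating vs senescent).

#' Compare two target-gene sets
#'
#' Exact set arithmetic on gene ids, the gene-list analogue of a Venn
#' diagram of candidate targets in two cell types.
#'
#' @param calls_a,calls_b target-call `data.frame`s ([assign_targets()]) or
#'   character vectors of gene ids.
#' @return A list of class `overlap_result`: `shared`, `unique_a`,
#'   `unique_b` (character vectors) and `counts`, a named integer vector
#'   `(n_a, n_b, shared, unique_a, unique_b)` satisfying
#'   `n_a = shared + unique_a` and `n_b = shared + unique_b`.
#' @export
compare_targets <- function(calls_a, calls_b) {
  a <- unique(if (is.data.frame(calls_a)) calls_a$gene_id
              else as.character(calls_a))
  b <- unique(if (is.data.frame(calls_b)) calls_b$gene_id
              else as.character(calls_b))
  shared <- sort(intersect(a, b))
  ua <- sort(setdiff(a, b))
  ub <- sort(setdiff(b, a))
  counts <- c(n_a = length(a), n_b = length(b), shared = length(shared),
              unique_a = length(ua), unique_b = length(ub))
  stopifnot(counts[["n_a"]] == counts[["shared"]] + counts[["unique_a"]],
            counts[["n_b"]] == counts[["shared"]] + counts[["unique_b"]])
  structure(list(shared = shared, unique_a = ua, unique_b = ub,
                 counts = counts), class = "overlap_result")
}

#' Binding-profile concordance between two conditions
#'
#' Quantifies whether the binding landscape is preserved (locations) while
#' the signal is globally rescaled (read density), as between proliferating
#' and senescent cells. `location_overlap` is the fraction of sites in each
#' list overlapped by at least one site of the other; `density_ratio` is the
#' median, over reciprocal-best overlapping site pairs, of the B/A ratio of
#' maximum member-peak scores.
#'
#' @param sites_a,sites_b non-empty co-occupancy site `GRanges`
#'   ([call_cooccupancy()]) with a `max_score` column.
#' @return A list of class `concordance_result`: `location_overlap` (named
#'   numeric `c(a_in_b, b_in_a)`), `density_ratio` (`NA` when no sites
#'   match) and `n_matched`.
#' @export
profile_concordance <- function(sites_a, sites_b) {
  if (length(sites_a) == 0L || length(sites_b) == 0L)
    stop("profile_concordance requires non-empty site lists on both sides")
  ov_ab <- mean(countOverlaps(sites_a, sites_b, ignore.strand = TRUE) > 0L)
  ov_ba <- mean(countOverlaps(sites_b, sites_a, ignore.strand = TRUE) > 0L)
  hits <- findOverlaps(sites_a, sites_b, ignore.strand = TRUE)
  ratio <- NA_real_
  n_matched <- 0L
  if (length(hits)) {
    ovw <- width(pintersect(granges(sites_a)[queryHits(hits)],
                            granges(sites_b)[subjectHits(hits)],
                            ignore.strand = TRUE))
    o <- order(-ovw)
    h <- data.frame(a = queryHits(hits)[o], b = subjectHits(hits)[o])
    best_ab <- h[!duplicated(h$a), ]
    best_ba <- h[!duplicated(h$b), ]
    matched <- merge(best_ab, best_ba) # reciprocal best pairs
    n_matched <- nrow(matched)
    if (n_matched) {
      r <- sites_b$max_score[matched$b] / sites_a$max_score[matched$a]
      ratio <- median(r, na.rm = TRUE)
    }
  }
  structure(list(location_overlap = c(a_in_b = ov_ab, b_in_a = ov_ba),
                 density_ratio = ratio, n_matched = n_matched),
            class = "concordance_result")
}
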