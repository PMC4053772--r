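# From per-replicate, per-factor peak calls to per-factor binding regions
# and multi-factor co-occupancy sites satisfying the compilation criterion:
# at least one CBX, at least one RING protein and H3K27me3.

#' Merge replicate peak calls into per-factor binding regions
#'
#' All peaks must come from one factor and one sample. In `"union"` mode the
#' peaks of all replicates are pooled and gap-merged; each region records how
#' many distinct replicates contributed (`support`) and the maximum
#' contributing peak score (`max_score`). In `"intersection"` mode each
#' replicate's peaks are first gap-merged separately and only the bases
#' covered by at least two replicates are kept, so the output regions are
#' exactly the per-base ">= 2 replicates" set.
#'
#' @param peaks a `GRanges` of peaks for one factor/sample with `replicate`,
#'   `score`, `factor`, `sample` metadata (see [read_peaks()]).
#' @param mode `"union"` or `"intersection"`.
#' @param gap non-negative merge gap in bp.
#' @return A `GRanges` of binding regions with metadata `factor`, `sample`,
#'   `support`, `max_score`.
#' @export
merge_replicates <- function(peaks, mode = c("union", "intersection"),
                             gap = 0L) {
  mode <- match.arg(mode)
  if (gap < 0) stop("gap must be >= 0")
  fac <- unique(peaks$factor)
  smp <- unique(peaks$sample)
  if (length(fac) > 1L || length(smp) > 1L)
    stop("merge_replicates expects peaks from a single factor and sample; ",
         "got factors {", paste(fac, collapse = ","), "} samples {",
         paste(smp, collapse = ","), "}")
  if (length(peaks) == 0L) {
    out <- granges(peaks)
    mcols(out) <- DataFrame(factor = character(), sample = character(),
                            support = integer(), max_score = numeric())
    return(out)
  }
  if (mode == "union") {
    regions <- merge_intervals(peaks, gap = gap)
  } else {
    per_rep <- lapply(split(peaks, peaks$replicate), merge_intervals, gap = gap)
    if (length(per_rep) < 2L) {
      regions <- GRanges()
    } else {
      cov <- coverage(do.call(c, unname(per_rep)))
      irl <- slice(cov, lower = 2L, rangesOnly = TRUE)
      regions <- GRanges(rep(names(irl), lengths(irl)),
                         unlist(irl, use.names = FALSE))
    }
  }
  regions <- sort(regions, ignore.strand = TRUE)
  hits <- findOverlaps(regions, peaks, ignore.strand = TRUE)
  support <- integer(length(regions))
  max_score <- rep(NA_real_, length(regions))
  if (length(hits)) {
    reps <- split(peaks$replicate[subjectHits(hits)], queryHits(hits))
    scs <- split(peaks$score[subjectHits(hits)], queryHits(hits))
    qi <- as.integer(names(reps))
    support[qi] <- vapply(reps, function(r) length(unique(r)), 1L)
    max_score[qi] <- vapply(scs, max, 1)
  }
  mcols(regions) <- DataFrame(
    factor = rep(fac, length(regions)),
    sample = rep(smp, length(regions)),
    support = support,
    max_score = max_score
  )
  regions
}

#' Call co-occupancy sites from per-factor binding regions
#'
#' Pools the regions of all factors, links regions within `link_gap` bases
#' into candidate spans, records which factors overlap each span, and keeps
#' spans bound by at least one CBX-class factor, at least one RING-class
#' factor and the required histone mark (H3K27me3 by default) -- the
#' candidate-target compilation criterion.
#'
#' @param regions_by_factor named list of `GRanges`, one per factor (binding
#'   regions from [merge_replicates()] or raw peaks). A `max_score` or
#'   `score` metadata column, when present, feeds the per-site member scores.
#' @param registry factor registry (see [factor_registry()]).
#' @param required_mark factor name that must be present (default
#'   `"H3K27me3"`).
#' @param link_gap gap (bp) within which regions of different factors are
#'   linked into one candidate span; default 1000.
#' @return A sorted `GRanges` of co-occupancy sites with metadata columns
#'   `factors_present`, `cbx_members`, `ring_members` (`CharacterList`),
#'   `n_prc1_factors`, `has_h3k27me3`, `max_score`, `rejected`, and member
#'   bookkeeping (`member_factors`, `member_scores`, `member_starts`,
#'   `member_ends`) used by [filter_foothills()].
#' @export
call_cooccupancy <- function(regions_by_factor,
                             registry = default_factor_registry(),
                             required_mark = "H3K27me3",
                             link_gap = 1000L) {
  if (length(regions_by_factor) == 0L) return(empty_sites())
  if (is.null(names(regions_by_factor)) || any(!nzchar(names(regions_by_factor))))
    stop("regions_by_factor must be a named list (factor names)")
  classes <- registry_class(registry, names(regions_by_factor))
  if (!required_mark %in% names(regions_by_factor))
    stop("required mark '", required_mark, "' absent from regions_by_factor")
  pool <- do.call(c, unname(lapply(names(regions_by_factor), function(f) {
    gr <- granges(regions_by_factor[[f]])
    sc <- mcols(regions_by_factor[[f]])$max_score
    if (is.null(sc)) sc <- mcols(regions_by_factor[[f]])$score
    if (is.null(sc)) sc <- rep(NA_real_, length(gr))
    mcols(gr) <- DataFrame(factor = rep(f, length(gr)), score = as.numeric(sc))
    gr
  })))
  if (length(pool) == 0L) return(empty_sites())
  spans <- merge_intervals(pool, gap = link_gap)
  hits <- findOverlaps(spans, pool, ignore.strand = TRUE)
  mf <- splitAsList(pool$factor[subjectHits(hits)],
                    factor(queryHits(hits), levels = seq_along(spans)))
  ms <- splitAsList(pool$score[subjectHits(hits)],
                    factor(queryHits(hits), levels = seq_along(spans)))
  mst <- splitAsList(start(pool)[subjectHits(hits)],
                     factor(queryHits(hits), levels = seq_along(spans)))
  men <- splitAsList(end(pool)[subjectHits(hits)],
                     factor(queryHits(hits), levels = seq_along(spans)))
  sites <- decorate_sites(spans, mf, ms, mst, men, registry, required_mark)
  sites[!sites$rejected]
}

empty_sites <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(
    factors_present = CharacterList(), cbx_members = CharacterList(),
    ring_members = CharacterList(), n_prc1_factors = integer(),
    has_h3k27me3 = logical(), max_score = numeric(), rejected = logical(),
    member_factors = CharacterList(), member_scores = NumericList(),
    member_starts = IntegerList(), member_ends = IntegerList()
  )
  gr
}

# attach factor-set metadata to candidate spans and evaluate the criterion
decorate_sites <- function(spans, member_factors, member_scores,
                           member_starts, member_ends,
                           registry, required_mark) {
  member_factors <- unname(member_factors)
  member_scores <- unname(member_scores)
  member_starts <- unname(member_starts)
  member_ends <- unname(member_ends)
  fp <- unique(member_factors)
  cls <- relist(registry[unlist(fp)], fp)
  cbx <- fp[cls == "CBX"]
  ring <- fp[cls == "RING"]
  has_mark <- any(fp == required_mark)
  keep <- lengths(cbx) >= 1L & lengths(ring) >= 1L & has_mark
  mcols(spans) <- DataFrame(
    factors_present = fp,
    cbx_members = cbx,
    ring_members = ring,
    n_prc1_factors = unname(lengths(cbx) + lengths(ring)),
    has_h3k27me3 = unname(has_mark),
    max_score = unname(vapply(as.list(member_scores), function(s) {
      s <- s[!is.na(s)]
      if (length(s)) max(s) else NA_real_
    }, 1)),
    rejected = unname(!keep),
    member_factors = member_factors,
    member_scores = member_scores,
    member_starts = member_starts,
    member_ends = member_ends
  )
  spans
}

#' Remove low-score "foothill" member peaks from co-occupancy sites
#'
#' Foothill peaks are weak flanking peaks at the fringes of a site's main
#' body, interpreted as weaker or less frequent contacts rather than
#' factor-specific binding. This filter drops member peaks whose score falls
#' below `min_fraction` of the site's maximum member score and recomputes
#' the factor sets. A site that no longer satisfies the co-occupancy
#' criterion is flagged `rejected = TRUE` rather than silently dropped.
#' `min_fraction = 0` (the default elsewhere in the package) is the identity.
#'
#' @param sites co-occupancy sites from [call_cooccupancy()].
#' @param min_fraction numeric in `[0, 1]`.
#' @param registry factor registry used to recompute classes.
#' @param required_mark required histone mark.
#' @return Sites with members filtered, factor sets recomputed, and a
#'   `rejected` flag.
#' @export
filter_foothills <- function(sites, min_fraction,
                             registry = default_factor_registry(),
                             required_mark = "H3K27me3") {
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must be in [0, 1]")
  if (min_fraction == 0 || length(sites) == 0L) return(sites)
  keep <- mapply(function(sc, mx) !is.na(sc) & sc >= min_fraction * mx,
                 as.list(sites$member_scores), as.list(sites$max_score),
                 SIMPLIFY = FALSE)
  keep <- LogicalList(keep)
  decorate_sites(granges(sites),
                 sites$member_factors[keep], sites$member_scores[keep],
                 sites$member_starts[keep], sites$member_ends[keep],
                 registry, required_mark)
}

#' Read a peak-file manifest
#'
#' A manifest declares one peak file per factor/replicate with columns
#' `path`, `factor`, `class`, `sample`, `replicate` (TSV with header, or a
#' YAML list of records with those fields). Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path manifest path.
#' @return A `data.frame` with the five columns above.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest does not exist: ", path)
  if (grepl("\\.ya?ml$", path)) {
    recs <- yaml::read_yaml(path)
    m <- do.call(rbind, lapply(recs, function(r) as.data.frame(r[c(
      "path", "factor", "class", "sample", "replicate")])))
  } else {
    m <- read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("path", "factor", "class", "sample", "replicate")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m$replicate <- as.character(m$replicate)
  rel <- !grepl("^/", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  missing <- !file.exists(m$path)
  if (any(missing))
    stop("manifest declares missing peak file(s): ",
         paste(basename(m$path[missing]), collapse = ", "))
  m
}

#' Load all peaks declared in a manifest
#'
#' @param manifest a `data.frame` from [read_manifest()].
#' @param format peak file format passed to [read_peaks()].
#' @return A named list `sample -> factor -> GRanges` of pooled replicate
#'   peaks, plus a factor registry assembled from the manifest's `class`
#'   column as attribute `"registry"`.
#' @export
load_peakset <- function(manifest, format = "narrowPeak") {
  reg_tab <- unique(manifest[, c("factor", "class")])
  registry <- factor_registry(reg_tab$factor, reg_tab$class)
  out <- lapply(split(manifest, manifest$sample), function(ms) {
    lapply(split(ms, ms$factor), function(mf) {
      do.call(c, unname(Map(function(p, f, s, r)
        read_peaks(p, format = format, factor = f, sample = s, replicate = r),
        mf$path, mf$factor, mf$sample, mf$replicate)))
    })
  })
  attr(out, "registry") <- registry
  out
}

#' Write co-occupancy sites as BED6+
#'
#' Columns: chrom, start, end, name, score (max member score), strand `.`,
#' plus a comma-joined `factors_present` extra column. 0-based half-open.
#'
#' @param sites co-occupancy sites.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cooccupancy_bed <- function(sites, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.\t%s",
                   as.character(seqnames(sites)), start(sites) - 1L,
                   end(sites), sprintf("site_%d", seq_along(sites)),
                   fmt_num(ifelse(is.na(sites$max_score), 0, sites$max_score)),
                   vapply(as.list(sites$factors_present),
                          paste, "", collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
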