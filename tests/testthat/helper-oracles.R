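# Independent per-base boolean-array oracles for interval arithmetic on a
# small synthetic chromosome, and brute-force scans. These deliberately
# avoid GenomicRanges so they stay independent of the implementation path.

bool_from <- function(start, end, len) {
  v <- logical(len)
  for (i in seq_along(start)) v[start[i]:end[i]] <- TRUE
  v
}

runs_of <- function(v) {
  r <- rle(v)
  en <- cumsum(r$lengths)
  st <- en - r$lengths + 1L
  data.frame(start = st[r$values], end = en[r$values])
}

# gap-bridging union of 1-based closed intervals
ora_merge <- function(start, end, gap, len = max(end) + gap + 10L) {
  r <- runs_of(bool_from(start, end, len))
  if (nrow(r) <= 1L) return(r)
  out <- r[1L, , drop = FALSE]
  for (i in 2:nrow(r)) {
    if (r$start[i] - out$end[nrow(out)] - 1L <= gap) {
      out$end[nrow(out)] <- r$end[i]
    } else {
      out <- rbind(out, r[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

# bases covered by >= k replicate tracks (each track gap-merged first)
ora_multi_cover <- function(tracks, gap, k, len) {
  covered <- integer(len)
  for (t in tracks) {
    m <- ora_merge(t$start, t$end, gap, len)
    covered <- covered + bool_from(m$start, m$end, len)
  }
  out <- runs_of(covered >= k)
  rownames(out) <- NULL
  out
}

# co-occupancy criterion evaluated over per-base factor presence
ora_cooccupancy <- function(tracks, link_gap, registry, required_mark, len) {
  arrays <- lapply(tracks, function(d) bool_from(d$start, d$end, len))
  allv <- Reduce(`|`, arrays)
  if (!any(allv)) return(data.frame(start = integer(), end = integer()))
  r <- runs_of(allv)
  comps <- ora_merge(r$start, r$end, link_gap, len)
  keep <- vapply(seq_len(nrow(comps)), function(i) {
    span <- comps$start[i]:comps$end[i]
    present <- names(arrays)[vapply(arrays, function(a) any(a[span]),
                                    TRUE)]
    cls <- registry[present]
    sum(cls == "CBX") >= 1L && sum(cls == "RING") >= 1L &&
      required_mark %in% present
  }, TRUE)
  out <- comps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive nearest-point scan with the coding-then-id tie rule
ora_nearest <- function(chrom, pos, features) {
  if (is.null(features$coding)) features$coding <- TRUE
  if (is.null(features$id)) features$id <- as.character(seq_len(nrow(features)))
  vapply(seq_along(pos), function(i) {
    on <- which(features$chrom == chrom[i])
    if (!length(on)) return(NA_integer_)
    d <- abs(features$pos[on] - pos[i])
    cand <- on[d == min(d)]
    o <- order(!features$coding[cand], features$id[cand])
    cand[o[1L]]
  }, 1L)
}

gr_df <- function(gr) {
  data.frame(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}
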