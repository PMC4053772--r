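# Call genes active/silent from duplicate RNA read counts under a ten-read
# threshold, cross-reference with target calls, and compute the
# expression-integration summaries (target vs genome-wide active fractions,
# H3K4me3 promoter flags).

#' Read a per-gene read-count table
#'
#' TSV with a header: a `gene_id` column plus one column per replicate of
#' raw mapped read counts (at least two replicates).
#'
#' @param path TSV path.
#' @return A `data.frame` with `gene_id` first, count columns after.
#' @export
read_count_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(d)) stop("count table needs a gene_id column")
  cnt <- d[setdiff(names(d), "gene_id")]
  if (ncol(cnt) < 2L) stop("count table needs >= 2 replicate columns")
  if (any(unlist(cnt) < 0, na.rm = TRUE)) stop("negative read counts")
  cbind(d["gene_id"], cnt)
}

#' Call transcriptional activity from duplicate read counts
#'
#' A gene is scored transcriptionally active when its read count reaches the
#' threshold (default ten reads) in *every* replicate -- the strict reading
#' of "ten read counts in duplicate samples". The alternative reading
#' (replicate sum reaching the threshold) is available as `mode = "sum"`.
#'
#' @param counts a numeric matrix/data.frame (genes x replicates, >= 2
#'   columns) or a single numeric vector of >= 2 replicate counts.
#' @param threshold integer read-count threshold (default 10).
#' @param mode `"each"` (default) or `"sum"`.
#' @return A logical vector (one element per gene).
#' @export
call_active <- function(counts, threshold = 10L, mode = c("each", "sum")) {
  mode <- match.arg(mode)
  if (is.vector(counts) && is.numeric(counts)) counts <- t(as.matrix(counts))
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L)
    stop("activity is defined on duplicate samples: need >= 2 replicates")
  if (any(counts < 0, na.rm = TRUE)) stop("negative read counts")
  if (mode == "each") {
    as.vector(rowSums(counts >= threshold) == ncol(counts))
  } else {
    as.vector(rowSums(counts) >= threshold)
  }
}

expression_flags <- function(expression, threshold = 10L, mode = "each") {
  act <- call_active(as.matrix(expression[setdiff(names(expression),
                                                  "gene_id")]),
                     threshold = threshold, mode = mode)
  setNames(act, expression$gene_id)
}

#' Fraction of target genes transcriptionally active
#'
#' @param calls target-call `data.frame` ([assign_targets()]), or a
#'   character vector of target gene ids.
#' @param expression count table ([read_count_table()]).
#' @param threshold,mode passed to [call_active()].
#' @return Named numeric `c(active = , silent = )`, summing to 1. Target
#'   genes missing from the expression table are counted silent, with a
#'   warning.
#' @export
active_fraction <- function(calls, expression, threshold = 10L,
                            mode = "each") {
  ids <- if (is.data.frame(calls)) calls$gene_id else as.character(calls)
  if (length(ids) == 0L) stop("no target calls supplied")
  flags <- expression_flags(expression, threshold, mode)
  m <- flags[ids]
  if (anyNA(m)) {
    warning(sum(is.na(m)), " target gene(s) missing from the expression ",
            "table; counted silent")
    m[is.na(m)] <- FALSE
  }
  fa <- mean(m)
  c(active = fa, silent = 1 - fa)
}

#' Genome-wide active/silent ratio
#'
#' The same activity computation as [active_fraction()] but over the whole
#' annotation, reported beside the target fraction as enrichment context
#' (the "all expressed and non-expressed genes" comparator).
#'
#' @param expression count table ([read_count_table()]).
#' @param threshold,mode passed to [call_active()].
#' @return Named numeric `c(active = , silent = )`.
#' @export
background_ratio <- function(expression, threshold = 10L, mode = "each") {
  if (nrow(expression) == 0L) stop("empty expression table")
  flags <- expression_flags(expression, threshold, mode)
  fa <- mean(flags)
  c(active = fa, silent = 1 - fa)
}

#' Flag target genes with an H3K4me3 peak at the TSS
#'
#' A call is flagged when any H3K4me3 region overlaps the promoter window
#' `[tss - window, tss + window)` of its gene.
#'
#' @param calls target-call `data.frame` ([assign_targets()]).
#' @param genes gene models ([read_genes()]).
#' @param h3k4me3 a `GRanges` of H3K4me3 regions or peaks.
#' @param window promoter half-width in bp (default 2000).
#' @return A list: `flags` (named logical by gene_id) and `fraction`.
#' @export
flag_h3k4me3_tss <- function(calls, genes, h3k4me3, window = 2000L) {
  if (window <= 0) stop("window must be > 0")
  gi <- match(calls$gene_id, genes$gene_id)
  if (anyNA(gi)) stop("target call gene(s) absent from the annotation")
  tss <- genes$tss[gi]
  prom <- GRanges(seqnames(genes)[gi],
                  IRanges(pmax(1L, tss - as.integer(window)),
                          tss + as.integer(window) - 1L))
  fl <- countOverlaps(prom, h3k4me3, ignore.strand = TRUE) > 0L
  list(flags = setNames(fl, calls$gene_id),
       fraction = if (length(fl)) mean(fl) else NA_real_)
}
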