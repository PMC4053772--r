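# Domain types, coordinate conventions, interval arithmetic and readers /
# writers for the BED-family and GTF formats every other module consumes.
#
# Internally everything is a GRanges (1-based, closed). BED-family files
# (BED6, narrowPeak) are 0-based half-open on disk and are converted on
# read/write; GTF is 1-based inclusive and needs no conversion.

#' Construct a peak track
#'
#' A peak is a located genomic span with an enrichment score, an optional
#' summit offset and provenance labels (factor, sample, replicate). Peaks are
#' represented as an unstranded `GRanges` with metadata columns `score`,
#' `summit` (integer offset from the interval start, `NA` when absent),
#' `factor`, `sample` and `replicate`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 1-based closed interval bounds (`start <= end`).
#' @param score non-negative enrichment score.
#' @param summit integer offset of the summit from `start` (0-based within
#'   the peak), or `NA`.
#' @param factor,sample,replicate provenance labels.
#' @return A `GRanges` of peaks.
#' @export
peak_track <- function(chrom, start, end, score = 0, summit = NA_integer_,
                       factor = NA_character_, sample = NA_character_,
                       replicate = NA_character_) {
  gr <- GRanges(chrom, IRanges(start, end))
  n <- length(gr)
  mcols(gr) <- DataFrame(
    score = rep_len(as.numeric(score), n),
    summit = rep_len(as.integer(summit), n),
    factor = rep_len(as.character(factor), n),
    sample = rep_len(as.character(sample), n),
    replicate = rep_len(as.character(replicate), n)
  )
  validate_peaks(gr)
  gr
}

validate_peaks <- function(peaks) {
  if (any(peaks$score < 0, na.rm = TRUE))
    stop("peak scores must be non-negative")
  bad <- !is.na(peaks$summit) &
    (peaks$summit < 0L | peaks$summit >= width(peaks))
  if (any(bad))
    stop("summit offsets must lie within the peak (0 <= summit < width)")
  invisible(peaks)
}

#' Read peak calls from a narrowPeak or BED6 file
#'
#' narrowPeak is the 10-column ENCODE format: the enrichment score is taken
#' from column 7 (signalValue) and the summit offset from column 10 (`-1`
#' meaning absent). BED6 files use column 5 as the score and have no summit.
#' On-disk coordinates are 0-based half-open and converted to the internal
#' 1-based closed convention.
#'
#' @param path file path.
#' @param format `"narrowPeak"` or `"bed6"`.
#' @param factor,sample,replicate provenance labels attached to every peak.
#' @return A `GRanges` of peaks (see [peak_track()]); empty for an empty file.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6"),
                       factor = NA_character_, sample = NA_character_,
                       replicate = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(peak_track(character(), integer(), integer())[0])
  }
  need <- if (format == "narrowPeak") 10L else 6L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < need)) {
    i <- which(nf < need)[1L]
    stop(sprintf("%s line %d: expected >= %d columns, found %d",
                 basename(path), i, need, nf[i]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(s0) | is.na(e0) | s0 != floor(s0) | e0 != floor(e0)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("%s line %d: non-integer coordinates", basename(path), i))
  }
  if (any(s0 >= e0)) {
    i <- which(s0 >= e0)[1L]
    stop(sprintf("%s line %d: start >= end (%d >= %d)",
                 basename(path), i, s0[i], e0[i]))
  }
  if (format == "narrowPeak") {
    score <- as.numeric(vapply(fields, `[[`, "", 7L))
    summit <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 10L)))
    summit[!is.na(summit) & summit < 0L] <- NA_integer_
  } else {
    score <- as.numeric(vapply(fields, `[[`, "", 5L))
    summit <- NA_integer_
  }
  if (any(is.na(score))) {
    i <- which(is.na(score))[1L]
    stop(sprintf("%s line %d: non-numeric score", basename(path), i))
  }
  peak_track(chrom, s0 + 1L, e0, score = score, summit = summit,
             factor = factor, sample = sample, replicate = replicate)
}

#' Write peaks to a narrowPeak or BED6 file
#'
#' Output is tab-separated, headerless, 0-based half-open. For narrowPeak the
#' internal score is written to column 7 (signalValue) and the summit offset
#' to column 10 (`NA` becomes `-1`); p/q-value columns are written as `-1`.
#'
#' @param peaks a `GRanges` of peaks.
#' @param path output path.
#' @param format `"narrowPeak"` or `"bed6"`.
#' @param name optional record names (defaults to `peak_<i>`).
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("narrowPeak", "bed6"),
                        name = NULL) {
  format <- match.arg(format)
  n <- length(peaks)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  chrom <- as.character(seqnames(peaks))
  s0 <- start(peaks) - 1L
  e0 <- end(peaks)
  sc <- fmt_num(mcols(peaks)$score)
  if (format == "narrowPeak") {
    summit <- mcols(peaks)$summit
    if (is.null(summit)) summit <- rep(NA_integer_, n)
    summit[is.na(summit)] <- -1L
    bed5 <- pmin(1000L, as.integer(round(mcols(peaks)$score)))
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t-1\t-1\t%d",
                     chrom, s0, e0, name, bed5, sc, summit)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.", chrom, s0, e0, name, sc)
  }
  writeLines(lines, path)
  invisible(path)
}

# deterministic, round-trip-safe numeric formatting
fmt_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

#' Read gene models from a GTF or BED12 file
#'
#' Returns one record per gene with metadata columns `gene_id`, `name`,
#' `biotype` (`"coding"` or `"noncoding"`), and absolute `tss`/`tes`
#' positions (1-based) derived from the strand: the TSS is the 5' end of the
#' gene span and the TES the 3' end. For GTF input, records with
#' `type == "gene"` are used when present, otherwise gene spans are the
#' per-`gene_id` outermost coordinates over all records (multi-isoform genes
#' collapse to their extremal span). Biotype attributes containing
#' `"protein_coding"` (or absent) map to `"coding"`, anything else to
#' `"noncoding"`.
#'
#' @param path file path.
#' @param format `"gtf"` or `"bed12"`.
#' @return A stranded `GRanges` of gene models.
#' @export
read_genes <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file does not exist: ", path)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    has_gene_rows <- !is.null(gr$type) && any(gr$type == "gene")
    if (has_gene_rows) gr <- gr[gr$type == "gene"]
    if (is.null(gr$gene_id) || anyNA(gr$gene_id))
      stop("GTF records lack gene_id attributes")
    if (has_gene_rows && anyDuplicated(gr$gene_id)) {
      dup <- unique(gr$gene_id[duplicated(gr$gene_id)])
      stop("duplicate gene_id: ", paste(head(dup, 10L), collapse = ", "))
    }
    if (anyDuplicated(gr$gene_id)) {
      # collapse multi-record genes to their outermost span
      sp <- split(gr, gr$gene_id)
      rg <- unlist(range(sp, ignore.strand = FALSE))
      if (anyDuplicated(names(rg))) {
        dup <- unique(names(rg)[duplicated(names(rg))])
        stop("duplicate gene_id with inconsistent placement: ",
             paste(dup, collapse = ", "))
      }
      first <- gr[!duplicated(gr$gene_id)]
      first <- first[match(names(rg), first$gene_id)]
      mcols(rg) <- mcols(first)
      gr <- unname(rg)
    }
    biotype <- gr$gene_biotype
    if (is.null(biotype)) biotype <- gr$gene_type
    if (is.null(biotype)) biotype <- rep("protein_coding", length(gr))
    biotype[is.na(biotype)] <- "protein_coding"
    nm <- gr$gene_name
    if (is.null(nm)) nm <- gr$gene_id
    nm[is.na(nm)] <- gr$gene_id[is.na(nm)]
    out <- granges(gr)
    mcols(out) <- DataFrame(
      gene_id = gr$gene_id,
      name = nm,
      biotype = ifelse(grepl("protein_coding", biotype), "coding", "noncoding")
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$name)) stop("BED12 records lack a name column")
    out <- granges(gr)
    mcols(out) <- DataFrame(
      gene_id = gr$name,
      name = gr$name,
      biotype = rep("coding", length(gr))
    )
  }
  if (any(!as.character(strand(out)) %in% c("+", "-"))) {
    bad <- out$gene_id[!as.character(strand(out)) %in% c("+", "-")]
    stop("gene(s) without strand: ", paste(head(bad, 5L), collapse = ", "))
  }
  if (anyDuplicated(out$gene_id)) {
    dup <- unique(out$gene_id[duplicated(out$gene_id)])
    stop("duplicate gene_id: ", paste(head(dup, 10L), collapse = ", "))
  }
  plus <- as.character(strand(out)) == "+"
  out$tss <- ifelse(plus, start(out), end(out))
  out$tes <- ifelse(plus, end(out), start(out))
  out <- sortSeqlevels(out)
  sort(out, ignore.strand = TRUE)
}

#' Write gene models as GTF
#'
#' One `gene` record per gene, 1-based inclusive coordinates; reading the
#' result back with [read_genes()] reproduces the original coordinates.
#'
#' @param genes a `GRanges` of gene models (see [read_genes()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_gtf <- function(genes, path) {
  biotype <- ifelse(genes$biotype == "coding", "protein_coding", "lincRNA")
  lines <- sprintf(
    paste0("%s\tprc1targets\tgene\t%d\t%d\t.\t%s\t.\t",
           "gene_id \"%s\"; gene_name \"%s\"; gene_biotype \"%s\";"),
    as.character(seqnames(genes)), start(genes), end(genes),
    as.character(strand(genes)), genes$gene_id, genes$name, biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Merge intervals that overlap or lie within a gap of one another
#'
#' Returns the maximal disjoint intervals covering the input, joining inputs
#' on the same chromosome that are separated by at most `gap` bases. Output
#' is sorted by (chromosome, start); strand is ignored.
#'
#' @param x a `GRanges`.
#' @param gap non-negative integer gap (bp); intervals separated by `<= gap`
#'   bases are joined. `gap = 0` joins only overlapping or abutting intervals.
#' @return An unstranded, sorted `GRanges`.
#' @export
merge_intervals <- function(x, gap = 0L) {
  if (gap < 0) stop("gap must be >= 0")
  out <- reduce(granges(x), min.gapwidth = gap + 1L, ignore.strand = TRUE)
  sort(out, ignore.strand = TRUE)
}

#' Nearest point feature to each query position
#'
#' For each query position, finds the feature position on the same chromosome
#' minimizing the absolute distance, and reports the signed distance
#' `feature - query`. Ties in absolute distance are broken by preferring
#' features with `coding = TRUE`, then the lexicographically smallest `id`.
#' Queries on chromosomes with no feature are returned as unassigned
#' (`NA` index and distance) rather than raising an error.
#'
#' @param chrom,pos character/integer vectors of query positions.
#' @param features a `data.frame` with columns `chrom`, `pos`, and optionally
#'   `coding` (logical) and `id` (character) used for tie-breaking.
#' @return A `data.frame` with one row per query: `feature` (row index into
#'   `features`, `NA` when unassigned) and `distance` (signed, feature minus
#'   query).
#' @export
nearest_feature <- function(chrom, pos, features) {
  stopifnot(length(chrom) == length(pos))
  n <- length(pos)
  idx <- rep(NA_integer_, n)
  if (is.null(features$coding)) features$coding <- TRUE
  if (is.null(features$id)) features$id <- as.character(seq_len(nrow(features)))
  by_chr <- split(seq_len(nrow(features)), features$chrom)
  for (ch in unique(chrom)) {
    fi <- by_chr[[ch]]
    if (is.null(fi)) next
    fpos <- features$pos[fi]
    ord <- order(fpos)
    fi <- fi[ord]; fpos <- fpos[ord]
    qi <- which(chrom == ch)
    left <- findInterval(pos[qi], fpos)
    for (k in seq_along(qi)) {
      q <- pos[qi[k]]
      cand <- unique(pmin(pmax(c(left[k], left[k] + 1L), 1L), length(fpos)))
      dmin <- min(abs(fpos[cand] - q))
      tied <- fi[abs(fpos - q) == dmin]
      if (length(tied) > 1L) {
        o <- order(!features$coding[tied], features$id[tied])
        tied <- tied[o]
      }
      idx[qi[k]] <- tied[1L]
    }
  }
  data.frame(
    feature = idx,
    distance = ifelse(is.na(idx), NA_real_, features$pos[idx] - pos)
  )
}
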