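# Shared fixture builders: write small peak/annotation files and construct
# co-occupancy sites from simple interval specifications.

write_np_lines <- function(lines, path = tempfile(fileext = ".narrowPeak")) {
  writeLines(lines, path)
  path
}

np_line <- function(chrom, start0, end0, score = 10, summit = -1,
                    name = "p") {
  sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t-1\t-1\t%d",
          chrom, start0, end0, name, as.integer(min(1000, round(score))),
          format(score), summit)
}

# peaks from 1-based closed coordinates
mk_peaks <- function(start, end, score = 10, replicate = "1",
                     factor = "CBX7", sample = "A", chrom = "chrT") {
  peak_track(chrom, start, end, score = score, factor = factor,
             sample = sample, replicate = replicate)
}

# regions_by_factor list from a named list of start/end matrices
mk_tracks <- function(spec, chrom = "chrT", score = 10) {
  lapply(spec, function(m) {
    m <- matrix(m, ncol = 2)
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(m[, 1], m[, 2]))
    gr$score <- rep_len(score, length(gr))
    gr
  })
}

# minimal gene model GRanges
mk_genes <- function(start, end, strand = "+", gene_id = NULL,
                     biotype = "coding", chrom = "chrT") {
  n <- length(start)
  if (is.null(gene_id)) gene_id <- sprintf("g%02d", seq_len(n))
  gr <- GenomicRanges::GRanges(rep_len(chrom, n),
                               IRanges::IRanges(start, end),
                               strand = rep_len(strand, n))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = gene_id, name = gene_id,
    biotype = rep_len(biotype, n))
  plus <- as.character(GenomicRanges::strand(gr)) == "+"
  gr$tss <- ifelse(plus, GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr$tes <- ifelse(plus, GenomicRanges::end(gr), GenomicRanges::start(gr))
  gr
}

# one co-occupancy "site" GRanges with the metadata assign_targets needs
mk_sites <- function(start, end, chrom = "chrT",
                     cbx = "CBX7", ring = "RING1", max_score = 10) {
  n <- length(start)
  gr <- GenomicRanges::GRanges(rep_len(chrom, n),
                               IRanges::IRanges(start, end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    factors_present = IRanges::CharacterList(
      replicate(n, c(cbx, ring, "H3K27me3"), simplify = FALSE)),
    cbx_members = IRanges::CharacterList(replicate(n, cbx, simplify = FALSE)),
    ring_members = IRanges::CharacterList(replicate(n, ring,
                                                    simplify = FALSE)),
    n_prc1_factors = rep_len(length(cbx) + length(ring), n),
    has_h3k27me3 = rep_len(TRUE, n),
    max_score = rep_len(max_score, n),
    rejected = rep_len(FALSE, n)
  )
  gr
}
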