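# End-to-end orchestration: manifest + annotation + counts -> co-occupancy
# sites, target tables, category proportions, strain overlap, expression
# integration and (when a senescent condition is present) profile
# concordance. All reports are TSV/JSON so they can be diffed.

#' Pipeline run configuration
#'
#' @param manifest path to a peak-file manifest ([read_manifest()]).
#' @param genes path to the gene annotation (GTF).
#' @param counts named character vector of count-table paths, one per
#'   sample (names must match manifest sample labels).
#' @param outdir output directory.
#' @param replicate_mode `"union"` (default) or `"intersection"` replicate
#'   merging.
#' @param merge_gap within-factor replicate merge gap (bp).
#' @param link_gap gap linking different factors' regions into candidate
#'   co-occupancy spans (bp; default 1000).
#' @param required_mark histone mark required at every site.
#' @param foothill_min_fraction member peaks below this fraction of the
#'   site maximum are dropped (default 0 = keep foothills).
#' @param activity_threshold read-count threshold for active transcription.
#' @param activity_mode `"each"` or `"sum"` (see [call_active()]).
#' @param h3k4me3_window promoter half-width for H3K4me3 flagging (bp).
#' @param architecture an [architecture_config()].
#' @param senescent_suffix sample-label suffix identifying a senescent
#'   condition of a base sample (compared to its base, excluded from the
#'   strain comparison).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(manifest, genes, counts = NULL, outdir,
                       replicate_mode = c("union", "intersection"),
                       merge_gap = 0L, link_gap = 1000L,
                       required_mark = "H3K27me3",
                       foothill_min_fraction = 0,
                       activity_threshold = 10L,
                       activity_mode = c("each", "sum"),
                       h3k4me3_window = 2000L,
                       architecture = architecture_config(),
                       senescent_suffix = "_senescent") {
  cfg <- list(manifest = manifest, genes = genes, counts = counts,
              outdir = outdir,
              replicate_mode = match.arg(replicate_mode),
              merge_gap = merge_gap, link_gap = link_gap,
              required_mark = required_mark,
              foothill_min_fraction = foothill_min_fraction,
              activity_threshold = activity_threshold,
              activity_mode = match.arg(activity_mode),
              h3k4me3_window = h3k4me3_window,
              architecture = architecture,
              senescent_suffix = senescent_suffix)
  for (f in c(manifest, genes, counts))
    if (!file.exists(f)) stop("config validation: missing input file: ", f)
  if (cfg$foothill_min_fraction < 0 || cfg$foothill_min_fraction > 1)
    stop("config validation: foothill_min_fraction outside [0, 1]")
  if (cfg$link_gap < 0 || cfg$merge_gap < 0)
    stop("config validation: gaps must be >= 0")
  structure(cfg, class = "run_config")
}

#' Run the full analysis
#'
#' Stages, mirroring the analysis order: load peaks, merge replicates per
#' factor, call co-occupancy sites, assign and classify target genes,
#' integrate expression, compare the two base samples, and quantify
#' concordance for any senescent condition against its base sample. Writes,
#' per sample: a co-occupancy BED, a per-locus target table, a
#' category-proportion TSV and an activity TSV; plus an overlap JSON for
#' the sample pair, a concordance JSON per senescent condition, a combined
#' target table, and a run log recording every parameter applied.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with per-sample results (`sites`, `calls`,
#'   `proportions`, `activity`, `h3k4me3`), `overlap`, `concordance`, and
#'   `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run_log.txt")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("prc1targets run: ", format(Sys.time()))
  for (p in c("replicate_mode", "merge_gap", "link_gap", "required_mark",
              "foothill_min_fraction", "activity_threshold", "activity_mode",
              "h3k4me3_window", "senescent_suffix"))
    logf("param ", p, " = ", config[[p]])
  logf("param end_window = ", config$architecture$end_window)
  logf("param body_overlap_fraction = ",
       config$architecture$body_overlap_fraction)
  logf("param max_assignment_distance = ",
       config$architecture$max_assignment_distance)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  manifest <- stage("manifest", read_manifest(config$manifest))
  genes <- stage("annotation", read_genes(config$genes, format = "gtf"))
  peakset <- stage("load_peaks", load_peakset(manifest))
  registry <- attr(peakset, "registry")

  all_samples <- names(peakset)
  sen <- grep(paste0(config$senescent_suffix, "$"), all_samples,
              value = TRUE)
  base_samples <- setdiff(all_samples, sen)

  results <- list()
  files <- character()
  for (s in all_samples) {
    regions <- stage(paste0("merge_replicates[", s, "]"),
                     lapply(peakset[[s]], merge_replicates,
                            mode = config$replicate_mode,
                            gap = config$merge_gap))
    sites <- stage(paste0("cooccupancy[", s, "]"),
                   call_cooccupancy(regions, registry = registry,
                                    required_mark = config$required_mark,
                                    link_gap = config$link_gap))
    if (config$foothill_min_fraction > 0) {
      sites <- filter_foothills(sites, config$foothill_min_fraction,
                                registry = registry,
                                required_mark = config$required_mark)
      sites <- sites[!sites$rejected]
    }
    bed <- file.path(config$outdir, paste0("cooccupancy_", s, ".bed"))
    write_cooccupancy_bed(sites, bed)
    files[paste0("cooccupancy_", s)] <- bed
    res <- list(sites = sites, h3k4me3 = regions[["H3K4me3"]])
    if (s %in% base_samples) {
      res$calls <- stage(paste0("assign_targets[", s, "]"),
                         assign_targets(sites, genes,
                                        config = config$architecture))
      res$proportions <- category_proportions(res$calls)
      pt <- file.path(config$outdir, paste0("category_proportions_", s,
                                            ".tsv"))
      write.table(data.frame(category = names(res$proportions$proportions),
                             fraction = unname(res$proportions$proportions),
                             n = res$proportions$n,
                             n_ambiguous = res$proportions$n_ambiguous),
                  pt, sep = "\t", quote = FALSE, row.names = FALSE)
      files[paste0("category_proportions_", s)] <- pt
    }
    results[[s]] <- res
  }

  # expression integration per base sample
  activity_flags <- list()
  for (s in base_samples) {
    if (is.null(config$counts) || !s %in% names(config$counts)) next
    expr <- stage(paste0("expression[", s, "]"),
                  read_count_table(config$counts[[s]]))
    af <- active_fraction(results[[s]]$calls, expr,
                          threshold = config$activity_threshold,
                          mode = config$activity_mode)
    bg <- background_ratio(expr, threshold = config$activity_threshold,
                           mode = config$activity_mode)
    k4 <- if (!is.null(results[[s]]$h3k4me3))
      flag_h3k4me3_tss(results[[s]]$calls, genes, results[[s]]$h3k4me3,
                       window = config$h3k4me3_window)
    else list(flags = NULL, fraction = NA_real_)
    results[[s]]$activity <- list(target = af, background = bg,
                                  h3k4me3_fraction = k4$fraction)
    activity_flags[[s]] <- expression_flags(expr,
                                            config$activity_threshold,
                                            config$activity_mode)
    at <- file.path(config$outdir, paste0("activity_", s, ".tsv"))
    write.table(data.frame(set = c("targets", "all_genes"),
                           fraction_active = c(af[["active"]],
                                               bg[["active"]]),
                           fraction_silent = c(af[["silent"]],
                                               bg[["silent"]]),
                           h3k4me3_tss_fraction = c(k4$fraction, NA)),
                at, sep = "\t", quote = FALSE, row.names = FALSE)
    files[paste0("activity_", s)] <- at
  }

  # combined per-locus target table
  calls_by_sample <- lapply(results[base_samples], `[[`, "calls")
  names(calls_by_sample) <- base_samples
  tt <- file.path(config$outdir, "target_table.tsv")
  write_target_table(calls_by_sample,
                     active_by_sample =
                       if (length(activity_flags)) activity_flags else NULL,
                     path = tt)
  files["target_table"] <- tt

  # strain comparison
  overlap <- NULL
  if (length(base_samples) >= 2L) {
    overlap <- compare_targets(calls_by_sample[[1L]], calls_by_sample[[2L]])
    oj <- file.path(config$outdir, "overlap.json")
    jsonlite::write_json(list(sample_a = base_samples[1L],
                              sample_b = base_samples[2L],
                              counts = as.list(overlap$counts),
                              shared = overlap$shared,
                              unique_a = overlap$unique_a,
                              unique_b = overlap$unique_b),
                         oj, auto_unbox = TRUE, digits = NA)
    files["overlap"] <- oj
  }

  # senescence concordance against the base sample
  concordance <- list()
  for (sc in sen) {
    base <- sub(paste0(config$senescent_suffix, "$"), "", sc)
    if (!base %in% all_samples) next
    cr <- stage(paste0("concordance[", sc, "]"),
                profile_concordance(results[[base]]$sites,
                                    results[[sc]]$sites))
    concordance[[sc]] <- cr
    cj <- file.path(config$outdir, paste0("concordance_", sc, ".json"))
    jsonlite::write_json(list(base = base, condition = sc,
                              location_overlap =
                                as.list(cr$location_overlap),
                              density_ratio = cr$density_ratio,
                              n_matched = cr$n_matched),
                         cj, auto_unbox = TRUE, digits = NA)
    files[paste0("concordance_", sc)] <- cj
  }

  logf("samples: ", paste(all_samples, collapse = ", "))
  logf("completed: ", format(Sys.time()))
  invisible(list(samples = results, overlap = overlap,
                 concordance = concordance, files = files,
                 base_samples = base_samples))
}

#' Generate a synthetic fixture and run the pipeline on it
#'
#' Convenience wrapper: [generate_dataset()] into `workdir/fixture`, then
#' [run_pipeline()] into `workdir/out` with the supplied analysis
#' parameters.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed for generation.
#' @param workdir working directory.
#' @param ... overrides passed to [run_config()].
#' @return A list with `truth` and `report` (the [run_pipeline()] result).
#' @export
run_fixture_pipeline <- function(config = generator_config(), seed,
                                 workdir = tempfile("prc1fix"), ...) {
  truth <- generate_dataset(config, seed = seed,
                            dir = file.path(workdir, "fixture"))
  cnts <- truth$files[paste0("counts_", config$samples)]
  names(cnts) <- config$samples
  rc <- run_config(manifest = truth$files[["manifest"]],
                   genes = truth$files[["genes"]],
                   counts = cnts,
                   outdir = file.path(workdir, "out"), ...)
  report <- run_pipeline(rc)
  list(truth = truth, report = report)
}
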