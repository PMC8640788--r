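#' Build a run configuration
#'
#' One declarative object holds every input path and threshold of the
#' end-to-end analysis; the effective configuration is echoed into the
#' output directory so no run depends on silent defaults. Provide either
#' the three input paths (FASTA required; BED/VCF optional) or a
#' [study_spec()] to synthesise the inputs, not both.
#'
#' @param fasta,pause_bed,vcf Input paths (external-data mode).
#' @param synth_spec A [study_spec()] (synthetic mode).
#' @param out_dir Output directory.
#' @param motif_window Interval width for the motif census (bases).
#' @param fold_window Window width for folding/composition/SNP statistics.
#' @param preset Motif preset name for [motif_config()].
#' @param n_bins Quantile bins for [bin_by_energy()].
#' @param n_random Random windows for the null comparison.
#' @param random_width Width of the random windows.
#' @param seed Seed for synthesis and randomisation.
#' @param fold_max_windows Cap on the number of windows folded (smallest
#'   coordinates first); `Inf` folds everything.
#' @param enrich_k SD multiplier for [flag_enriched()].
#' @return List of class `run_config`.
#' @export
run_config <- function(fasta = NULL, pause_bed = NULL, vcf = NULL,
                       synth_spec = NULL, out_dir = tempfile("fragilescan_"),
                       motif_window = 10000, fold_window = 500,
                       preset = "default", n_bins = 100, n_random = 1000,
                       random_width = 10000, seed = 1,
                       fold_max_windows = Inf, enrich_k = 3) {
  structure(list(fasta = fasta, pause_bed = pause_bed, vcf = vcf,
                 synth_spec = synth_spec, out_dir = out_dir,
                 motif_window = motif_window, fold_window = fold_window,
                 preset = preset, n_bins = n_bins, n_random = n_random,
                 random_width = random_width, seed = seed,
                 fold_max_windows = fold_max_windows, enrich_k = enrich_k),
            class = "run_config")
}

#' Validate a run configuration
#'
#' @param config A [run_config()] (or plain list).
#' @return Data frame of findings (`key`, `severity`, `message`); zero rows
#'   means the configuration is runnable. Severity `"error"` blocks
#'   [run_analysis()].
#' @export
validate_config <- function(config) {
  f <- list()
  add <- function(key, severity, msg)
    f[[length(f) + 1L]] <<- data.frame(key = key, severity = severity,
                                       message = msg)
  known <- names(run_config())
  unknown <- setdiff(names(config), known)
  for (u in unknown) add(u, "warning", "unknown configuration key")
  has_paths <- !is.null(config$fasta)
  has_synth <- !is.null(config$synth_spec)
  if (has_paths && has_synth)
    add("inputs", "error", "provide input paths or synth_spec, not both")
  if (!has_paths && !has_synth)
    add("inputs", "error", "no inputs: set fasta (+bed/vcf) or synth_spec")
  if (has_paths) {
    for (key in c("fasta", "pause_bed", "vcf")) {
      p <- config[[key]]
      if (!is.null(p) && !file.exists(p))
        add(key, "error", paste0("missing file: ", p))
    }
  }
  for (key in c("motif_window", "fold_window", "n_bins", "n_random",
                "random_width")) {
    v <- config[[key]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      add(key, "error", "must be a positive number")
  }
  out <- if (length(f)) do.call(rbind, f) else
    data.frame(key = character(), severity = character(),
               message = character())
  rownames(out) <- NULL
  out
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage_log <- function(stage, t0, n_in, n_out) {
  message(sprintf("[%s] in=%s out=%s elapsed=%.2fs", stage,
                  n_in, n_out, as.numeric(Sys.time()) - t0))
}

#' Run the end-to-end pause-site analysis
#'
#' Stage chain: input loading (or synthesis) -> motif census -> folding and
#' composition -> SNP variation, binning, randomisation null, and spectra.
#' Each stage's tables are written to the output directory before the next
#' stage begins; a failure aborts naming the stage, retaining earlier
#' outputs. Without a VCF the variation stage is skipped with a warning
#' (motif/folding tables are still produced).
#'
#' @param config A [run_config()].
#' @return List of class `report_bundle`: the result tables plus `paths`
#'   and the effective `config`.
#' @export
run_analysis <- function(config = run_config()) {
  findings <- validate_config(config)
  if (any(findings$severity == "error"))
    stop("configuration errors:\n",
         paste0("  - ", findings$key, ": ", findings$message,
                collapse = "\n"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config, paths = list())
  emit <- function(name, table) {
    report$paths[[name]] <<- .write_tsv(
      table, file.path(config$out_dir, paste0(name, ".tsv")))
    report[[name]] <<- table
  }
  run_stage <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- stage: inputs -------------------------------------------------
  t0 <- as.numeric(Sys.time())
  genome <- NULL
  snps <- NULL
  pause <- NULL
  run_stage("inputs", {
    if (!is.null(config$synth_spec)) {
      paths <- make_study_fixture(file.path(config$out_dir, "inputs"),
                                  seed = config$seed,
                                  spec = config$synth_spec)
      config$fasta <- paths$fasta
      config$pause_bed <- paths$bed
      config$vcf <- paths$vcf
    }
    genome <- read_fasta(config$fasta)
    if (!is.null(config$pause_bed)) pause <- read_bed(config$pause_bed)
    if (!is.null(config$vcf)) snps <- read_snvs(config$vcf)
  })
  .stage_log("inputs", t0, length(config$fasta),
             length(genome))

  meta <- list(package_version = as.character(utils::packageVersion(
                 "fragilescan")),
               config = config[setdiff(names(config), "synth_spec")],
               synth = !is.null(config$synth_spec),
               motif_config = unclass(motif_config(config$preset)),
               window_policy = "trailing partial windows dropped",
               tt_strand = "plus",
               n_policy = "windows with >10% N excluded from folding/SNP stats")
  yaml::write_yaml(meta, file.path(config$out_dir, "run_metadata.yaml"))

  # ---- stage: motif census ------------------------------------------
  t0 <- as.numeric(Sys.time())
  run_stage("motifs", {
    cfg <- motif_config(config$preset)
    hits <- scan_all(genome, cfg)
    grid10 <- tile_regions(genome, config$motif_window)
    summary10 <- summarize_by_interval(hits, grid10, pause)
    emit("motif_hits", hits)
    emit("interval_summary", summary10)
    enr <- flag_enriched(summary10, "count_inverted_repeat",
                         k = config$enrich_k)
    emit("enrichment_inverted_repeat", enr)
  })
  .stage_log("motifs", t0, sum(nchar(genome)), nrow(report$motif_hits))

  # ---- stage: folding + composition ---------------------------------
  t0 <- as.numeric(Sys.time())
  run_stage("folding", {
    grid <- tile_regions(genome, config$fold_window)
    comp <- window_composition(genome, grid)
    emit("composition", comp)
    fold_grid <- grid
    if (is.finite(config$fold_max_windows) &&
        nrow(grid) > config$fold_max_windows)
      fold_grid <- grid[seq_len(config$fold_max_windows), , drop = FALSE]
    folds <- fold_windows(genome, fold_grid)
    emit("folds", folds)
  })
  .stage_log("folding", t0, nrow(report$composition), nrow(report$folds))

  # ---- stage: variation ---------------------------------------------
  if (is.null(snps)) {
    warning("no VCF provided; variation stage skipped")
  } else {
    t0 <- as.numeric(Sys.time())
    run_stage("variation", {
      grid <- tile_regions(genome, config$fold_window)
      wv <- window_variation(snps, grid, pause)
      emit("variation", wv)
      sp <- spectrum_report(wv)
      emit("spectrum", sp$counts)
      if (!is.null(sp$ratios))
        emit("spectrum_ratios",
             data.frame(metric = names(sp$ratios), ratio = sp$ratios))
      if (any(wv$pause) && any(!wv$pause)) {
        cmpres <- compare_groups(wv$n_per_10kb[wv$pause],
                                 wv$n_per_10kb[!wv$pause],
                                 names = c("pause", "nonpause"))
        emit("comparisons", data.frame(
          comparison = "snp_density_pause_vs_nonpause",
          n_a = cmpres$n[1], n_b = cmpres$n[2],
          median_a = cmpres$median[1], median_b = cmpres$median[2],
          mean_a = cmpres$mean[1], mean_b = cmpres$mean[2],
          statistic = cmpres$statistic, p_value = cmpres$p_value))
      }
      folds <- report$folds
      if (!is.null(folds) && nrow(folds) >= config$n_bins) {
        bins <- bin_by_energy(folds, wv, n_bins = config$n_bins)
        emit("bins", bins)
      }
      rw <- random_windows(genome, n = config$n_random,
                           width = config$random_width,
                           seed = config$seed)
      # random windows may overlap each other, so count by interval overlap
      pos0 <- snps$pos - 1
      rn <- vapply(seq_len(nrow(rw)), function(i)
        sum(snps$chrom == rw$chrom[i] & pos0 >= rw$start[i] &
              pos0 < rw$end[i]), numeric(1))
      emit("random_null", data.frame(
        window = rw$label, chrom = rw$chrom, start = rw$start,
        end = rw$end, n_snps = rn,
        n_per_10kb = rn * 10000 / (rw$end - rw$start)))
    })
    .stage_log("variation", t0, nrow(snps), nrow(report$variation))
  }

  class(report) <- "report_bundle"
  report
}
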