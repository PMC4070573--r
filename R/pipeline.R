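default_stage_params <- function() {
  list(breakpoint_window = 400,
       gc_peak_window = 500, gc_background_window = 10000,
       gc_peak_step = 100, gc_rel_increase = 0.5,
       genotype_threshold = 1.5,
       merge_max_gap = 3000, merge_max_fraction = 0.8,
       filter_p_large = 0.60, filter_n_large = 50,
       filter_p_small = 0.75, filter_n_small = 30,
       hmm_means = c(-0.6, 0, 0.45), hmm_persistence = 0.999,
       caller2_k = 1, caller2_min_probes = 30, combine_min_coverage = 0.5,
       n_resamples = 1000, homology_perms = 100, top_k = 25,
       he_group_size = 5, he_draws = 1000,
       gc_profile_flank = 4000, gc_peak_max_distance = 4000)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a list (or a YAML file path) with optional keys `mode`
#' (`"synthetic"` or `"real"`), `seed`, `synthetic` (arguments for
#' [simulation_config()]), `paths` (real-mode input files) and `params`
#' (stage parameters). Missing entries are filled with defaults — the
#' stage parameters default to the study's stated values (400 bp
#' breakpoint windows, 500 bp / 10 kb GC windows, median +/- 1.5 SD
#' genotyping, 3 kb / 80% merging, 0.60/0.75/30/50 posterior filters,
#' 1,000 resamples, top-25 ranking). Unknown keys raise an error.
#'
#' @param config list or YAML path; `NULL` or an empty file gives all
#'   defaults (synthetic mode, seed 1).
#' @return a normalized list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config) %||% list()
  }
  config <- config %||% list()
  if (inherits(config, "pipeline_config")) return(config)
  known <- c("mode", "seed", "synthetic", "paths", "params")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  mode <- config$mode %||% "synthetic"
  if (!mode %in% c("synthetic", "real")) {
    stop("mode must be 'synthetic' or 'real'", call. = FALSE)
  }
  seed <- as.integer(config$seed %||% 1L)
  params <- default_stage_params()
  extra <- setdiff(names(config$params %||% list()), names(params))
  if (length(extra)) {
    stop(sprintf("unknown stage parameter(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  params[names(config$params %||% list())] <- config$params
  for (k in c("breakpoint_window", "gc_peak_window", "gc_background_window",
              "genotype_threshold", "n_resamples", "top_k")) {
    if (params[[k]] <= 0) stop(sprintf("%s must be positive", k),
                               call. = FALSE)
  }
  out <- list(mode = mode, seed = seed, params = params)
  if (mode == "synthetic") {
    syn_args <- config$synthetic %||% list()
    syn_args$seed <- syn_args$seed %||% seed
    out$synthetic <- do.call(simulation_config, syn_args)
    if (params$breakpoint_window > out$synthetic$cnv_len_range[1]) {
      warning("breakpoint window exceeds the minimum CNV length")
    }
  } else {
    paths <- config$paths %||% list()
    need <- c("probes_dir", "genome_fasta", "repeats_bed", "gaps_bed",
              "genes_bed", "regions_bed", "controls_bed", "samples_tsv")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      stop(sprintf("real mode needs paths: %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    for (k in setdiff(need, "probes_dir")) {
      if (!file.exists(paths[[k]])) {
        stop(sprintf("missing input file for %s: %s", k, paths[[k]]),
             call. = FALSE)
      }
    }
    if (!dir.exists(paths$probes_dir)) {
      stop(sprintf("missing probes directory: %s", paths$probes_dir),
           call. = FALSE)
    }
    out$paths <- paths
  }
  class(out) <- "pipeline_config"
  out
}

#' Run the full CNV pipeline end to end
#'
#' Synthetic mode generates the genome, annotations, truth genotypes and
#' per-sample probe tracks, then runs discovery (two callers, posterior
#' filter, conservative combination, within-sample merging, cross-sample
#' region definition), genotyping, sharing classification and
#' polarization, population genetics (VST ranking, heterozygosity
#' comparison), breakpoint analyses (GC peaks and profile, homology
#' permutation test, repeat enrichment), the gene-overlap randomization
#' test and the QC computations (control-region FDR, self-self calls).
#' Real mode reads the same inputs from files. Every stochastic stage
#' derives its own sub-seed from the master seed, so results are pure
#' functions of (config, seed).
#'
#' @param config a [validate_config()]-compatible list, YAML path or
#'   `pipeline_config`.
#' @param out_dir optional report directory (see [write_report()]).
#' @return a results list of class `canidcnv_results`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  config <- validate_config(config)
  pp <- config$params
  res <- list(seed = config$seed, stage_counts = list())
  if (config$mode == "synthetic") {
    syn <- generate_genome(config$synthetic)
    samples <- config$synthetic$samples
    truth <- draw_truth_genotypes(config$synthetic, samples, syn$cnv_loci)
    tracks <- simulate_acgh(truth, syn)
    genome <- syn$genome
    repeats <- syn$repeats; gaps <- syn$gaps; genes <- syn$genes
    panel <- syn$cnv_loci; controls <- syn$controls
    res$truth <- truth
    res$stage_counts$probes <- nrow(tracks[[1]])
  } else {
    genome <- read_fasta(config$paths$genome_fasta)
    repeats <- read_bed(config$paths$repeats_bed)
    gaps <- read_bed(config$paths$gaps_bed)
    genes <- read_bed(config$paths$genes_bed)
    panel <- read_bed(config$paths$regions_bed)
    controls <- read_bed(config$paths$controls_bed)
    samples <- read_sample_sheet(config$paths$samples_tsv)
    files <- file.path(config$paths$probes_dir,
                       paste0(samples$sample, ".tsv"))
    missing <- files[!file.exists(files)]
    if (length(missing)) {
      stop(sprintf("missing probe track(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    tracks <- lapply(files, read_probe_track)
    names(tracks) <- samples$sample
    for (s in samples$sample) attr(tracks[[s]], "source") <- s
  }

  # --- discovery
  segs <- lapply(samples$sample, function(s)
    discover_sample(tracks[[s]], repeats, gaps,
                    hmm_means = pp$hmm_means,
                    hmm_persistence = pp$hmm_persistence,
                    caller2_k = pp$caller2_k,
                    caller2_min_probes = pp$caller2_min_probes,
                    min_coverage = pp$combine_min_coverage))
  pooled <- do.call(rbind, segs)
  class(pooled) <- c("cnv_segments", "data.frame")
  regions <- define_regions(pooled)
  res$segments <- pooled
  res$regions <- regions
  res$stage_counts$segments <- nrow(pooled)
  res$stage_counts$regions <- nrow(regions)
  if (nrow(regions) == 0) {
    warning("no CNV regions discovered; downstream stages skipped")
    res$config_echo <- config_echo(config)
    class(res) <- "canidcnv_results"
    if (!is.null(out_dir)) write_report(res, out_dir)
    return(res)
  }

  # --- genotyping
  gm <- genotype_matrix(regions, tracks, samples,
                        threshold = pp$genotype_threshold)
  res$genotypes <- gm
  res$sharing <- classify_sharing(gm)
  res$polarization <- polarize_events(gm)
  res$per_sample <- per_sample_summary(gm)

  # --- population genetics
  vr <- vst_regions(gm)
  res$vst <- vr
  res$vst_top <- rank_vst(vr, k = min(pp$top_k, nrow(vr)))
  res$he <- wolf_subsample_he_test(gm, group_size = pp$he_group_size,
                                   n_draws = pp$he_draws, seed = config$seed)
  res$group_he <- group_mean_he(gm)

  # --- QC
  cgm <- genotype_matrix(controls, tracks, samples,
                         threshold = pp$genotype_threshold)
  res$control_fdr <- control_region_fdr(cgm)
  if (config$mode == "synthetic") {
    ss <- simulate_self_self(syn)
    res$self_self <- self_self_calls(ss, repeats, gaps,
                                     hmm_means = pp$hmm_means,
                                     hmm_persistence = pp$hmm_persistence,
                                     caller2_k = pp$caller2_k,
                                     caller2_min_probes = pp$caller2_min_probes,
                                     min_coverage = pp$combine_min_coverage)
  }

  # --- breakpoints
  pairs <- suppressWarnings(
    make_breakpoint_pairs(regions, window = pp$breakpoint_window,
                          genome = genome))
  res$breakpoint_pairs <- pairs
  peaks <- detect_gc_peaks(genome, peak_window = pp$gc_peak_window,
                           background_window = pp$gc_background_window,
                           step = pp$gc_peak_step,
                           rel_increase = pp$gc_rel_increase)
  res$gc_peaks <- peaks
  if (nrow(pairs) >= 2) {
    res$gc_profile <- gc_profile_around_breakpoints(
      pairs, genome, window = pp$breakpoint_window,
      flank = pp$gc_profile_flank)
    if (nrow(peaks) > 0) {
      res$gc_peak_profile <- gc_peak_breakpoint_profile(
        peaks, pairs, genome$lengths, step = pp$breakpoint_window,
        max_distance = pp$gc_peak_max_distance,
        n_resamples = pp$n_resamples, seed = config$seed)
    }
    res$homology <- homology_permutation_test(pairs, genome,
                                              n_perm = pp$homology_perms,
                                              seed = config$seed)
    res$repeat_enrichment <- repeat_enrichment(
      pairs, repeats, chrom_lengths = genome$lengths,
      n_resamples = pp$n_resamples, seed = config$seed,
      window_sizes = pp$breakpoint_window)
  }

  # --- gene-overlap randomization on dog-specific regions
  dog_specific <- names(res$sharing$class)[res$sharing$class == "dog_specific"]
  if (length(dog_specific) >= 1) {
    target <- regions[regions$label %in% dog_specific, , drop = FALSE]
    res$gene_enrichment <- gene_enrichment_test(
      as_interval_set(target), panel, genes, n = pp$n_resamples,
      seed = config$seed)
  }

  res$config_echo <- config_echo(config)
  res$stage_counts$cnv_regions <- res$sharing$n_cnv_regions
  class(res) <- "canidcnv_results"
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

config_echo <- function(config) {
  list(mode = config$mode, seed = config$seed,
       params = lapply(config$params, function(x)
         if (is.numeric(x)) as.numeric(x) else x))
}

#' @export
print.canidcnv_results <- function(x, ...) {
  cat("canidcnv pipeline results\n")
  cat(sprintf("  seed: %d\n", x$seed))
  for (k in names(x$stage_counts)) {
    cat(sprintf("  %s: %s\n", k, x$stage_counts[[k]]))
  }
  if (!is.null(x$sharing)) {
    cat(sprintf("  sharing: %s\n",
                paste(sprintf("%s=%d", names(x$sharing$counts),
                              as.integer(x$sharing$counts)), collapse = " ")))
  }
  if (!is.null(x$control_fdr)) {
    cat(sprintf("  control FDR: %.2f%% (%d/%d)\n", x$control_fdr$fdr_percent,
                x$control_fdr$calls, x$control_fdr$tests))
  }
  invisible(x)
}
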