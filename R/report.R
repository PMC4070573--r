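#' Write the pipeline report tables
#'
#' Emits, under `path`: the genotype matrix (`genotypes.tsv`), the
#' per-sample CNV summary in the Total/Gains/Loses layout
#' (`per_sample_summary.tsv`), the VST ranking (`vst_top.tsv`), a run
#' summary with sharing percentages and QC numbers (`summary.tsv`) and a
#' plain-text run log echoing seed and configuration (`run_log.txt`).
#' Output is a pure function of the results object: two runs with the
#' same config and seed give byte-identical files.
#'
#' @param results a results list from [run_pipeline()] (or a compatible
#'   subset; missing components yield headers-only tables).
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (file.access(path, 2) != 0) {
    stop(sprintf("cannot write to %s", path), call. = FALSE)
  }
  tsv <- function(df, file) {
    utils::write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  gm <- results$genotypes
  if (!is.null(gm)) {
    gdf <- data.frame(region = rownames(gm$calls),
                      chrom = gm$regions$chrom,
                      start = gm$regions$start, end = gm$regions$end,
                      stringsAsFactors = FALSE)
    gdf <- cbind(gdf, as.data.frame(gm$calls, stringsAsFactors = FALSE))
    tsv(gdf, "genotypes.tsv")
    ps <- per_sample_summary(gm)
    names(ps) <- c("sample", "total", "gains", "loses", "unique_total",
                   "unique_gains", "unique_loses")
    tsv(ps, "per_sample_summary.tsv")
  } else {
    tsv(data.frame(region = character(), chrom = character(),
                   start = numeric(), end = numeric()), "genotypes.tsv")
    tsv(data.frame(sample = character(), total = integer(),
                   gains = integer(), loses = integer(),
                   unique_total = integer(), unique_gains = integer(),
                   unique_loses = integer()), "per_sample_summary.tsv")
  }
  vt <- results$vst_top
  if (is.null(vt)) {
    vt <- data.frame(region = character(), chrom = character(),
                     start = numeric(), end = numeric(), vt = numeric(),
                     vs = numeric(), vst = numeric())
  }
  vt_out <- data.frame(vst = sprintf("%.3f", vt$vst), chrom = vt$chrom,
                       start = vt$start, end = vt$end, region = vt$region)
  if (!is.null(vt$genes)) vt_out$genes <- vt$genes
  tsv(vt_out, "vst_top.tsv")

  summ <- list()
  add <- function(metric, value) {
    summ[[length(summ) + 1]] <<- data.frame(metric = metric,
                                            value = as.character(value))
  }
  if (!is.null(results$sharing)) {
    sh <- results$sharing
    add("cnv_regions", sh$n_cnv_regions)
    for (k in names(sh$counts)) add(paste0("regions_", k), sh$counts[[k]])
    for (k in names(sh$percent)) {
      add(paste0("percent_", k), sprintf("%.1f", sh$percent[[k]]))
    }
  }
  if (!is.null(results$polarization)) {
    add("post_domestication_duplications", results$polarization$n_duplications)
    add("post_domestication_deletions", results$polarization$n_deletions)
  }
  if (!is.null(results$control_fdr)) {
    add("control_calls", results$control_fdr$calls)
    add("control_tests", results$control_fdr$tests)
    add("control_fdr_percent", sprintf("%.2f", results$control_fdr$fdr_percent))
  }
  if (!is.null(results$self_self)) add("self_self_calls", results$self_self)
  if (!is.null(results$he)) {
    add("dog_mean_he", sprintf("%.3f", results$he$dog_he))
    add("wolf_subsample_mean_he", sprintf("%.3f", results$he$null_mean))
    add("wolf_subsample_sd_he", sprintf("%.3f", results$he$null_sd))
    add("he_p_value", sprintf("%.3f", results$he$p_value))
  }
  if (!is.null(results$homology)) {
    add("homology_observed_mean_bp", sprintf("%.1f", results$homology$observed_mean))
    add("homology_null_mean_bp", sprintf("%.1f", results$homology$null_mean))
    add("homology_p_value", sprintf("%.4g", results$homology$p_value))
  }
  summ_df <- if (length(summ)) do.call(rbind, summ) else
    data.frame(metric = character(), value = character())
  tsv(summ_df, "summary.tsv")

  log_lines <- c("canidcnv run log",
                 sprintf("package_version: %s",
                         as.character(utils::packageVersion("canidcnv"))),
                 sprintf("seed: %s", results$seed %||% "NA"),
                 "config:",
                 paste0("  ", strsplit(yaml::as.yaml(results$config_echo %||%
                                                       list()), "\n")[[1]]),
                 "stage_counts:")
  for (k in names(results$stage_counts %||% list())) {
    log_lines <- c(log_lines,
                   sprintf("  %s: %s", k, results$stage_counts[[k]]))
  }
  writeLines(log_lines, file.path(path, "run_log.txt"))
  invisible(path)
}
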