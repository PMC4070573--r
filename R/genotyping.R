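#' Chip-wide log2 statistics for one sample
#'
#' The genotyping thresholds are anchored on the whole chip: the median and
#' standard deviation of all of the sample's probe log2 values.
#'
#' @param track a [probe_track()].
#' @return list of class `chip_stats` with `median` and `sd`.
#' @export
chip_stats <- function(track) {
  s <- stats::sd(track$log2ratio)
  if (!is.finite(s) || s <= 0) stop("chip SD must be positive", call. = FALSE)
  structure(list(median = stats::median(track$log2ratio), sd = s),
            class = "chip_stats")
}

#' Genotype one sample at one region
#'
#' The mean log2 ratio over the region's probes is compared with the
#' chip-wide median +/- `threshold` standard deviations: at or above the
#' upper bound is a gain, at or below the lower bound a loss, otherwise
#' equal copy. Ties exactly at a bound are non-equal calls.
#'
#' @param region one row of a region [interval_set()] (needs `chrom`,
#'   `start`, `end`, `label`).
#' @param track the sample's [probe_track()].
#' @param stats the sample's [chip_stats()].
#' @param threshold multiplier on the chip SD.
#' @return `"loss"`, `"equal"` or `"gain"`.
#' @export
genotype_region <- function(region, track, stats, threshold = 1.5) {
  sel <- track$chrom == region$chrom & track$position >= region$start &
    track$position < region$end
  if (!any(sel)) {
    stop(sprintf("no probes in region %s (%s:%s-%s)",
                 region$label, region$chrom,
                 format(region$start, scientific = FALSE),
                 format(region$end, scientific = FALSE)), call. = FALSE)
  }
  m <- mean(track$log2ratio[sel])
  if (m >= stats$median + threshold * stats$sd) return("gain")
  if (m <= stats$median - threshold * stats$sd) return("loss")
  "equal"
}

#' Genotype all samples at all regions
#'
#' @param regions region [interval_set()] (labels are region ids).
#' @param tracks named list of [probe_track()]s, one per sample.
#' @param samples a [sample_sheet()] covering the track names.
#' @param threshold multiplier on the chip SD (see [genotype_region()]).
#' @return object of class `genotype_matrix`: list with `calls` (character
#'   matrix, regions x samples, values loss/equal/gain), `regions`,
#'   `samples`, and `region_log2` (matrix of per-sample region mean log2
#'   ratios, the substrate of the VST statistic).
#' @export
genotype_matrix <- function(regions, tracks, samples, threshold = 1.5) {
  stopifnot(all(samples$sample %in% names(tracks)))
  nr <- nrow(regions)
  ns <- nrow(samples)
  calls <- matrix("equal", nr, ns,
                  dimnames = list(regions$label, samples$sample))
  lmat <- matrix(NA_real_, nr, ns,
                 dimnames = list(regions$label, samples$sample))
  for (s in samples$sample) {
    track <- tracks[[s]]
    cs <- chip_stats(track)
    for (i in seq_len(nr)) {
      region <- regions[i, , drop = FALSE]
      calls[i, s] <- genotype_region(region, track, cs, threshold)
      sel <- track$chrom == region$chrom & track$position >= region$start &
        track$position < region$end
      lmat[i, s] <- mean(track$log2ratio[sel])
    }
  }
  structure(list(calls = calls, regions = regions, samples = samples,
                 region_log2 = lmat), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d regions x %d samples\n",
              nrow(x$calls), ncol(x$calls)))
  tab <- table(factor(x$calls, levels = c("loss", "equal", "gain")))
  cat(sprintf("  calls: %d loss, %d equal, %d gain\n",
              tab["loss"], tab["equal"], tab["gain"]))
  invisible(x)
}

group_cols <- function(gm, groups) {
  gm$samples$sample[gm$samples$group %in% groups]
}

#' Classify CNV sharing between dogs and wild canids
#'
#' Per region: `dog_specific` when at least one dog (dingo included) has a
#' non-equal call and no wild canid (gray wolves and outgroup species)
#' does; `wild_specific` symmetrically; `shared` when both sides carry
#' non-equal calls; `monomorphic` when nobody does.
#'
#' @param gm a [genotype_matrix()].
#' @return list of class `sharing_classification`: `class` (named character
#'   vector per region), `counts`, `percent` (of polymorphic regions, one
#'   decimal), `n_cnv_regions` (polymorphic region count).
#' @export
classify_sharing <- function(gm) {
  dogs <- group_cols(gm, "dog")
  wild <- group_cols(gm, c("wolf", "outgroup"))
  dog_cnv <- apply(gm$calls[, dogs, drop = FALSE] != "equal", 1, any)
  wild_cnv <- apply(gm$calls[, wild, drop = FALSE] != "equal", 1, any)
  cls <- ifelse(dog_cnv & wild_cnv, "shared",
                ifelse(dog_cnv, "dog_specific",
                       ifelse(wild_cnv, "wild_specific", "monomorphic")))
  names(cls) <- rownames(gm$calls)
  counts <- table(factor(cls, levels = c("dog_specific", "wild_specific",
                                         "shared", "monomorphic")))
  n_cnv <- sum(cls != "monomorphic")
  pct <- if (n_cnv > 0) {
    vapply(c("dog_specific", "wild_specific", "shared"),
           function(k) as.numeric(fmt_percent1(counts[[k]], n_cnv)), 0)
  } else c(dog_specific = NA_real_, wild_specific = NA_real_,
           shared = NA_real_)
  structure(list(class = cls, counts = counts, percent = pct,
                 n_cnv_regions = n_cnv), class = "sharing_classification")
}

#' Polarize CNV events against gray wolves
#'
#' A post-domestication duplication is a gain present in at least one dog
#' (dingo included) and absent from all gray wolves; deletions
#' symmetrically for losses. The outgroup species are not consulted here:
#' the comparison is stated against wolves only. One region can carry both
#' flags.
#'
#' @param gm a [genotype_matrix()].
#' @return list of class `polarization`: logical vectors `duplication` and
#'   `deletion` per region plus `n_duplications`, `n_deletions`.
#' @export
polarize_events <- function(gm) {
  dogs <- group_cols(gm, "dog")
  wolves <- group_cols(gm, "wolf")
  if (!length(wolves)) stop("no gray wolves in the sample sheet", call. = FALSE)
  dog_gain <- apply(gm$calls[, dogs, drop = FALSE] == "gain", 1, any)
  dog_loss <- apply(gm$calls[, dogs, drop = FALSE] == "loss", 1, any)
  wolf_gain <- apply(gm$calls[, wolves, drop = FALSE] == "gain", 1, any)
  wolf_loss <- apply(gm$calls[, wolves, drop = FALSE] == "loss", 1, any)
  dup <- dog_gain & !wolf_gain
  del <- dog_loss & !wolf_loss
  names(dup) <- names(del) <- rownames(gm$calls)
  structure(list(duplication = dup, deletion = del,
                 n_duplications = sum(dup), n_deletions = sum(del)),
            class = "polarization")
}

#' Per-sample CNV summary table
#'
#' One row per sample: total non-equal calls split into gains and losses,
#' plus the unique calls (regions where this sample is the only one in the
#' panel with a non-equal call), in the layout of the study's per-sample
#' summary table.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with columns sample, total, gains, losses,
#'   unique_total, unique_gains, unique_losses.
#' @export
per_sample_summary <- function(gm) {
  calls <- gm$calls
  non_equal_per_region <- rowSums(calls != "equal")
  out <- lapply(colnames(calls), function(s) {
    g <- calls[, s] == "gain"
    l <- calls[, s] == "loss"
    uniq <- (g | l) & non_equal_per_region == 1
    data.frame(sample = s, total = sum(g) + sum(l), gains = sum(g),
               losses = sum(l), unique_total = sum(uniq),
               unique_gains = sum(uniq & g), unique_losses = sum(uniq & l),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
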