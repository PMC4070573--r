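#' Count distinct genes overlapped by a region set
#'
#' A gene is counted once no matter how many regions it overlaps (>= 1 bp).
#'
#' @param regions an [interval_set()].
#' @param genes a gene [interval_set()] (labels are gene ids).
#' @return integer count of distinct overlapped genes.
#' @export
count_gene_overlaps <- function(regions, genes) {
  length(overlapping_rows(genes, regions))
}

#' Gene-overlap randomization test for a region set
#'
#' The observed distinct-gene count of the target set is compared with the
#' null distribution over simulated sets with the same number and lengths
#' of regions, each simulated region being a same-length window placed
#' uniformly inside a uniformly chosen universe region that can hold it
#' (the array footprint is the universe, not the whole genome). The
#' empirical p-value is two-sided: `(b + 1) / (n + 1)` with `b` the number
#' of null counts at least as far from the null mean as the observed
#' count.
#'
#' @param target the region [interval_set()] under test.
#' @param universe the universe [interval_set()] the nulls are drawn from.
#' @param genes gene [interval_set()].
#' @param n number of simulated sets.
#' @param seed RNG seed.
#' @return list of class `gene_overlap_test`: `observed`, `null_counts`,
#'   `null_mean`, `p_value`, `enrichment` (observed / null mean).
#' @export
gene_enrichment_test <- function(target, universe, genes, n = 1000,
                                 seed = 1) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  lens <- target$end - target$start
  ulens <- universe$end - universe$start
  bad <- which(lens > max(ulens))
  if (length(bad)) {
    stop(sprintf("target region %s (%d bp) is longer than every universe region",
                 target$label[bad[1]] %||% bad[1], lens[bad[1]]),
         call. = FALSE)
  }
  observed <- count_gene_overlaps(target, genes)
  null_counts <- with_seed(subseed(seed, "gene-enrichment"), {
    vapply(seq_len(n), function(r) {
      sim <- simulate_matched_set(lens, universe)
      count_gene_overlaps(sim, genes)
    }, 0)
  })
  nm <- mean(null_counts)
  b <- sum(abs(null_counts - nm) >= abs(observed - nm))
  structure(list(observed = observed, null_counts = null_counts,
                 null_mean = nm, p_value = (b + 1) / (n + 1),
                 enrichment = if (nm > 0) observed / nm else NA_real_),
            class = "gene_overlap_test")
}

# One simulated set: for each target length, choose a universe region that
# can hold it uniformly at random, then a uniform same-length window
# within it.
simulate_matched_set <- function(lens, universe) {
  ulens <- universe$end - universe$start
  chrom <- character(length(lens))
  start <- numeric(length(lens))
  for (i in seq_along(lens)) {
    ok <- which(ulens >= lens[i])
    u <- ok[sample.int(length(ok), 1L)]
    off <- floor(stats::runif(1, 0, ulens[u] - lens[i] + 1))
    chrom[i] <- universe$chrom[u]
    start[i] <- universe$start[u] + off
  }
  interval_set(chrom, start, start + lens)
}

#' Control-region false discovery rate
#'
#' Non-equal genotype calls on putative single-copy control regions are
#' false positives; the FDR percentage is `100 * calls / tests`,
#' floor-truncated to two decimals (17 calls over 966 tests prints as
#' 1.75).
#'
#' @param calls number of non-equal calls on control regions, or a
#'   [genotype_matrix()] restricted to control regions.
#' @param tests number of (region x sample) tests; ignored when `calls`
#'   is a genotype matrix.
#' @return list of class `control_fdr`: `calls`, `tests`, `fdr_percent`.
#' @export
control_region_fdr <- function(calls, tests = NULL) {
  if (inherits(calls, "genotype_matrix")) {
    tests <- length(calls$calls)
    calls <- sum(calls$calls != "equal")
  }
  if (is.null(tests) || tests == 0) {
    stop("number of control tests must be positive", call. = FALSE)
  }
  structure(list(calls = calls, tests = tests,
                 fdr_percent = truncate_percent2(calls, tests)),
            class = "control_fdr")
}

#' CNV calls on a self-self hybridization
#'
#' Runs the full discovery stack (both callers, posterior filter,
#' conservative combination, within-sample merging) on a track from a
#' same-individual hybridization, where every call is a false positive.
#'
#' @param track a [probe_track()] with no true CNVs.
#' @param repeats,gaps annotation [interval_set()]s for the merging rule.
#' @param ... passed to [discover_sample()].
#' @return integer number of post-filter CNV calls.
#' @export
self_self_calls <- function(track, repeats = interval_set(),
                            gaps = interval_set(), ...) {
  nrow(discover_sample(track, repeats, gaps, ...))
}

#' Concordance of aCGH calls with qPCR copy numbers
#'
#' Taking the qPCR integer copy numbers as truth (gain when above the
#' reference copy, loss when below, equal at it): the false positive rate
#' is the fraction of comparisons where aCGH called non-equal but qPCR
#' says equal, and the false negative rate the fraction of comparisons
#' where aCGH called equal but qPCR says non-equal.
#'
#' @param acgh_calls character vector of aCGH calls (loss/equal/gain) per
#'   (sample, region) observation.
#' @param qpcr_copies parallel integer qPCR copy numbers.
#' @param reference_copy diploid reference copy number (default 2).
#' @return list of class `concordance_report`: `comparisons`,
#'   `false_positive_rate`, `false_negative_rate`.
#' @export
qpcr_concordance <- function(acgh_calls, qpcr_copies, reference_copy = 2) {
  if (length(acgh_calls) != length(qpcr_copies)) {
    stop("aCGH calls and qPCR copies must be paired", call. = FALSE)
  }
  if (any(is.na(acgh_calls)) || any(is.na(qpcr_copies))) {
    stop("unpaired (missing) records", call. = FALSE)
  }
  qstate <- ifelse(qpcr_copies > reference_copy, "gain",
                   ifelse(qpcr_copies < reference_copy, "loss", "equal"))
  acgh_pos <- acgh_calls != "equal"
  q_pos <- qstate != "equal"
  n <- length(acgh_calls)
  fp <- sum(acgh_pos & !q_pos) / n
  fn <- sum(!acgh_pos & q_pos) / n
  structure(list(comparisons = length(acgh_calls),
                 false_positive_rate = fp, false_negative_rate = fn),
            class = "concordance_report")
}
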