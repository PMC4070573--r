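#' Breakpoint window pairs of CNVs
#'
#' Each CNV contributes two breakpoint windows of `window` bp centered on
#' its start and end coordinates, absorbing the positional uncertainty of
#' array-based breakpoint inference. Windows are clipped at chromosome
#' edges with a warning; CNVs shorter than the window are skipped with a
#' warning.
#'
#' @param cnvs an [interval_set()] of CNV regions (labels become ids).
#' @param window window size in bp (default 400, the smallest detected CNV).
#' @param genome optional `genome_sequence`; when given, window sequences
#'   are extracted into `left_seq` / `right_seq`.
#' @return data.frame of class `breakpoint_pairs`: id, chrom, cnv_start,
#'   cnv_end, left_start, left_end, right_start, right_end (0-based
#'   half-open), plus sequences when a genome is supplied. The window size
#'   is kept in attribute `window`.
#' @export
make_breakpoint_pairs <- function(cnvs, window = 400, genome = NULL) {
  half <- window / 2
  keep <- (cnvs$end - cnvs$start) >= window
  if (any(!keep)) {
    warning(sprintf("%d CNV(s) shorter than the %d bp window skipped",
                    sum(!keep), window))
  }
  cnvs <- cnvs[keep, , drop = FALSE]
  df <- data.frame(id = if (all(is.na(cnvs$label)))
    sprintf("cnv_%04d", seq_len(nrow(cnvs))) else cnvs$label,
    chrom = cnvs$chrom, cnv_start = cnvs$start, cnv_end = cnvs$end,
    left_start = floor(cnvs$start - half), left_end = floor(cnvs$start + half),
    right_start = floor(cnvs$end - half), right_end = floor(cnvs$end + half),
    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    lens <- genome$lengths[df$chrom]
    clipped <- df$left_start < 0 | df$right_end > lens
    if (any(clipped)) {
      warning(sprintf("%d breakpoint window(s) clipped at chromosome edges",
                      sum(clipped)))
    }
    df$left_start <- pmax(df$left_start, 0)
    df$right_end <- pmin(df$right_end, lens)
    df$left_end <- pmin(df$left_end, lens)
    df$right_start <- pmax(df$right_start, 0)
    df$left_seq <- vapply(seq_len(nrow(df)), function(i)
      subsequence(genome, df$chrom[i], df$left_start[i], df$left_end[i]), "")
    df$right_seq <- vapply(seq_len(nrow(df)), function(i)
      subsequence(genome, df$chrom[i], df$right_start[i], df$right_end[i]), "")
  }
  attr(df, "window") <- window
  class(df) <- c("breakpoint_pairs", "data.frame")
  df
}

#' Detect peaks of elevated GC content
#'
#' A 500 bp peak-discovery window centered in a 10 kb background window is
#' slid along each chromosome; a position qualifies when the peak window's
#' GC fraction exceeds the background's (which includes the peak span) by
#' more than `rel_increase` (50%: peak > 1.5 x background). Qualifying
#' overlapping or adjacent peak windows are merged into maximal peaks of
#' 500 bp or more, and each merged peak is re-checked against its own
#' centered background before being reported. N bases never count toward
#' GC denominators; windows more than half N are dropped.
#'
#' @param genome a `genome_sequence`.
#' @param peak_window peak-discovery window (bp).
#' @param background_window background window (bp).
#' @param step slide step (bp).
#' @param rel_increase required relative GC increase of peak over
#'   background.
#' @return an [interval_set()] of peaks with extra columns `peak_gc` and
#'   `background_gc`.
#' @export
detect_gc_peaks <- function(genome, peak_window = 500,
                            background_window = 10000, step = 100,
                            rel_increase = 0.5) {
  rows <- list()
  for (ch in names(genome$seq)) {
    len <- genome$lengths[[ch]]
    if (len < background_window) next
    cs <- base_cumsums(genome$seq[[ch]])
    bg_start <- seq(0, len - background_window, by = step)
    pk_start <- bg_start + (background_window - peak_window) / 2
    pk_gc <- window_gc_from_cumsums(cs, pk_start, pk_start + peak_window)
    bg_gc <- window_gc_from_cumsums(cs, bg_start, bg_start + background_window)
    n_frac <- window_n_fraction(cs, pk_start, pk_start + peak_window)
    ok <- !is.na(pk_gc) & !is.na(bg_gc) & n_frac <= 0.5 &
      pk_gc > (1 + rel_increase) * bg_gc
    if (!any(ok)) next
    ir <- IRanges::reduce(IRanges::IRanges(pk_start[ok] + 1,
                                           pk_start[ok] + peak_window),
                          min.gapwidth = 1L)
    m_start <- IRanges::start(ir) - 1
    m_end <- IRanges::end(ir)
    # re-check each merged peak against its own centered background
    center <- (m_start + m_end) / 2
    rb_start <- pmax(0, pmin(len - background_window,
                             round(center - background_window / 2)))
    m_gc <- window_gc_from_cumsums(cs, m_start, m_end)
    rb_gc <- window_gc_from_cumsums(cs, rb_start, rb_start + background_window)
    ok2 <- !is.na(m_gc) & !is.na(rb_gc) & m_gc > (1 + rel_increase) * rb_gc
    if (!any(ok2)) next
    rows[[ch]] <- data.frame(chrom = ch, start = m_start[ok2],
                             end = m_end[ok2], peak_gc = m_gc[ok2],
                             background_gc = rb_gc[ok2],
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- interval_set()
    out$peak_gc <- out$background_gc <- numeric()
    return(out)
  }
  df <- do.call(rbind, rows)
  out <- interval_set(df$chrom, df$start, df$end, "gc_peak")
  out$peak_gc <- df$peak_gc
  out$background_gc <- df$background_gc
  rownames(out) <- NULL
  out
}

#' GC profile around CNV breakpoints
#'
#' Mean GC content in sliding `window`-bp bins at signed distances from
#' the breakpoints: negative offsets lie inside the CNV, positive outside.
#' An inside window only draws on CNVs long enough to contain it, and the
#' proportion of breakpoints contributing at each offset is reported
#' alongside the unweighted mean. Windows falling off the chromosome or
#' more than half N are dropped.
#'
#' @param pairs a [make_breakpoint_pairs()] result.
#' @param genome a `genome_sequence`.
#' @param window bin width in bp.
#' @param flank maximal absolute offset (bp); a multiple of `window`.
#' @return data.frame: offset_bp (signed window center offset), mean_gc,
#'   coverage_proportion, n_windows.
#' @export
gc_profile_around_breakpoints <- function(pairs, genome, window = 400,
                                          flank = 4000) {
  if (flank %% window != 0) {
    stop("flank must be a multiple of the window size", call. = FALSE)
  }
  nf <- flank / window
  offsets <- setdiff(seq(-nf, nf), 0) * window
  offsets <- c(offsets, 0)
  offsets <- sort(offsets)
  cs_cache <- lapply(genome$seq, base_cumsums)
  # each pair contributes two breakpoints; `outward` is +1 when increasing
  # coordinates move out of the CNV
  bp <- rbind(data.frame(chrom = pairs$chrom, pos = pairs$cnv_start,
                         outward = -1, len = pairs$cnv_end - pairs$cnv_start),
              data.frame(chrom = pairs$chrom, pos = pairs$cnv_end,
                         outward = 1, len = pairs$cnv_end - pairs$cnv_start))
  out <- lapply(offsets, function(off) {
    center <- bp$pos + bp$outward * off
    w_start <- round(center - window / 2)
    w_end <- w_start + window
    ok <- rep(TRUE, nrow(bp))
    if (off < 0) {
      # window must lie fully inside the CNV
      ok <- bp$len >= (-off + window / 2)
    }
    lens <- genome$lengths[bp$chrom]
    ok <- ok & w_start >= 0 & w_end <= lens
    gc <- rep(NA_real_, nrow(bp))
    for (ch in unique(bp$chrom[ok])) {
      sel <- ok & bp$chrom == ch
      cs <- cs_cache[[ch]]
      nf_ <- window_n_fraction(cs, w_start[sel], w_end[sel])
      g <- window_gc_from_cumsums(cs, w_start[sel], w_end[sel])
      g[nf_ > 0.5] <- NA
      gc[sel] <- g
    }
    data.frame(offset_bp = off, mean_gc = mean(gc, na.rm = TRUE),
               coverage_proportion = sum(ok) / nrow(bp),
               n_windows = sum(ok & !is.na(gc)))
  })
  do.call(rbind, out)
}

#' Longest stretch of perfect homology between two sequences
#'
#' Length of the longest common substring of `a` and `b` over A/C/G/T;
#' N never matches, not even another N. Implemented as a binary search
#' over candidate lengths with substring-set intersection, which matches
#' the quadratic dynamic-programming computation exactly.
#'
#' @param a,b character strings (A/C/G/T/N).
#' @return integer length (0 for empty input or no common substring).
#' @export
longest_perfect_homology <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(0L)
  has_k <- function(k) {
    sa <- substring(a, 1:(na - k + 1), k:na)
    sa <- sa[!grepl("N", sa, fixed = TRUE)]
    if (!length(sa)) return(FALSE)
    sb <- substring(b, 1:(nb - k + 1), k:nb)
    sb <- sb[!grepl("N", sb, fixed = TRUE)]
    if (!length(sb)) return(FALSE)
    any(sa %in% sb)
  }
  lo <- 0L
  hi <- min(na, nb)
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (has_k(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

# Re-place each breakpoint pair uniformly on its own chromosome, keeping
# the two breakpoints at the same distance from each other. Window
# sequences are re-extracted when a genome is supplied.
redistribute_pairs <- function(pairs, chrom_lengths, genome = NULL) {
  w <- attr(pairs, "window")
  half <- w / 2
  d <- pairs$cnv_end - pairs$cnv_start
  len <- chrom_lengths[pairs$chrom]
  lo <- half
  hi <- len - d - half
  short <- hi <= lo
  if (any(short)) {
    stop(sprintf("chromosome %s too short to re-place pair %s",
                 pairs$chrom[which(short)[1]], pairs$id[which(short)[1]]),
         call. = FALSE)
  }
  new_start <- floor(stats::runif(nrow(pairs), lo, hi))
  out <- pairs
  out$cnv_start <- new_start
  out$cnv_end <- new_start + d
  out$left_start <- new_start - half
  out$left_end <- new_start + half
  out$right_start <- out$cnv_end - half
  out$right_end <- out$cnv_end + half
  if (!is.null(genome)) {
    out$left_seq <- vapply(seq_len(nrow(out)), function(i)
      subsequence(genome, out$chrom[i], out$left_start[i], out$left_end[i]), "")
    out$right_seq <- vapply(seq_len(nrow(out)), function(i)
      subsequence(genome, out$chrom[i], out$right_start[i], out$right_end[i]),
      "")
  }
  out
}

#' Permutation test of breakpoint-pair homology
#'
#' The longest perfect-homology stretch is recorded for every real
#' breakpoint pair, then the pairs are repeatedly re-placed uniformly on
#' their own chromosome (keeping the two breakpoints at the same distance
#' from each other) and the same statistic is recorded. Real and
#' redistributed per-pair values are compared with a two-sample Wilcoxon
#' rank-sum test (exact when the combined sample is small and untied,
#' otherwise the tie-corrected normal approximation).
#'
#' @param pairs a [make_breakpoint_pairs()] result with sequences.
#' @param genome the `genome_sequence`.
#' @param n_perm number of redistributions.
#' @param seed RNG seed.
#' @return list of class `homology_test`: `observed_mean`, `null_mean`,
#'   `p_value`, `observed` and `null` per-pair values.
#' @export
homology_permutation_test <- function(pairs, genome, n_perm = 100, seed = 1) {
  if (nrow(pairs) < 2) stop("need at least 2 breakpoint pairs", call. = FALSE)
  obs <- vapply(seq_len(nrow(pairs)), function(i)
    longest_perfect_homology(pairs$left_seq[i], pairs$right_seq[i]), 0L)
  null <- with_seed(subseed(seed, "homology-perm"), {
    unlist(lapply(seq_len(n_perm), function(r) {
      rp <- redistribute_pairs(pairs, genome$lengths, genome)
      vapply(seq_len(nrow(rp)), function(i)
        longest_perfect_homology(rp$left_seq[i], rp$right_seq[i]), 0L)
    }))
  })
  p <- wilcoxon_p(obs, null)
  structure(list(observed_mean = mean(obs), null_mean = mean(null),
                 p_value = p, observed = obs, null = null),
            class = "homology_test")
}

# Two-sample Wilcoxon rank-sum p-value: exact for small untied samples,
# tie-corrected normal approximation otherwise.
wilcoxon_p <- function(x, y) {
  exact <- (length(x) + length(y)) < 30 && !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact)$p.value)
}

#' Enrichment of GC peaks near CNV breakpoints by distance bin
#'
#' Counts GC peaks whose midpoint falls within each `step`-bp distance bin
#' of the nearest breakpoint, and compares each bin's count against the
#' null obtained by re-placing the breakpoint pairs chromosome-wise
#' (intra-pair distance preserved).
#'
#' @param peaks an interval set of GC peaks (from [detect_gc_peaks()]).
#' @param pairs a [make_breakpoint_pairs()] result.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param step bin width in bp.
#' @param max_distance largest distance considered (bp).
#' @param n_resamples number of redistributions.
#' @param seed RNG seed.
#' @return data.frame, one row per bin: bin_start, bin_end, observed,
#'   null_mean, null_sd, ratio, p_value (one-sided enrichment,
#'   `(b+1)/(n+1)`).
#' @export
gc_peak_breakpoint_profile <- function(peaks, pairs, chrom_lengths,
                                       step = 400, max_distance = 4000,
                                       n_resamples = 1000, seed = 1) {
  breaks <- seq(0, max_distance, by = step)
  count_bins <- function(pp) {
    mid <- (peaks$start + peaks$end) / 2
    d <- rep(Inf, nrow(peaks))
    for (ch in unique(pp$chrom)) {
      sel <- peaks$chrom == ch
      if (!any(sel)) next
      bp_pos <- c(pp$cnv_start[pp$chrom == ch], pp$cnv_end[pp$chrom == ch])
      d[sel] <- vapply(mid[sel], function(m) min(abs(m - bp_pos)), 0)
    }
    tabulate(findInterval(d, breaks, rightmost.closed = FALSE,
                          left.open = FALSE), nbins = length(breaks) - 1)
  }
  obs <- count_bins(pairs)
  null <- with_seed(subseed(seed, "gc-peak-profile"), {
    vapply(seq_len(n_resamples), function(r)
      count_bins(redistribute_pairs(pairs, chrom_lengths)),
      numeric(length(obs)))
  })
  null <- matrix(null, nrow = length(obs))
  nm <- rowMeans(null)
  nsd <- apply(null, 1, stats::sd)
  p <- vapply(seq_along(obs), function(i)
    (sum(null[i, ] >= obs[i]) + 1) / (n_resamples + 1), 0)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             observed = obs, null_mean = nm, null_sd = nsd,
             ratio = ifelse(nm > 0, obs / nm, NA_real_), p_value = p)
}

# Family of a repeat label: "L1/Canis" -> "L1", "SINE" -> "SINE".
repeat_family <- function(labels) sub("/.*$", "", labels)

#' Relabel L1 repeats by age class
#'
#' L1 elements carry labels of the form `"L1/<age class>"`; this helper
#' keeps only L1 rows and uses the age class as the label, so that
#' [repeat_enrichment()] stratifies by age.
#'
#' @param repeats a repeat [interval_set()].
#' @return an [interval_set()] of L1 elements labelled by age class.
#' @export
l1_age_labels <- function(repeats) {
  l1 <- repeats[repeat_family(repeats$label) == "L1", , drop = FALSE]
  interval_set(l1$chrom, l1$start, l1$end, sub("^L1/", "", l1$label))
}

#' Repeat enrichment in breakpoint windows
#'
#' For each repeat family and each breakpoint window size, counts the
#' distinct repeat elements overlapping any breakpoint window and compares
#' against the null from chromosome-wise redistribution of the pairs
#' (intra-pair distance preserved). The observed/expected ratio uses the
#' null mean as expectation.
#'
#' @param pairs a [make_breakpoint_pairs()] result.
#' @param repeats repeat [interval_set()]; labels are families (optionally
#'   `"L1/<age>"`; matching is on the family part).
#' @param families families to test; default all present.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param n_resamples number of redistributions.
#' @param seed RNG seed.
#' @param window_sizes breakpoint window sizes (bp) to scan.
#' @return data.frame: family, window, observed, null_mean, null_sd,
#'   ratio, p_value (one-sided enrichment).
#' @export
repeat_enrichment <- function(pairs, repeats, families = NULL, chrom_lengths,
                              n_resamples = 1000, seed = 1,
                              window_sizes = 400) {
  fam_all <- repeat_family(repeats$label)
  if (is.null(families)) families <- sort(unique(fam_all))
  unknown <- setdiff(families, fam_all)
  if (length(unknown)) {
    stop(sprintf("unknown repeat family: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  count_for <- function(pp, fam_rows, w) {
    half <- w / 2
    win <- interval_set(rep(pp$chrom, 2),
                        pmax(0, c(pp$cnv_start - half, pp$cnv_end - half)),
                        c(pp$cnv_start + half, pp$cnv_end + half))
    length(overlapping_rows(fam_rows, win))
  }
  out <- list()
  for (w in window_sizes) {
    for (f in families) {
      fam_rows <- repeats[fam_all == f, , drop = FALSE]
      obs <- count_for(pairs, fam_rows, w)
      null <- with_seed(subseed(seed, sprintf("repeat-enrich:%s:%d", f, w)), {
        vapply(seq_len(n_resamples), function(r)
          count_for(redistribute_pairs(pairs, chrom_lengths), fam_rows, w), 0)
      })
      out[[length(out) + 1]] <- data.frame(
        family = f, window = w, observed = obs, null_mean = mean(null),
        null_sd = stats::sd(null),
        ratio = if (mean(null) > 0) obs / mean(null) else NA_real_,
        p_value = (sum(null >= obs) + 1) / (n_resamples + 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
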