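#' Three-state Gaussian HMM segmentation of a probe track
#'
#' Stage-1 caller: a fixed-architecture hidden Markov model with states
#' loss / normal / gain, Gaussian emissions with state means and a shared
#' standard deviation, and a symmetric sticky transition matrix. The track
#' is decoded per chromosome: forward-backward posteriors are computed, the
#' Viterbi path is taken, and every maximal run of a non-normal state
#' becomes a candidate segment whose posterior support is the mean
#' forward-backward posterior of the called state over its probes.
#'
#' @param track a [probe_track()].
#' @param means emission means for (loss, normal, gain); loss mean must be
#'   negative and gain mean positive.
#' @param sd shared emission SD; `NULL` estimates it from the track's
#'   median absolute deviation (robust to the CNV probes themselves).
#' @param persistence self-transition probability of every state.
#' @return data.frame of class `cnv_segments`: sample, chrom, start, end
#'   (0-based half-open, end = last probe position + 1), state, n_probes,
#'   mean_log2, posterior.
#' @export
segment_hmm <- function(track, means = c(-0.6, 0, 0.45), sd = NULL,
                        persistence = 0.999) {
  stopifnot(length(means) == 3, means[1] < 0, means[3] > 0,
            persistence > 0, persistence < 1)
  sample_id <- attr(track, "source") %||% NA_character_
  out <- list()
  for (ch in unique(track$chrom)) {
    x <- track$log2ratio[track$chrom == ch]
    p <- track$position[track$chrom == ch]
    if (length(x) < 2L) {
      warning(sprintf("skipping %s: fewer than 2 probes", ch))
      next
    }
    s <- if (is.null(sd)) stats::mad(x) else sd
    if (s <= 0) s <- 1e-3
    dec <- hmm_decode(x, means, s, persistence)
    runs <- true_runs(dec$path != 2L)
    for (k in seq_len(nrow(runs))) {
      i0 <- runs$start_idx[k]; i1 <- runs$end_idx[k]
      # a run of non-normal Viterbi states can mix loss and gain probes;
      # emit one segment per maximal constant-state sub-run
      r2 <- rle(dec$path[i0:i1])
      off <- i0 - 1L
      at <- 0L
      for (j in seq_along(r2$lengths)) {
        from <- off + at + 1L
        to <- off + at + r2$lengths[j]
        at <- at + r2$lengths[j]
        stj <- r2$values[j]
        out[[length(out) + 1]] <- data.frame(
          sample = sample_id, chrom = ch, start = p[from], end = p[to] + 1,
          state = if (stj == 1L) "loss" else "gain",
          n_probes = to - from + 1L,
          mean_log2 = mean(x[from:to]),
          posterior = mean(dec$gamma[from:to, stj]),
          stringsAsFactors = FALSE)
      }
    }
  }
  segments_frame(out)
}

segments_frame <- function(rows) {
  if (!length(rows)) {
    df <- data.frame(sample = character(), chrom = character(),
                     start = numeric(), end = numeric(), state = character(),
                     n_probes = integer(), mean_log2 = numeric(),
                     posterior = numeric(), stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, rows)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("cnv_segments", "data.frame")
  df
}

# Scaled forward-backward + Viterbi for a 3-state Gaussian HMM.
# Returns list(gamma = T x 3 posterior matrix, path = integer states 1..3).
hmm_decode <- function(x, means, sd, persistence) {
  T_ <- length(x)
  K <- 3L
  off <- (1 - persistence) / (K - 1)
  logA <- log(matrix(off, K, K) + diag(persistence - off, K))
  init <- c((1 - persistence) / 2, persistence, (1 - persistence) / 2)
  em <- vapply(1:K, function(k) stats::dnorm(x, means[k], sd), numeric(T_))
  em <- pmax(em, 1e-300)
  A <- exp(logA)
  # forward (scaled)
  alpha <- matrix(0, T_, K)
  cvec <- numeric(T_)
  a <- init * em[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  for (t in 2:T_) {
    a <- (alpha[t - 1, ] %*% A) * em[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  # backward (scaled)
  beta <- matrix(0, T_, K)
  beta[T_, ] <- 1
  for (t in (T_ - 1):1) {
    b <- A %*% (em[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  # Viterbi in log space
  logem <- log(em)
  delta <- matrix(-Inf, T_, K)
  psi <- matrix(0L, T_, K)
  delta[1, ] <- log(init) + logem[1, ]
  for (t in 2:T_) {
    for (k in 1:K) {
      v <- delta[t - 1, ] + logA[, k]
      psi[t, k] <- which.max(v)
      delta[t, k] <- v[psi[t, k]] + logem[t, k]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta[T_, ])
  for (t in (T_ - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  list(gamma = gamma, path = path)
}

#' Robust run-length second caller
#'
#' Stage-1's independent second method: per chromosome, the probe median
#' and a robust SD (median absolute deviation) are computed, and every
#' maximal run of at least `min_probes` consecutive probes all beyond
#' median +/- `k` robust SDs on the same side becomes a segment. The long
#' minimum run makes chance calls on a null track essentially impossible
#' while single-copy changes pass probe-wise with high margin.
#'
#' @param track a [probe_track()].
#' @param k threshold in robust SD units.
#' @param min_probes minimum run length.
#' @return a `cnv_segments` data.frame (posterior is `NA`).
#' @export
second_caller <- function(track, k = 1, min_probes = 30) {
  sample_id <- attr(track, "source") %||% NA_character_
  out <- list()
  for (ch in unique(track$chrom)) {
    x <- track$log2ratio[track$chrom == ch]
    p <- track$position[track$chrom == ch]
    med <- stats::median(x)
    s <- stats::mad(x)
    if (s <= 0) s <- 1e-3
    for (side in c("gain", "loss")) {
      beyond <- if (side == "gain") x > med + k * s else x < med - k * s
      runs <- true_runs(beyond)
      runs <- runs[runs$end_idx - runs$start_idx + 1L >= min_probes, ,
                   drop = FALSE]
      for (j in seq_len(nrow(runs))) {
        i0 <- runs$start_idx[j]; i1 <- runs$end_idx[j]
        out[[length(out) + 1]] <- data.frame(
          sample = sample_id, chrom = ch, start = p[i0], end = p[i1] + 1,
          state = side, n_probes = i1 - i0 + 1L, mean_log2 = mean(x[i0:i1]),
          posterior = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  segments_frame(out)
}

#' Combine the two stage-1 callers conservatively
#'
#' Intersection semantics: a segment from caller `a` (the HMM) survives if
#' and only if at least half of its length is covered by same-state
#' segments from caller `b`. Surviving segments keep the HMM coordinates
#' and support values.
#'
#' @param a,b `cnv_segments` from the two callers, same sample.
#' @param min_coverage required covered fraction of the `a` segment.
#' @return the surviving subset of `a`.
#' @export
combine_callers <- function(a, b, min_coverage = 0.5) {
  if (!nrow(a)) return(a)
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    same <- b[b$chrom == a$chrom[i] & b$state == a$state[i], , drop = FALSE]
    if (!nrow(same)) next
    cov <- covered_fraction(as_interval_set(same), a$chrom[i], a$start[i],
                           a$end[i])
    keep[i] <- cov >= min_coverage
  }
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnv_segments", "data.frame")
  out
}

#' Posterior-support filter for HMM segments
#'
#' Keeps a segment when its average posterior exceeds 0.60 with at least 50
#' probes, or exceeds 0.75 with 30-49 probes; segments with fewer than 30
#' probes are discarded.
#'
#' @param segments a `cnv_segments` data.frame with posteriors populated.
#' @param p_large,n_large posterior threshold and probe count for large
#'   segments.
#' @param p_small,n_small posterior threshold and minimum probe count for
#'   small segments.
#' @return the filtered `cnv_segments`.
#' @export
filter_segments <- function(segments, p_large = 0.60, n_large = 50,
                            p_small = 0.75, n_small = 30) {
  keep <- (segments$n_probes >= n_large & segments$posterior > p_large) |
    (segments$n_probes >= n_small & segments$n_probes < n_large &
       segments$posterior > p_small)
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnv_segments", "data.frame")
  out
}

#' Join nearby same-state segments within a sample
#'
#' Two consecutive same-state segments are joined when they are less than
#' `max_gap` bp apart, or when more than `max_fraction` of the open
#' interval strictly between them is covered by repeats or assembly gaps.
#' The rule is closed transitively; merged segments span from the first
#' start to the last end, and probe count and mean log2 are recomputed
#' (from the track when provided, else by probe-count weighting).
#'
#' @param segments a `cnv_segments` data.frame (one sample).
#' @param repeats,gaps [interval_set()]s of repeats and assembly gaps.
#' @param max_gap join distance in bp.
#' @param max_fraction repeat/gap covered fraction above which a longer
#'   gap still joins.
#' @param track optional [probe_track()] to recompute probe statistics.
#' @return merged `cnv_segments`.
#' @export
merge_within_sample <- function(segments, repeats, gaps, max_gap = 3000,
                                max_fraction = 0.8, track = NULL) {
  if (!nrow(segments)) return(segments)
  blockers <- rbind(as.data.frame(repeats)[, c("chrom", "start", "end")],
                    as.data.frame(gaps)[, c("chrom", "start", "end")])
  blockers$label <- rep(NA_character_, nrow(blockers))
  blockers <- as_interval_set(blockers)
  out <- list()
  for (ch in unique(segments$chrom)) {
    for (st in c("loss", "gain")) {
      seg <- segments[segments$chrom == ch & segments$state == st, ,
                      drop = FALSE]
      if (!nrow(seg)) next
      seg <- seg[order(seg$start), , drop = FALSE]
      cur <- seg[1, , drop = FALSE]
      flush <- function(cur) {
        if (!is.null(track)) {
          sel <- track$chrom == ch & track$position >= cur$start &
            track$position < cur$end
          cur$n_probes <- sum(sel)
          cur$mean_log2 <- mean(track$log2ratio[sel])
        }
        cur
      }
      for (i in seq_len(nrow(seg))[-1]) {
        gap_start <- cur$end
        gap_end <- seg$start[i]
        join <- (gap_end - gap_start) < max_gap ||
          covered_fraction(blockers, ch, gap_start, gap_end) > max_fraction
        if (join) {
          w <- c(cur$n_probes, seg$n_probes[i])
          cur$mean_log2 <- sum(w * c(cur$mean_log2, seg$mean_log2[i])) / sum(w)
          cur$n_probes <- sum(w)
          cur$end <- max(cur$end, seg$end[i])
          cur$posterior <- max(cur$posterior, seg$posterior[i])
        } else {
          out[[length(out) + 1]] <- flush(cur)
          cur <- seg[i, , drop = FALSE]
        }
      }
      out[[length(out) + 1]] <- flush(cur)
    }
  }
  segments_frame(out)
}

#' Define cross-sample CNV regions
#'
#' Single-linkage union of overlapping (at least 1 bp) per-sample segments
#' across all samples, ignoring state: a gain in one sample may overlap a
#' loss in another, and regions are re-genotyped per sample afterwards.
#'
#' @param segments a `cnv_segments` data.frame pooled over samples (e.g.
#'   `do.call(rbind, per_sample_segments)`).
#' @return an [interval_set()] of regions, sorted, with ids `region_0001`,
#'   ... as labels and a `n_segments` column.
#' @export
define_regions <- function(segments) {
  if (!nrow(segments)) {
    out <- interval_set()
    out$n_segments <- integer()
    return(out)
  }
  rows <- list()
  for (ch in sort(unique(segments$chrom))) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(seg$start + 1, seg$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    cnt <- IRanges::countOverlaps(red, ir)
    rows[[ch]] <- data.frame(chrom = ch, start = IRanges::start(red) - 1,
                             end = IRanges::end(red), n_segments = cnt,
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  out <- interval_set(df$chrom, df$start, df$end,
                      sprintf("region_%04d", seq_len(nrow(df))))
  out$n_segments <- df$n_segments
  out
}

#' Full per-sample discovery stack
#'
#' Convenience wrapper running the two callers, the posterior filter, the
#' conservative combination and within-sample merging for one track.
#'
#' @param track a [probe_track()].
#' @param repeats,gaps annotation [interval_set()]s for the merging rule.
#' @param hmm_means,hmm_sd,hmm_persistence HMM parameters
#'   (see [segment_hmm()]).
#' @param caller2_k,caller2_min_probes second-caller parameters
#'   (see [second_caller()]).
#' @param min_coverage combination coverage (see [combine_callers()]).
#' @return merged, filtered `cnv_segments` for the sample.
#' @export
discover_sample <- function(track, repeats, gaps,
                            hmm_means = c(-0.6, 0, 0.45), hmm_sd = NULL,
                            hmm_persistence = 0.999,
                            caller2_k = 1, caller2_min_probes = 30,
                            min_coverage = 0.5) {
  a <- segment_hmm(track, means = hmm_means, sd = hmm_sd,
                   persistence = hmm_persistence)
  a <- filter_segments(a)
  b <- second_caller(track, k = caller2_k, min_probes = caller2_min_probes)
  ab <- combine_callers(a, b, min_coverage = min_coverage)
  merge_within_sample(ab, repeats, gaps, track = track)
}
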