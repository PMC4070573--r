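#' EM allele frequencies for a three-category CNV genotype
#'
#' Estimates the frequencies (p, q, r) of the normal, gain and loss alleles
#' of a CNV locus from the counts of samples called loss / equal / gain,
#' assuming Hardy-Weinberg proportions. Per-haplotype copies are L = 0,
#' N = 1, G = 2, so the diploid phenotype map is: copy < 2 (LL, LN) reads
#' as loss, copy = 2 (NN, LG) as equal, copy > 2 (NG, GG) as gain, giving
#' multinomial class probabilities
#' `P(loss) = r^2 + 2pr`, `P(equal) = p^2 + 2qr`, `P(gain) = q^2 + 2pq`.
#' Because the "equal" class can be explained either by NN homozygotes or
#' by GL heterozygotes, the likelihood can be bimodal; the EM iteration is
#' therefore run from several deterministic starting points (smoothed
#' category proportions plus three corner-biased starts; the uniform point
#' is an exact fixed point of the allele-counting EM map and is never
#' used) and the fit with the best log-likelihood is returned. Each run
#' stops when the log-likelihood improves by less than `tol`.
#'
#' @param n_loss,n_equal,n_gain sample counts per category.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return list of class `allele_freqs` with `p`, `q`, `r`, `loglik`,
#'   `iterations`, and the per-iteration log-likelihood trace.
#' @export
em_allele_freqs <- function(n_loss, n_equal, n_gain, tol = 1e-10,
                            max_iter = 1000) {
  n <- n_loss + n_equal + n_gain
  if (n < 1) stop("at least one genotyped sample is required", call. = FALSE)
  starts <- list(
    # smoothed category proportions (never the uniform point, which is an
    # exact fixed point of the EM map)
    c((n_equal + 0.5) / (n + 1.5), (n_gain + 0.5) / (n + 1.5),
      (n_loss + 0.5) / (n + 1.5)),
    c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8))
  best <- NULL
  for (s in starts) {
    fit <- em_one_start(n_loss, n_equal, n_gain, s[1], s[2], s[3], tol,
                        max_iter)
    if (is.null(best) || fit$loglik > best$loglik + 1e-12) best <- fit
  }
  structure(best, class = "allele_freqs")
}

em_one_start <- function(n_loss, n_equal, n_gain, p, q, r, tol, max_iter) {
  ll_of <- function(p, q, r) {
    probs <- c(loss = r^2 + 2 * p * r, equal = p^2 + 2 * q * r,
               gain = q^2 + 2 * p * q)
    cnt <- c(n_loss, n_equal, n_gain)
    sum(ifelse(cnt > 0, cnt * log(pmax(probs, 1e-300)), 0))
  }
  trace <- ll <- ll_of(p, q, r)
  for (it in seq_len(max_iter)) {
    # E-step: expected allele counts given the phenotype classes
    # loss = {LL: r^2, LN: 2pr}; equal = {NN: p^2, LG: 2qr};
    # gain = {GG: q^2, NG: 2pq}
    d_loss <- r^2 + 2 * p * r
    d_eq <- p^2 + 2 * q * r
    d_gain <- q^2 + 2 * p * q
    cL <- cN <- cG <- 0
    if (n_loss > 0 && d_loss > 0) {
      w_ll <- r^2 / d_loss; w_ln <- 2 * p * r / d_loss
      cL <- cL + n_loss * (2 * w_ll + w_ln)
      cN <- cN + n_loss * w_ln
    }
    if (n_equal > 0 && d_eq > 0) {
      w_nn <- p^2 / d_eq; w_lg <- 2 * q * r / d_eq
      cN <- cN + n_equal * 2 * w_nn
      cL <- cL + n_equal * w_lg
      cG <- cG + n_equal * w_lg
    }
    if (n_gain > 0 && d_gain > 0) {
      w_gg <- q^2 / d_gain; w_ng <- 2 * p * q / d_gain
      cG <- cG + n_gain * (2 * w_gg + w_ng)
      cN <- cN + n_gain * w_ng
    }
    tot <- cL + cN + cG
    p <- cN / tot; q <- cG / tot; r <- cL / tot
    ll_new <- ll_of(p, q, r)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  list(p = p, q = q, r = r, loglik = ll, iterations = it, trace = trace)
}

#' Expected heterozygosity of a CNV locus
#'
#' `He = 1 - (p^2 + q^2 + r^2)` over the three allele frequencies; maximal
#' (2/3) at the uniform point, 0 for a fixed locus.
#'
#' @param f an `allele_freqs` object, or a numeric vector of three
#'   frequencies summing to 1.
#' @return He in `[0, 2/3]`.
#' @export
expected_het <- function(f) {
  if (inherits(f, "allele_freqs")) f <- c(f$p, f$q, f$r)
  stopifnot(length(f) == 3, abs(sum(f) - 1) < 1e-6)
  1 - sum(f^2)
}

# Direct (sample-category) frequencies: proportions of loss/equal/gain
# calls, usable as a plug-in alternative to the EM allele frequencies.
category_freqs <- function(n_loss, n_equal, n_gain) {
  n <- n_loss + n_equal + n_gain
  c(c(n_equal, n_gain, n_loss) / n)
}

#' The VST copy-number differentiation statistic
#'
#' `VST = (VT - VS) / VT`, where `VT` is the (n-1 denominator) variance of
#' per-sample region mean log2 ratios over all included samples, and `VS`
#' the population-size-weighted mean of the within-group variances. By
#' convention `VST = 0` when `VT = 0`.
#'
#' @param values per-sample region mean log2 ratios.
#' @param groups parallel group labels; exactly two groups with at least
#'   two samples each.
#' @return list of class `vst_result` with `vt`, `vs`, `vst`.
#' @export
vst <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) != 2) stop("VST needs exactly two groups", call. = FALSE)
  if (any(tab < 2)) {
    stop(sprintf("group %s has fewer than 2 samples",
                 names(tab)[which.min(tab)]), call. = FALSE)
  }
  vt <- stats::var(values)
  vi <- tapply(values, groups, stats::var)
  ni <- as.numeric(tab[names(vi)])
  vs <- sum(ni * vi) / sum(ni)
  v <- if (vt == 0) 0 else (vt - vs) / vt
  structure(list(vt = vt, vs = vs, vst = v), class = "vst_result")
}

#' VST for every region of a genotype matrix
#'
#' Computes VST per region between dogs (dingo included) and gray wolves
#' from the per-sample region mean log2 ratios. Outgroup samples are
#' excluded. Monomorphic regions (all calls equal across the included
#' samples) can be dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param polymorphic_only keep only regions with at least one non-equal
#'   call among the included samples.
#' @return data.frame: region, chrom, start, end, vt, vs, vst.
#' @export
vst_regions <- function(gm, polymorphic_only = TRUE) {
  dogs <- group_cols(gm, "dog")
  wolves <- group_cols(gm, "wolf")
  cols <- c(dogs, wolves)
  grp <- c(rep("dog", length(dogs)), rep("wolf", length(wolves)))
  rows <- lapply(seq_len(nrow(gm$calls)), function(i) {
    if (polymorphic_only && all(gm$calls[i, cols] == "equal")) return(NULL)
    v <- vst(gm$region_log2[i, cols], grp)
    data.frame(region = rownames(gm$calls)[i], chrom = gm$regions$chrom[i],
               start = gm$regions$start[i], end = gm$regions$end[i],
               vt = v$vt, vs = v$vs, vst = v$vst, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region = character(), chrom = character(),
                      start = numeric(), end = numeric(), vt = numeric(),
                      vs = numeric(), vst = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Top-k most differentiated regions
#'
#' Descending by VST; ties broken by (chrom, start) so the ranking is
#' deterministic.
#'
#' @param results a data.frame as returned by [vst_regions()].
#' @param k number of regions to keep.
#' @return the top-`k` rows.
#' @export
rank_vst <- function(results, k = 25) {
  if (k > nrow(results)) {
    stop(sprintf("k = %d exceeds the %d available regions", k, nrow(results)),
         call. = FALSE)
  }
  ord <- order(-results$vst, results$chrom, results$start)
  out <- results[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Mean He over the given regions for a set of sample columns, using direct
# category frequencies of those samples.
mean_he_direct <- function(gm, cols, region_idx) {
  he <- vapply(region_idx, function(i) {
    calls <- gm$calls[i, cols]
    expected_het(category_freqs(sum(calls == "loss"), sum(calls == "equal"),
                                sum(calls == "gain")))
  }, 0)
  mean(he)
}

#' Wolf-subsampling comparison of CNV heterozygosity
#'
#' Dogs and gray wolves differ in sample size, so the dog mean expected
#' heterozygosity is compared against the distribution of the same
#' statistic over `n_draws` random wolf subsets of the dog group's size.
#' He is averaged over polymorphic regions (regions with at least one
#' non-equal call among dogs and gray wolves) using the direct category
#' frequencies of the respective sample subset. The empirical p-value is
#' `(#draws with mean He <= dog mean He + 1) / (n_draws + 1)`.
#'
#' @param gm a [genotype_matrix()].
#' @param group_size wolves per draw (default 5, the dog group size).
#' @param n_draws number of random wolf subsets.
#' @param seed RNG seed.
#' @return list of class `he_comparison`: `dog_he`, `null_mean`, `null_sd`,
#'   `p_value`, `draws` (the per-draw means).
#' @export
wolf_subsample_he_test <- function(gm, group_size = 5, n_draws = 1000,
                                   seed = 1) {
  dogs <- group_cols(gm, "dog")
  wolves <- group_cols(gm, "wolf")
  if (length(wolves) < group_size) {
    stop(sprintf("only %d wolves available for subsets of %d",
                 length(wolves), group_size), call. = FALSE)
  }
  cols <- c(dogs, wolves)
  poly <- which(apply(gm$calls[, cols, drop = FALSE] != "equal", 1, any))
  if (!length(poly)) stop("no polymorphic regions", call. = FALSE)
  dog_he <- mean_he_direct(gm, dogs, poly)
  draws <- with_seed(subseed(seed, "wolf-he"), {
    vapply(seq_len(n_draws), function(i) {
      sub <- sample(wolves, group_size)
      mean_he_direct(gm, sub, poly)
    }, 0)
  })
  p <- (sum(draws <= dog_he) + 1) / (n_draws + 1)
  structure(list(dog_he = dog_he, null_mean = mean(draws),
                 null_sd = stats::sd(draws), p_value = p, draws = draws),
            class = "he_comparison")
}

#' Group-wise mean expected heterozygosity from EM allele frequencies
#'
#' For each polymorphic region, EM allele frequencies are fitted per group
#' from that group's category counts and converted to He; the mean over
#' regions is reported per group.
#'
#' @param gm a [genotype_matrix()].
#' @return named numeric vector of mean He for the `dog` and `wolf` groups.
#' @export
group_mean_he <- function(gm) {
  dogs <- group_cols(gm, "dog")
  wolves <- group_cols(gm, "wolf")
  cols <- c(dogs, wolves)
  poly <- which(apply(gm$calls[, cols, drop = FALSE] != "equal", 1, any))
  one <- function(colset) {
    mean(vapply(poly, function(i) {
      calls <- gm$calls[i, colset]
      f <- em_allele_freqs(sum(calls == "loss"), sum(calls == "equal"),
                           sum(calls == "gain"))
      expected_het(f)
    }, 0))
  }
  c(dog = one(dogs), wolf = one(wolves))
}
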