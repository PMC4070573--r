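# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; nothing is read from disk except files the tests
# themselves write to tempdir().

# A small, fast simulation: 2 short chromosomes, 10 CNV loci, 6 controls,
# a 10-sample roster (4 dogs incl. the dingo-like one, 5 wolves, 1
# outgroup). Used where the full 23-sample default would be wasteful.
mini_samples <- function() {
  sample_sheet(sample = c("RefBoxer", "DogA", "DogB", "Dingo",
                          paste0("Wolf", 1:5), "Coyote"),
               group = c(rep("dog", 4), rep("wolf", 5), "outgroup"),
               reference = c(TRUE, rep(FALSE, 9)))
}

mini_config <- function(seed, ...) {
  args <- list(seed = seed,
               chrom_lengths = c(chr1 = 500000, chr2 = 400000),
               n_cnv_loci = 10, n_control_regions = 6, n_gaps = 1,
               n_genes = 20, n_gc_peaks = 8, array_pad = 4000,
               samples = mini_samples())
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# Random A/C/G/T string (plain base R, independent of the generator).
rand_seq <- function(n, gc = 0.5) {
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

# O(|a| * |b|) dynamic-programming longest-common-substring oracle.
# N never matches anything, matching the package semantics.
lcs_dp <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  if (na == 0 || nb == 0) return(0L)
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    for (j in seq_len(nb)) {
      if (av[i] != "N" && av[i] == bv[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# Brute-force grid-search MLE of the three-category HWE multinomial
# likelihood (step over q and r; p = 1 - q - r). The grid and the class
# probabilities are computed once and reused across count vectors.
em_grid_oracle_env <- new.env()
em_grid_oracle <- function(n_loss, n_equal, n_gain, step = 0.001) {
  key <- paste0("grid", step)
  if (is.null(em_grid_oracle_env[[key]])) {
    q <- seq(0, 1, by = step)
    grid <- expand.grid(q = q, r = q)
    grid <- grid[grid$q + grid$r <= 1 + 1e-12, ]
    p <- 1 - grid$q - grid$r
    em_grid_oracle_env[[key]] <- list(
      p = p, q = grid$q, r = grid$r,
      l_loss = log(pmax(grid$r^2 + 2 * p * grid$r, 1e-300)),
      l_eq = log(pmax(p^2 + 2 * grid$q * grid$r, 1e-300)),
      l_gain = log(pmax(grid$q^2 + 2 * p * grid$q, 1e-300)))
  }
  g <- em_grid_oracle_env[[key]]
  ll <- n_loss * g$l_loss + n_equal * g$l_eq + n_gain * g$l_gain
  i <- which.max(ll)
  c(p = g$p[i], q = g$q[i], r = g$r[i])
}

# Hand-built genotype matrix for genotyping/popgen unit tests.
# calls: regions x samples character matrix; groups: per-sample labels.
fake_gm <- function(calls, groups, region_log2 = NULL) {
  ns <- ncol(calls)
  if (is.null(colnames(calls))) colnames(calls) <- paste0("s", seq_len(ns))
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("region_%04d", seq_len(nrow(calls)))
  }
  samples <- sample_sheet(colnames(calls), groups,
                          reference = c(TRUE, rep(FALSE, ns - 1)))
  regions <- interval_set(rep("chr1", nrow(calls)),
                          seq_len(nrow(calls)) * 10000,
                          seq_len(nrow(calls)) * 10000 + 5000,
                          rownames(calls))
  if (is.null(region_log2)) {
    region_log2 <- matrix(0, nrow(calls), ns,
                          dimnames = dimnames(calls))
    region_log2[calls == "gain"] <- 0.6
    region_log2[calls == "loss"] <- -1
  }
  structure(list(calls = calls, regions = regions, samples = samples,
                 region_log2 = region_log2), class = "genotype_matrix")
}
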