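test_that("breakpoint windows are centered, clipped and size-filtered", {
  cnv <- interval_set("chr1", 10000, 20000, "c1")
  p <- make_breakpoint_pairs(cnv, window = 400)
  expect_equal(c(p$left_start, p$left_end), c(9800, 10200))
  expect_equal(c(p$right_start, p$right_end), c(19800, 20200))

  set.seed(11)
  g <- genome_sequence(c(chr1 = rand_seq(3000)))
  near_edge <- interval_set("chr1", 100, 1500, "c2")
  expect_warning(pe <- make_breakpoint_pairs(near_edge, window = 400,
                                             genome = g), "clipped")
  expect_equal(pe$left_start, 0)
  expect_equal(nchar(pe$left_seq), pe$left_end - pe$left_start)

  short <- interval_set("chr1", 1000, 1300, "c3")
  expect_warning(ps <- make_breakpoint_pairs(short, window = 400), "skipped")
  expect_equal(nrow(ps), 0L)
})

test_that("longest perfect homology matches its definition and DP oracle", {
  expect_equal(longest_perfect_homology("ACGT", "ACGT"), 4L)
  expect_equal(longest_perfect_homology("AAAA", "CCCC"), 0L)
  expect_equal(longest_perfect_homology("GATTACA", "TTAC"), 4L)
  expect_equal(longest_perfect_homology("", "ACGT"), 0L)
  # N never matches, not even N against N
  expect_equal(longest_perfect_homology("ANNA", "ANNA"), 1L)
  expect_equal(longest_perfect_homology("NNNN", "NNNN"), 0L)

  set.seed(12)
  for (i in 1:100) {
    a <- rand_seq(sample(1:60, 1))
    b <- if (i %% 3 == 0) {
      # embed a shared motif to exercise long matches
      m <- substr(a, 1, min(nchar(a), 15))
      paste0(rand_seq(sample(0:20, 1)), m, rand_seq(sample(0:20, 1)))
    } else rand_seq(sample(1:60, 1))
    l <- longest_perfect_homology(a, b)
    expect_identical(l, lcs_dp(a, b))
    expect_identical(l, longest_perfect_homology(b, a))
    expect_lte(l, min(nchar(a), nchar(b)))
  }
  # a substring always scores its own length
  s <- rand_seq(40)
  expect_equal(longest_perfect_homology(substr(s, 10, 25), s), 16L)
})

test_that("GC peak detection obeys the 1.5x background criterion", {
  set.seed(13)
  flat <- genome_sequence(c(chr1 = rand_seq(60000, gc = 0.40)))
  expect_equal(nrow(detect_gc_peaks(flat)), 0L)

  hot <- flat
  substr(hot$seq[["chr1"]], 30001, 30500) <- rand_seq(500, gc = 0.95)
  pk <- detect_gc_peaks(hot)
  expect_gte(nrow(pk), 1L)
  expect_true(any(pk$start < 30500 & pk$end > 30000))
  for (i in seq_len(nrow(pk))) {
    expect_gt(pk$peak_gc[i], 1.5 * pk$background_gc[i])
    expect_gte(pk$end[i] - pk$start[i], 500)
    # re-check directly against the sequence
    direct <- window_gc(hot, pk$chrom[i], pk$start[i], pk$end[i])
    expect_equal(direct, pk$peak_gc[i])
  }

  warm <- flat
  substr(warm$seq[["chr1"]], 30001, 30500) <- rand_seq(500, gc = 0.55)
  expect_equal(nrow(detect_gc_peaks(warm)), 0L)
})

test_that("GC profiles are flat on uniform genomes and track coverage", {
  set.seed(14)
  g <- genome_sequence(c(chr1 = rand_seq(100000, gc = 0.40)))
  st <- seq(10000, 80000, by = 10000)
  lens <- rep(c(3000, 1600), length.out = length(st))
  cnvs <- interval_set(rep("chr1", length(st)), st, st + lens)
  pairs <- make_breakpoint_pairs(cnvs, window = 400, genome = g)
  prof <- gc_profile_around_breakpoints(pairs, g, window = 400, flank = 2000)
  covered <- prof$n_windows > 0
  expect_true(all(abs(prof$mean_gc[covered] - 0.40) < 0.03))
  # a window 2 kb inside needs a CNV of >= 2.2 kb: only half qualify
  expect_equal(prof$coverage_proportion[prof$offset_bp == -2000], 0.5)
  expect_equal(prof$coverage_proportion[prof$offset_bp == 2000], 1)

  # an implanted hot window centered 800 bp outside every breakpoint
  hot <- g
  for (i in seq_len(nrow(pairs))) {
    substr(hot$seq[["chr1"]], st[i] - 1000 + 1, st[i] - 600) <-
      rand_seq(400, gc = 0.95)
    substr(hot$seq[["chr1"]], st[i] + lens[i] + 600 + 1,
           st[i] + lens[i] + 1000) <- rand_seq(400, gc = 0.95)
  }
  prof2 <- gc_profile_around_breakpoints(pairs, hot, window = 400,
                                         flank = 2000)
  expect_equal(prof2$offset_bp[which.max(prof2$mean_gc)], 800)
})

test_that("pair redistribution preserves intra-pair distance exactly", {
  set.seed(15)
  st <- seq(5000, 60000, by = 7000)
  cnvs <- interval_set(rep("chr1", length(st)), st,
                       st + sample(1000:4000, length(st)))
  pairs <- make_breakpoint_pairs(cnvs, window = 400)
  rp <- canidcnv:::redistribute_pairs(pairs, c(chr1 = 80000))
  expect_equal(rp$cnv_end - rp$cnv_start, pairs$cnv_end - pairs$cnv_start)
  expect_true(all(rp$left_start >= 0 & rp$right_end <= 80000))

  tiny <- interval_set("chr1", 100, 70000, "big")
  pt <- make_breakpoint_pairs(tiny, window = 400)
  expect_error(canidcnv:::redistribute_pairs(pt, c(chr1 = 70200)),
               "too short.*big")
})

test_that("homology permutation test flags implanted motifs only", {
  cfg <- mini_config(16, n_cnv_loci = 10)
  syn <- generate_genome(cfg)
  g1 <- implant_breakpoint_homology(syn$genome, syn$cnv_loci,
                                    motif_length = 30, seed = 16)
  pairs <- make_breakpoint_pairs(syn$cnv_loci, window = 400, genome = g1)
  ht <- homology_permutation_test(pairs, g1, n_perm = 50, seed = 1)
  expect_lt(ht$p_value, 0.01)
  expect_gt(ht$observed_mean, ht$null_mean)
  ht2 <- homology_permutation_test(pairs, g1, n_perm = 50, seed = 1)
  expect_identical(ht$null, ht2$null)

  pairs0 <- make_breakpoint_pairs(syn$cnv_loci, window = 400,
                                  genome = syn$genome)
  ht0 <- homology_permutation_test(pairs0, syn$genome, n_perm = 50, seed = 1)
  expect_gt(ht0$p_value, 0.01)
})

test_that("repeat enrichment detects construction and respects families", {
  set.seed(17)
  st <- seq(20000, 2800000, by = 40000)
  cnvs <- interval_set(rep("chr1", length(st)), st, st + 2000)
  pairs <- make_breakpoint_pairs(cnvs, window = 400)
  # L1 elements planted inside every left breakpoint window; SINEs uniform
  l1 <- interval_set(rep("chr1", length(st)), st - 100, st + 100, "L1/Canis")
  sine_pos <- sort(sample(0:2990000, 150))
  sine <- interval_set(rep("chr1", 150), sine_pos, sine_pos + 200, "SINE")
  reps <- rbind(l1, sine)
  class(reps) <- c("interval_set", "data.frame")
  enr <- repeat_enrichment(pairs, reps, families = c("L1", "SINE"),
                           chrom_lengths = c(chr1 = 3000000),
                           n_resamples = 200, seed = 2)
  l1row <- enr[enr$family == "L1", ]
  expect_gt(l1row$ratio, 2)
  expect_lte(l1row$p_value, 0.01)
  expect_gt(enr$p_value[enr$family == "SINE"], 0.05)
  expect_error(repeat_enrichment(pairs, reps, families = "Alu",
                                 chrom_lengths = c(chr1 = 3000000)),
               "unknown repeat family")
})

test_that("GC peak distance profile is enriched at implanted breakpoints", {
  cfg <- mini_config(18, gc_peak_bp_fraction = 1, n_gc_peaks = 16)
  syn <- generate_genome(cfg)
  pairs <- make_breakpoint_pairs(syn$cnv_loci, window = 400)
  prof <- gc_peak_breakpoint_profile(syn$gc_peaks, pairs,
                                     syn$config$chrom_lengths,
                                     n_resamples = 200, seed = 3)
  expect_gt(prof$ratio[1], 1)
  expect_lt(prof$p_value[1], 0.05)
  none <- interval_set()
  none$peak_gc <- none$background_gc <- numeric()
  prof0 <- gc_peak_breakpoint_profile(none, pairs, syn$config$chrom_lengths,
                                      n_resamples = 50, seed = 3)
  expect_true(all(prof0$observed == 0))
})

test_that("L1 age-class relabelling splits the L1 family", {
  syn <- generate_genome(mini_config(19))
  ages <- l1_age_labels(syn$repeats)
  expect_true(all(ages$label %in% c("CanisFamiliaris", "Canis", "Canidae",
                                    "Carnivora", "OlderMammalia")))
  expect_equal(nrow(ages),
               sum(canidcnv:::repeat_family(syn$repeats$label) == "L1"))
})
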