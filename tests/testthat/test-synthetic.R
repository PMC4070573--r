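test_that("generated genomes hit the configured GC composition", {
  cfg <- mini_config(1, chrom_lengths = c(chr1 = 1000000), base_gc = 0.40,
                     n_gc_peaks = 0, n_gaps = 0)
  syn <- generate_genome(cfg)
  seq <- syn$genome$seq[["chr1"]]
  gc <- sum(strsplit(seq, "")[[1]] %in% c("G", "C")) / nchar(seq)
  expect_lt(abs(gc - 0.40), 0.01)
})

test_that("implanted GC peaks are recoverable from the emitted sequence", {
  cfg <- mini_config(2, n_gc_peaks = 6, gc_peak_gc = 0.90,
                     gc_peak_width = 500)
  syn <- generate_genome(cfg)
  for (i in seq_len(nrow(syn$gc_peaks))) {
    gc <- window_gc(syn$genome, syn$gc_peaks$chrom[i], syn$gc_peaks$start[i],
                    syn$gc_peaks$end[i])
    expect_gte(gc, 0.85)
  }
})

test_that("generation is a pure function of the seed", {
  a <- generate_genome(mini_config(7))
  b <- generate_genome(mini_config(7))
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$cnv_loci, b$cnv_loci)
  expect_identical(a$repeats, b$repeats)
  c <- generate_genome(mini_config(8))
  expect_false(identical(a$genome$seq, c$genome$seq))
})

test_that("annotations and loci stay within chromosome bounds", {
  syn <- generate_genome(mini_config(3))
  for (set in list(syn$repeats, syn$gaps, syn$genes, syn$cnv_loci,
                   syn$controls)) {
    expect_true(all(set$start >= 0))
    expect_true(all(set$end <= syn$config$chrom_lengths[set$chrom]))
    expect_true(all(set$start < set$end))
  }
})

test_that("truth genotypes follow the allele arithmetic", {
  samples <- mini_samples()
  freqs_for <- function(fl, fn, fg) {
    do.call(rbind, lapply(sprintf("locus_%03d", 1:10), function(id) {
      data.frame(locus = id, group = c("dog", "wolf", "outgroup"),
                 f_loss = fl, f_norm = fn, f_gain = fg)
    }))
  }
  cfg <- mini_config(4, locus_freqs = freqs_for(0, 1, 0))
  truth <- draw_truth_genotypes(cfg, samples)
  expect_true(all(truth$copy == 2))
  expect_true(all(truth$expected_log2 == 0))

  cfg <- mini_config(4, locus_freqs = freqs_for(1, 0, 0))
  truth <- draw_truth_genotypes(cfg, samples)
  ref <- samples$sample[samples$reference]
  expect_true(all(truth$copy[truth$sample != ref] == 0))
  expect_true(all(truth$expected_log2[truth$sample != ref] == -3))
  expect_true(all(truth$copy[truth$sample == ref] == 2))

  cfg <- mini_config(4, locus_freqs = freqs_for(0, 0, 1))
  truth <- draw_truth_genotypes(cfg, samples)
  expect_true(all(truth$copy[truth$sample != ref] == 4))
  expect_true(all(truth$expected_log2[truth$sample != ref] == 1))
})

test_that("group-private gains separate dogs from wolves by construction", {
  lf <- do.call(rbind, lapply(sprintf("locus_%03d", 1:10), function(id) {
    data.frame(locus = id, group = c("dog", "wolf", "outgroup"),
               f_loss = 0, f_norm = c(0.1, 1, 1), f_gain = c(0.9, 0, 0))
  }))
  cfg <- mini_config(5, locus_freqs = lf)
  truth <- draw_truth_genotypes(cfg, mini_samples())
  wolves <- mini_samples()$sample[mini_samples()$group == "wolf"]
  dogs <- setdiff(mini_samples()$sample[mini_samples()$group == "dog"],
                  "RefBoxer")
  expect_true(all(truth$copy[truth$sample %in% wolves] == 2))
  expect_gt(mean(truth$copy[truth$sample %in% dogs] >= 3), 0.9)
})

test_that("copy-number arithmetic maps to expected log2 ratios exactly", {
  cfg <- mini_config(6)
  truth <- draw_truth_genotypes(cfg, mini_samples())
  for (cp in c(1, 2, 3, 4)) {
    rows <- truth$copy == cp
    if (any(rows)) expect_equal(unique(truth$expected_log2[rows]),
                                log2(cp / 2))
  }
  expect_true(all(truth$expected_log2[truth$copy == 0] == cfg$log2_floor))
})

test_that("simulated tracks have the configured noise around truth", {
  lf <- do.call(rbind, lapply(sprintf("locus_%03d", 1:10), function(id) {
    data.frame(locus = id, group = c("dog", "wolf", "outgroup"),
               f_loss = 0, f_norm = 1, f_gain = 0)
  }))
  cfg <- mini_config(9, locus_freqs = lf, noise_sd = 0.15)
  syn <- generate_genome(cfg)
  truth <- draw_truth_genotypes(cfg, mini_samples(), syn$cnv_loci)
  tracks <- simulate_acgh(truth, syn)
  x <- tracks[["Wolf1"]]$log2ratio
  expect_lt(abs(mean(x)), 0.01)
  expect_lt(abs(sd(x) - 0.15), 0.01)
  # identical probe layout across samples, 50 bp spacing in small regions
  expect_identical(tracks[["Wolf1"]]$position, tracks[["DogA"]]$position)
  for (ch in unique(tracks[["Wolf1"]]$chrom)) {
    d <- diff(tracks[["Wolf1"]]$position[tracks[["Wolf1"]]$chrom == ch])
    expect_equal(sort(unique(d[d <= 50])), 50)
  }
})

test_that("probe spacing follows the tiled-region length rules", {
  syn <- generate_genome(mini_config(10))
  syn$cnv_loci <- interval_set("chr1", 10000, 160000)  # 150 kb + pad
  syn$controls <- interval_set("chr2", 5000, 7000)
  pos <- canidcnv:::array_probe_positions(syn)
  big <- pos$position[pos$chrom == "chr1"]
  expect_equal(unique(diff(big)), 150)
  small <- pos$position[pos$chrom == "chr2"]
  expect_equal(unique(diff(small)), 50)
})

test_that("homology implants create the promised perfect homology", {
  cfg <- mini_config(11)
  syn <- generate_genome(cfg)
  g0 <- syn$genome
  g1 <- implant_breakpoint_homology(g0, syn$cnv_loci, motif_length = 25,
                                    which_loci = 1:5, seed = 11)
  pairs <- make_breakpoint_pairs(syn$cnv_loci, window = 400, genome = g1)
  hom <- vapply(seq_len(nrow(pairs)), function(i)
    longest_perfect_homology(pairs$left_seq[i], pairs$right_seq[i]), 0L)
  expect_true(all(hom[1:5] >= 25))
  expect_gt(mean(hom[1:5]), mean(hom[6:10]))

  expect_identical(implant_breakpoint_homology(g0, syn$cnv_loci, 0), g0)
  expect_error(implant_breakpoint_homology(g0, syn$cnv_loci,
                                           motif_length = 500),
               "smaller than the breakpoint window")
})
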