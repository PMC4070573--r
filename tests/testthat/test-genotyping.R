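test_that("region genotyping applies the median +/- 1.5 SD rule", {
  tr <- probe_track(rep("chr1", 100), seq(0, by = 50, length.out = 100),
                    rep(0, 100))
  cs <- structure(list(median = 0, sd = 0.2), class = "chip_stats")
  region <- interval_set("chr1", 0, 5000, "r1")
  geno_at <- function(mean_val, stats = cs) {
    tr$log2ratio <- rep(mean_val, 100)
    genotype_region(region[1, ], tr, stats)
  }
  expect_equal(geno_at(0.35), "gain")
  expect_equal(geno_at(-0.35), "loss")
  expect_equal(geno_at(0.10), "equal")
  # ties exactly at the threshold are non-equal calls (0.25 and 1.5 * 0.25
  # are exactly representable, so the comparison is a true tie)
  cs25 <- structure(list(median = 0, sd = 0.25), class = "chip_stats")
  expect_equal(geno_at(0.375, cs25), "gain")
  expect_equal(geno_at(-0.375, cs25), "loss")

  far <- interval_set("chr2", 0, 1000, "r2")
  expect_error(genotype_region(far[1, ], tr, cs), "no probes in region r2")
})

test_that("sharing classification partitions the regions", {
  calls <- matrix("equal", 4, 6,
                  dimnames = list(NULL, c("Ref", "DogA", "Dingo", "Wolf1",
                                          "Wolf2", "Coyote")))
  calls[1, c("DogA", "Dingo")] <- "gain"          # dog-specific
  calls[2, c("DogA", "Wolf1")] <- "loss"          # shared
  calls[3, "Wolf2"] <- "gain"                     # wild-specific
  gm <- fake_gm(calls, c("dog", "dog", "dog", "wolf", "wolf", "outgroup"))
  sh <- classify_sharing(gm)
  expect_equal(unname(sh$class),
               c("dog_specific", "shared", "wild_specific", "monomorphic"))
  expect_equal(sum(sh$counts), nrow(calls))
  expect_equal(sh$n_cnv_regions, 3)
  # a CNV seen only in the outgroup is wild-specific, not dog-specific
  calls2 <- calls
  calls2[4, "Coyote"] <- "loss"
  sh2 <- classify_sharing(fake_gm(calls2, c("dog", "dog", "dog", "wolf",
                                            "wolf", "outgroup")))
  expect_equal(unname(sh2$class[4]), "wild_specific")
})

test_that("polarization tests dogs against gray wolves only", {
  calls <- matrix("equal", 4, 6,
                  dimnames = list(NULL, c("Ref", "DogA", "Dingo", "Wolf1",
                                          "Wolf2", "Coyote")))
  calls[1, c("DogA", "Dingo", "Ref")] <- "gain"   # no wolf gain -> duplication
  calls[2, c("DogA", "Wolf1")] <- "loss"          # wolf shares -> not flagged
  calls[3, "DogA"] <- "gain"; calls[3, "Dingo"] <- "loss"  # both flags
  calls[4, "DogA"] <- "loss"; calls[4, "Coyote"] <- "loss" # outgroup ignored
  gm <- fake_gm(calls, c("dog", "dog", "dog", "wolf", "wolf", "outgroup"))
  pol <- polarize_events(gm)
  expect_equal(unname(pol$duplication), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(pol$deletion), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(pol$n_duplications, 2)
  expect_equal(pol$n_deletions, 2)
})

test_that("per-sample summaries satisfy the total and uniqueness identities", {
  calls <- matrix("equal", 6, 4,
                  dimnames = list(NULL, c("Ref", "DogA", "Wolf1", "Wolf2")))
  calls[1:2, "DogA"] <- "gain"
  calls[3:5, "DogA"] <- "loss"
  calls[6, c("Wolf1", "Wolf2")] <- "loss"
  gm <- fake_gm(calls, c("dog", "dog", "wolf", "wolf"))
  ps <- per_sample_summary(gm)
  expect_equal(ps$total, ps$gains + ps$losses)
  a <- ps[ps$sample == "DogA", ]
  expect_equal(c(a$total, a$gains, a$losses, a$unique_total), c(5, 2, 3, 5))
  # a call shared by two samples is unique in neither
  expect_equal(ps$unique_total[ps$sample %in% c("Wolf1", "Wolf2")], c(0, 0))

  empty <- fake_gm(matrix("equal", 3, 4,
                          dimnames = list(NULL, c("a", "b", "c", "d"))),
                   c("dog", "dog", "wolf", "wolf"))
  ps0 <- per_sample_summary(empty)
  expect_true(all(ps0$total == 0) && all(ps0$unique_total == 0))
})

test_that("full-matrix genotyping agrees with the simulated truth", {
  cfg <- mini_config(31, array_pad = 10000)
  syn <- generate_genome(cfg)
  truth <- draw_truth_genotypes(cfg, cfg$samples, syn$cnv_loci)
  tracks <- simulate_acgh(truth, syn)
  gm <- genotype_matrix(syn$cnv_loci, tracks, cfg$samples)
  truth_state <- ifelse(truth$copy < 2, "loss",
                        ifelse(truth$copy > 2, "gain", "equal"))
  called <- gm$calls[cbind(match(truth$locus, rownames(gm$calls)),
                           match(truth$sample, colnames(gm$calls)))]
  expect_gt(mean(called == truth_state), 0.9)
  # losses (single-copy signal at log2 -1 or below) are all recovered
  expect_true(all(called[truth$copy < 2] == "loss"))
})
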