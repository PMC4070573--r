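make_track <- function(values, chrom = "chr1", spacing = 50, sample = "s") {
  probe_track(rep(chrom, length(values)),
              seq(0, by = spacing, length.out = length(values)), values,
              source = sample)
}

test_that("HMM posteriors sum to one at every probe", {
  set.seed(1)
  x <- c(rnorm(200, 0, 0.15), rnorm(80, -0.8, 0.15), rnorm(200, 0, 0.15))
  dec <- canidcnv:::hmm_decode(x, c(-0.6, 0, 0.45), 0.15, 0.999)
  expect_true(all(abs(rowSums(dec$gamma) - 1) < 1e-9))
})

test_that("a pure-noise track yields no filtered segments", {
  set.seed(2)
  n_calls <- vapply(1:5, function(i) {
    tr <- make_track(rnorm(3000, 0, 0.15))
    nrow(filter_segments(segment_hmm(tr)))
  }, 0L)
  expect_true(all(n_calls == 0L))
})

test_that("an implanted loss is recovered nearly probe-exactly", {
  set.seed(3)
  x <- c(rnorm(500, 0, 0.15), rnorm(100, -0.8, 0.15), rnorm(500, 0, 0.15))
  segs <- segment_hmm(make_track(x))
  loss <- segs[segs$state == "loss", ]
  expect_equal(nrow(loss), 1L)
  expect_gte(loss$n_probes, 90)
  # the called run lies inside the implanted probe window
  expect_gte(loss$start, 500 * 50 - 5 * 50)
  expect_lte(loss$end, 600 * 50 + 5 * 50)
})

test_that("constant tracks produce no segments", {
  expect_equal(nrow(segment_hmm(make_track(rep(0, 500)))), 0L)
  expect_warning(segment_hmm(make_track(0.1)), "fewer than 2 probes")
})

test_that("the run-length caller requires long clean runs", {
  set.seed(4)
  x <- rnorm(500, 0, 0.15)
  x[101:140] <- 1.0
  segs <- second_caller(make_track(x), k = 2, min_probes = 30)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$state, "gain")

  x2 <- rnorm(500, 0, 0.15)
  x2[101:105] <- 1.0
  expect_equal(nrow(second_caller(make_track(x2), min_probes = 30)), 0L)

  null_calls <- vapply(1:5, function(i)
    nrow(second_caller(make_track(rnorm(3000, 0, 0.15)))), 0L)
  expect_true(all(null_calls == 0L))
})

test_that("caller combination uses conservative 50% same-state coverage", {
  seg <- function(start, end, state, sample = "s") {
    data.frame(sample = sample, chrom = "chr1", start = start, end = end,
               state = state, n_probes = 50, mean_log2 = 0.5,
               posterior = 0.9, stringsAsFactors = FALSE)
  }
  a <- structure(seg(1000, 2000, "gain"),
                 class = c("cnv_segments", "data.frame"))
  expect_equal(nrow(combine_callers(a, seg(1000, 2000, "gain"))), 1L)
  expect_equal(nrow(combine_callers(a, seg(5000, 6000, "gain"))), 0L)
  expect_equal(nrow(combine_callers(a, seg(1000, 2000, "loss"))), 0L)
  # 60% overlap survives, 40% does not
  expect_equal(nrow(combine_callers(a, seg(1400, 2000, "gain"))), 1L)
  expect_equal(nrow(combine_callers(a, seg(1601, 2000, "gain"))), 0L)
})

test_that("the posterior filter implements the probe-count rules", {
  seg <- function(n, post) {
    structure(data.frame(sample = "s", chrom = "chr1", start = 0, end = 1000,
                         state = "gain", n_probes = n, mean_log2 = 0.5,
                         posterior = post),
              class = c("cnv_segments", "data.frame"))
  }
  expect_equal(nrow(filter_segments(seg(50, 0.65))), 1L)
  expect_equal(nrow(filter_segments(seg(35, 0.70))), 0L)
  expect_equal(nrow(filter_segments(seg(35, 0.80))), 1L)
  expect_equal(nrow(filter_segments(seg(29, 0.99))), 0L)
  expect_equal(nrow(filter_segments(seg(50, 0.60))), 0L)  # strict >
})

test_that("within-sample merging joins by distance or repeat content", {
  seg2 <- function(s1, e1, s2, e2, state = "gain") {
    structure(data.frame(sample = "s", chrom = "chr1",
                         start = c(s1, s2), end = c(e1, e2), state = state,
                         n_probes = c(40, 60), mean_log2 = c(0.5, 0.8),
                         posterior = c(0.8, 0.9)),
              class = c("cnv_segments", "data.frame"))
  }
  none <- interval_set()
  # 2,999 bp apart -> merged
  m <- merge_within_sample(seg2(0, 1000, 3999, 5000), none, none)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0, 5000))
  expect_equal(m$n_probes, 100)
  expect_equal(m$mean_log2, (40 * 0.5 + 60 * 0.8) / 100)
  # 5 kb apart with 85% repeat coverage between -> merged
  reps <- interval_set("chr1", 1000, 1000 + 0.85 * 5000)
  expect_equal(nrow(merge_within_sample(seg2(0, 1000, 6000, 7000), reps,
                                        none)), 1L)
  # 5 kb apart, 10% coverage -> stays split
  reps2 <- interval_set("chr1", 1000, 1500)
  expect_equal(nrow(merge_within_sample(seg2(0, 1000, 6000, 7000), reps2,
                                        none)), 2L)
  # different states never merge
  s <- seg2(0, 1000, 1500, 2500)
  s$state <- c("gain", "loss")
  expect_equal(nrow(merge_within_sample(s, none, none)), 2L)
})

test_that("merging is idempotent", {
  set.seed(5)
  st <- sort(sample(seq(0, 200000, by = 100), 30))
  segs <- structure(data.frame(sample = "s", chrom = "chr1", start = st,
                               end = st + sample(500:2500, 30),
                               state = sample(c("gain", "loss"), 30, TRUE),
                               n_probes = 40, mean_log2 = 0.5,
                               posterior = 0.9),
                    class = c("cnv_segments", "data.frame"))
  none <- interval_set()
  m1 <- merge_within_sample(segs, none, none)
  m2 <- merge_within_sample(m1, none, none)
  expect_equal(m1[order(m1$start), c("start", "end", "state")],
               m2[order(m2$start), c("start", "end", "state")],
               ignore_attr = TRUE)
})

test_that("cross-sample regions are the single-linkage union of segments", {
  seg <- function(sample, start, end, state = "gain") {
    data.frame(sample = sample, chrom = "chr1", start = start, end = end,
               state = state, n_probes = 50, mean_log2 = 0.5,
               posterior = 0.9, stringsAsFactors = FALSE)
  }
  both <- structure(rbind(seg("a", 100, 200), seg("b", 100, 200)),
                    class = c("cnv_segments", "data.frame"))
  expect_equal(nrow(define_regions(both)), 1L)

  disjoint <- structure(rbind(seg("a", 100, 200), seg("b", 300, 400)),
                        class = c("cnv_segments", "data.frame"))
  expect_equal(nrow(define_regions(disjoint)), 2L)
  # adjacency (end == start) is not overlap
  touching <- structure(rbind(seg("a", 100, 200), seg("b", 200, 300)),
                        class = c("cnv_segments", "data.frame"))
  expect_equal(nrow(define_regions(touching)), 2L)
  # A-B, B-C chain with A,C disjoint spans all three; state is ignored
  chain <- structure(rbind(seg("a", 100, 250), seg("b", 200, 350, "loss"),
                           seg("c", 300, 450)),
                     class = c("cnv_segments", "data.frame"))
  r <- define_regions(chain)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(100, 450))
})
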