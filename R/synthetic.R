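#' Simulation configuration for synthetic aCGH studies
#'
#' Bundles every dial of the synthetic-data generator: genome composition
#' (base GC, implanted GC peaks, repeat and gap landscape), the CNV locus
#' panel with per-group allele frequencies, the array design (probe spacing
#' by tiled-region length, control regions) and the probe noise model.
#' Defaults emulate the wolf-like canid study design at desk scale: a
#' 23-sample roster (5 dogs including the dingo, 15 gray wolves, 3 outgroup
#' canids), 42 single-copy control regions, 50 bp probe spacing in regions
#' under 100 kb, and homoscedastic Gaussian probe noise.
#'
#' @param seed integer master seed; mandatory, every downstream draw is a
#'   pure function of (config, seed).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param base_gc background GC fraction of the simulated genome.
#' @param n_gc_peaks number of implanted high-GC peaks.
#' @param gc_peak_width width of implanted peaks (bp, >= 500).
#' @param gc_peak_gc GC fraction inside implanted peaks.
#' @param gc_peak_bp_fraction fraction of peaks centered on CNV locus
#'   boundaries (the rest are uniform), emulating the association of GC
#'   peaks with CNV breakpoints.
#' @param repeat_density named per-Mb element counts per repeat family.
#' @param repeat_mean_len named mean element lengths (bp) per family.
#' @param repeat_bp_fraction fraction of L1 and Simple_repeat elements
#'   placed adjacent to CNV breakpoints rather than uniformly.
#' @param l1_age_classes age-class labels cycled over L1 elements, from
#'   lineage-specific to ancient.
#' @param n_gaps,gap_len assembly gaps (runs of N) and their length.
#' @param n_genes,gene_len_range gene annotation count and length range.
#' @param n_cnv_loci number of CNV loci tiled on the array.
#' @param cnv_len_range CNV locus length range (bp).
#' @param locus_freqs optional data.frame(locus, group, f_loss, f_norm,
#'   f_gain); when `NULL` a default scenario mix is built (monomorphic,
#'   shared, dog-specific with a highly differentiated subset at variant
#'   frequency 0.9, wolf-specific).
#' @param n_control_regions,control_len single-copy control regions tiled
#'   on the chip for false-discovery-rate estimation.
#' @param array_pad flanking bp tiled around each CNV locus. The default
#'   (10 kb per side) keeps CNV-state probes a small minority of the chip,
#'   as on the real array, where tiled regions are far larger than the
#'   CNVs they contain; the chip-wide SD used by the genotyper then
#'   reflects probe noise rather than the CNVs themselves.
#' @param noise_sd Gaussian probe noise standard deviation (log2 units).
#' @param log2_floor expected log2 ratio for homozygous deletions (copy 0),
#'   clamping `log2(0/2)`.
#' @param samples a [sample_sheet()]; defaults to [canid_sample_sheet()].
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              chrom_lengths = c(chr1 = 1800000, chr2 = 1200000),
                              base_gc = 0.41,
                              n_gc_peaks = 30,
                              gc_peak_width = 600,
                              gc_peak_gc = 0.78,
                              gc_peak_bp_fraction = 0.5,
                              repeat_density = c(L1 = 40, SINE = 60,
                                                 Simple_repeat = 30),
                              repeat_mean_len = c(L1 = 900, SINE = 180,
                                                  Simple_repeat = 80),
                              repeat_bp_fraction = 0.25,
                              l1_age_classes = c("CanisFamiliaris", "Canis",
                                                 "Canidae", "Carnivora",
                                                 "OlderMammalia"),
                              n_gaps = 4,
                              gap_len = 5000,
                              n_genes = 80,
                              gene_len_range = c(2000, 20000),
                              n_cnv_loci = 60,
                              cnv_len_range = c(2500, 12000),
                              locus_freqs = NULL,
                              n_control_regions = 42,
                              control_len = 2000,
                              array_pad = 10000,
                              noise_sd = 0.15,
                              log2_floor = -3,
                              samples = canid_sample_sheet()) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (noise_sd <= 0) stop("probe noise SD must be > 0", call. = FALSE)
  if (gc_peak_width < 500) stop("GC peak width must be >= 500 bp", call. = FALSE)
  if (gc_peak_width >= min(chrom_lengths)) {
    stop("GC peak wider than a chromosome", call. = FALSE)
  }
  if (base_gc <= 0 || base_gc >= 1 || gc_peak_gc <= 0 || gc_peak_gc > 1) {
    stop("GC fractions must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (is.null(locus_freqs)) {
    locus_freqs <- default_locus_freqs(n_cnv_loci)
  }
  validate_locus_freqs(locus_freqs, n_cnv_loci)
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              base_gc = base_gc, n_gc_peaks = n_gc_peaks,
              gc_peak_width = gc_peak_width, gc_peak_gc = gc_peak_gc,
              gc_peak_bp_fraction = gc_peak_bp_fraction,
              repeat_density = repeat_density,
              repeat_mean_len = repeat_mean_len,
              repeat_bp_fraction = repeat_bp_fraction,
              l1_age_classes = l1_age_classes,
              n_gaps = n_gaps, gap_len = gap_len, n_genes = n_genes,
              gene_len_range = gene_len_range, n_cnv_loci = n_cnv_loci,
              cnv_len_range = cnv_len_range, locus_freqs = locus_freqs,
              n_control_regions = n_control_regions, control_len = control_len,
              array_pad = array_pad, noise_sd = noise_sd,
              log2_floor = log2_floor, samples = samples)
  class(cfg) <- "simulation_config"
  cfg
}

validate_locus_freqs <- function(lf, n_loci) {
  need <- c("locus", "group", "f_loss", "f_norm", "f_gain")
  if (!all(need %in% names(lf))) {
    stop("locus_freqs needs columns locus, group, f_loss, f_norm, f_gain",
         call. = FALSE)
  }
  tot <- lf$f_loss + lf$f_norm + lf$f_gain
  if (any(abs(tot - 1) > 1e-9)) {
    stop("allele frequencies must sum to 1 at every locus/group", call. = FALSE)
  }
  if (any(c(lf$f_loss, lf$f_norm, lf$f_gain) < 0)) {
    stop("negative allele frequency", call. = FALSE)
  }
  if (length(unique(lf$locus)) != n_loci) {
    stop(sprintf("locus_freqs covers %d loci but n_cnv_loci is %d",
                 length(unique(lf$locus)), n_loci), call. = FALSE)
  }
  invisible(lf)
}

#' Default CNV locus scenario mix
#'
#' Builds per-locus, per-group allele frequencies over the alleles
#' {loss, normal, gain}. The mix emulates the structure of the canid panel:
#' a sizeable fraction of array loci show no CNV at all in the sample set,
#' shared polymorphisms segregate in both dogs and wolves, and a smaller
#' set is private to one group; a subset of dog-specific loci is highly
#' differentiated (variant frequency 0.9 in dogs, absent in wolves), the
#' configuration under which the VST ranking should place them on top.
#' The outgroup mirrors the wolf frequencies.
#'
#' @param n_loci number of loci.
#' @param p_mono,p_shared,p_dog,p_wolf scenario proportions (monomorphic,
#'   shared, dog-specific, wolf-specific); must sum to 1. Defaults follow
#'   the canid panel's reported composition: slightly over half of the
#'   array loci show no CNV in the sample set, shared CNVs dominate the
#'   polymorphic remainder, and dog-specific CNVs are the smallest class.
#' @param f_poly variant allele frequency of ordinary polymorphic loci.
#' @param f_diff variant allele frequency of differentiated dog loci.
#' @return a data.frame(locus, group, f_loss, f_norm, f_gain, scenario).
#' @export
default_locus_freqs <- function(n_loci, p_mono = 0.55, p_shared = 0.2,
                                p_dog = 0.1, p_wolf = 0.15,
                                f_poly = 0.3, f_diff = 0.9) {
  stopifnot(abs(p_mono + p_shared + p_dog + p_wolf - 1) < 1e-9)
  n_mono <- round(n_loci * p_mono)
  n_shared <- round(n_loci * p_shared)
  n_dog <- round(n_loci * p_dog)
  n_wolf <- n_loci - n_mono - n_shared - n_dog
  scen <- c(rep("monomorphic", n_mono), rep("shared", n_shared),
            rep("dog_specific", n_dog), rep("wolf_specific", n_wolf))
  # half of dog-specific loci are highly differentiated gains
  rows <- list()
  n_diff <- ceiling(n_dog / 2)
  i_diff <- 0
  for (i in seq_len(n_loci)) {
    s <- scen[i]
    allele <- if (i %% 2 == 0) "gain" else "loss"
    f_dog <- f_wolf <- 0
    if (s == "shared") f_dog <- f_wolf <- f_poly
    if (s == "dog_specific") {
      i_diff <- i_diff + 1
      f_dog <- if (i_diff <= n_diff) f_diff else f_poly
      if (i_diff <= n_diff) allele <- "gain"
    }
    if (s == "wolf_specific") f_wolf <- f_poly
    for (g in c("dog", "wolf", "outgroup")) {
      f <- switch(g, dog = f_dog, wolf = f_wolf, outgroup = f_wolf)
      rows[[length(rows) + 1]] <- data.frame(
        locus = sprintf("locus_%03d", i), group = g,
        f_loss = if (allele == "loss") f else 0,
        f_norm = 1 - f,
        f_gain = if (allele == "gain") f else 0,
        scenario = s, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' The 23-canid sample roster
#'
#' Default sample sheet: 4 purebred dogs and a dingo (group `dog`), 15 gray
#' wolves (`wolf`), and red wolf, coyote and golden jackal (`outgroup`).
#' The Boxer is the hybridization reference, so its own track is self-self
#' noise around zero.
#'
#' @return a [sample_sheet()] with 23 rows.
#' @export
canid_sample_sheet <- function() {
  dogs <- c("Boxer", "Dachshund", "Beagle", "Basenji", "Dingo")
  wolves <- c("IsraelWolf", "IsraelWolf2", "ItalianWolf", "ItalianWolf2",
              "PortugueseWolf", "IberianWolf", "YellowstoneWolf",
              "GreatlakesWolf", "IranianWolf", "MexicanWolf", "ChineseWolf",
              "IndianWolf", "MongolianWolf", "MongolianWolf2", "SwedenWolf")
  outgroup <- c("RedWolf", "Coyote", "GoldenJackal")
  sample_sheet(sample = c(dogs, wolves, outgroup),
               group = c(rep("dog", 5), rep("wolf", 15), rep("outgroup", 3)),
               population = c(dogs, wolves, outgroup),
               reference = c(TRUE, rep(FALSE, 22)))
}

# Deterministic slot layout: distribute n intervals of the given lengths
# over the chromosomes, non-overlapping, with at least `margin` bp between
# neighbours and to the chromosome ends. Returns an interval_set.
place_in_slots <- function(chrom_lengths, lengths, margin) {
  n <- length(lengths)
  total <- sum(chrom_lengths)
  counts <- pmax(1L, round(n * chrom_lengths / total))
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n) counts[which.min(counts)] <- counts[which.min(counts)] + 1L
  chrom <- rep(names(chrom_lengths), counts)
  start <- numeric(n)
  idx <- 1L
  for (ci in seq_along(chrom_lengths)) {
    k <- counts[ci]
    if (k == 0L) next
    len <- chrom_lengths[ci]
    slot <- floor((len - 2 * margin) / k)
    lens_here <- lengths[idx:(idx + k - 1L)]
    if (any(slot < lens_here + margin)) {
      stop("chromosomes too short for the requested interval layout",
           call. = FALSE)
    }
    offs <- floor(stats::runif(k, 0, slot - lens_here - margin / 2))
    start[idx:(idx + k - 1L)] <- margin + (seq_len(k) - 1L) * slot + offs
    idx <- idx + k
  }
  interval_set(chrom, start, start + lengths)
}

random_dna <- function(n, gc) {
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

#' Generate a synthetic genome with annotations and CNV locus panel
#'
#' Draws i.i.d. bases at the configured background GC, implants high-GC
#' peaks (a configurable fraction centered on CNV locus boundaries), writes
#' assembly gaps as runs of N, and lays down repeat elements (L1 elements
#' carry cycling age-class labels, encoded as `"L1/<age>"`), genes, the CNV
#' locus panel and single-copy control regions. All placements are pure
#' functions of the configuration seed.
#'
#' @param config a [simulation_config()].
#' @return a list of class `synthetic_genome` with elements `genome`
#'   (`genome_sequence`), `repeats`, `gaps`, `genes`, `cnv_loci`,
#'   `controls`, `gc_peaks` (interval sets).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(subseed(config$seed, "genome"), {
    cl <- config$chrom_lengths
    # --- joint slot layout for loci, controls and gaps (mutually disjoint)
    loc_len <- round(stats::runif(config$n_cnv_loci, config$cnv_len_range[1],
                                  config$cnv_len_range[2]))
    all_len <- c(loc_len,
                 rep(config$control_len, config$n_control_regions),
                 rep(config$gap_len, config$n_gaps))
    kind <- c(rep("locus", config$n_cnv_loci),
              rep("control", config$n_control_regions),
              rep("gap", config$n_gaps))
    perm <- sample(length(all_len))
    placed <- place_in_slots(cl, all_len[perm], margin = 10000)
    placed$kind <- kind[perm]
    loci <- placed[placed$kind == "locus", , drop = FALSE]
    loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
    loci$label <- sprintf("locus_%03d", seq_len(nrow(loci)))
    controls <- placed[placed$kind == "control", , drop = FALSE]
    controls <- controls[order(controls$chrom, controls$start), , drop = FALSE]
    controls$label <- sprintf("control_%02d", seq_len(nrow(controls)))
    gaps <- placed[placed$kind == "gap", , drop = FALSE]
    gaps$label <- rep("gap", nrow(gaps))
    loci$kind <- controls$kind <- gaps$kind <- NULL

    # --- raw sequence
    seqs <- vapply(names(cl), function(ch) random_dna(cl[[ch]], config$base_gc),
                   "")
    # --- GC peaks: a fraction on locus boundaries, the rest uniform
    n_bp_peaks <- round(config$n_gc_peaks * config$gc_peak_bp_fraction)
    w <- config$gc_peak_width
    bnd <- data.frame(chrom = rep(loci$chrom, 2),
                      pos = c(loci$start, loci$end))
    bnd <- bnd[sample(nrow(bnd), min(n_bp_peaks, nrow(bnd))), , drop = FALSE]
    pk_chrom <- bnd$chrom
    pk_start <- pmax(0, round(bnd$pos - w / 2))
    n_unif <- config$n_gc_peaks - nrow(bnd)
    if (n_unif > 0) {
      uch <- sample(names(cl), n_unif, replace = TRUE, prob = cl / sum(cl))
      ust <- floor(stats::runif(n_unif, 0, cl[uch] - w))
      pk_chrom <- c(pk_chrom, uch)
      pk_start <- c(pk_start, ust)
    }
    gc_peaks <- interval_set(pk_chrom, pk_start, pk_start + w, "gc_peak")
    for (i in seq_len(nrow(gc_peaks))) {
      ch <- gc_peaks$chrom[i]
      substr(seqs[[ch]], gc_peaks$start[i] + 1, gc_peaks$end[i]) <-
        random_dna(w, config$gc_peak_gc)
    }
    # --- gaps as N runs
    for (i in seq_len(nrow(gaps))) {
      ch <- gaps$chrom[i]
      substr(seqs[[ch]], gaps$start[i] + 1, gaps$end[i]) <-
        strrep("N", gaps$end[i] - gaps$start[i])
    }
    genome <- genome_sequence(seqs)

    # --- repeats: per family, density per Mb; a fraction of L1 and simple
    # repeats sits next to CNV locus boundaries
    mb <- sum(cl) / 1e6
    rep_rows <- list()
    age_i <- 0L
    for (fam in names(config$repeat_density)) {
      k <- round(config$repeat_density[[fam]] * mb)
      lens <- pmax(20, round(stats::rexp(k, 1 / config$repeat_mean_len[[fam]])))
      near_bp <- fam %in% c("L1", "Simple_repeat") &
        stats::runif(k) < config$repeat_bp_fraction
      ch <- sample(names(cl), k, replace = TRUE, prob = cl / sum(cl))
      st <- floor(stats::runif(k, 0, cl[ch] - lens))
      n_near <- sum(near_bp)
      if (n_near > 0 && nrow(loci) > 0) {
        pick <- sample(nrow(loci), n_near, replace = TRUE)
        side <- sample(c(-1, 1), n_near, replace = TRUE)
        bp <- ifelse(side < 0, loci$start[pick], loci$end[pick])
        ch[near_bp] <- loci$chrom[pick]
        st[near_bp] <- pmax(0, pmin(cl[ch[near_bp]] - lens[near_bp],
                                    round(bp + side * 150 - lens[near_bp] / 2)))
      }
      lab <- rep(fam, k)
      if (fam == "L1") {
        lab <- paste0("L1/", config$l1_age_classes[
          (seq_len(k) + age_i) %% length(config$l1_age_classes) + 1L])
      }
      rep_rows[[fam]] <- interval_set(ch, st, st + lens, lab)
    }
    repeats <- do.call(rbind, rep_rows)
    repeats <- as_interval_set(repeats[order(repeats$chrom, repeats$start), ])

    # --- genes
    glen <- round(stats::runif(config$n_genes, config$gene_len_range[1],
                               config$gene_len_range[2]))
    gch <- sample(names(cl), config$n_genes, replace = TRUE, prob = cl / sum(cl))
    gst <- floor(stats::runif(config$n_genes, 0, cl[gch] - glen))
    genes <- interval_set(gch, gst, gst + glen,
                          sprintf("gene_%03d", seq_len(config$n_genes)))

    out <- list(genome = genome, repeats = repeats, gaps = as_interval_set(gaps),
                genes = genes, cnv_loci = as_interval_set(loci),
                controls = as_interval_set(controls), gc_peaks = gc_peaks,
                config = config)
    class(out) <- "synthetic_genome"
    out
  })
}

#' Draw diploid truth genotypes at every CNV locus
#'
#' Two alleles per sample per locus are drawn independently from the
#' sample's group frequencies over {loss, normal, gain} (Hardy-Weinberg
#' sampling). Per-haplotype copies are L=0, N=1, G=2, so diploid copy
#' number ranges over 0..4 and the expected log2 ratio is `log2(copy/2)`,
#' clamped at the configured floor for copy 0. The reference sample is
#' forced to normal/normal everywhere: its hybridization is self-self.
#'
#' @param config a [simulation_config()].
#' @param samples a [sample_sheet()]; defaults to `config$samples`.
#' @param loci CNV locus interval set (from [generate_genome()]); when
#'   `NULL`, loci are re-derived from the config seed.
#' @return a data.frame of class `truth_set` with one row per
#'   (locus, sample): alleles, diploid copy, expected log2 ratio.
#' @export
draw_truth_genotypes <- function(config, samples = config$samples,
                                 loci = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(loci)) loci <- generate_genome(config)$cnv_loci
  lf <- config$locus_freqs
  missing_groups <- setdiff(unique(samples$group), unique(lf$group))
  if (length(missing_groups)) {
    stop(sprintf("no allele frequencies for group(s): %s",
                 paste(missing_groups, collapse = ", ")), call. = FALSE)
  }
  with_seed(subseed(config$seed, "truth"), {
    rows <- vector("list", nrow(loci))
    copies <- c(loss = 0, normal = 1, gain = 2)
    for (i in seq_len(nrow(loci))) {
      id <- loci$label[i]
      frow <- lf[lf$locus == id, , drop = FALSE]
      a1 <- a2 <- character(nrow(samples))
      for (j in seq_len(nrow(samples))) {
        f <- frow[frow$group == samples$group[j], , drop = FALSE]
        pr <- c(f$f_loss[1], f$f_norm[1], f$f_gain[1])
        if (samples$reference[j]) {
          a1[j] <- a2[j] <- "normal"
        } else {
          draw <- sample(c("loss", "normal", "gain"), 2, replace = TRUE,
                         prob = pr)
          a1[j] <- draw[1]; a2[j] <- draw[2]
        }
      }
      copy <- copies[a1] + copies[a2]
      rows[[i]] <- data.frame(locus = id, chrom = loci$chrom[i],
                              start = loci$start[i], end = loci$end[i],
                              sample = samples$sample, allele1 = a1,
                              allele2 = a2, copy = as.numeric(copy),
                              expected_log2 = ifelse(copy == 0,
                                                     config$log2_floor,
                                                     log2(copy / 2)),
                              stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    class(truth) <- c("truth_set", "data.frame")
    truth
  })
}

# Probe positions implied by the array design: CNV loci padded by
# `array_pad` plus control regions, tiled at 50 bp when the region is
# < 100 kb, 150 bp for 100-300 kb, 1 kb beyond.
array_probe_positions <- function(syn) {
  config <- syn$config
  regions <- rbind(
    data.frame(chrom = syn$cnv_loci$chrom,
               start = pmax(0, syn$cnv_loci$start - config$array_pad),
               end = pmin(config$chrom_lengths[syn$cnv_loci$chrom],
                          syn$cnv_loci$end + config$array_pad)),
    data.frame(chrom = syn$controls$chrom, start = syn$controls$start,
               end = syn$controls$end))
  spacing <- function(len) if (len < 1e5) 50 else if (len <= 3e5) 150 else 1000
  pos <- lapply(seq_len(nrow(regions)), function(i) {
    s <- spacing(regions$end[i] - regions$start[i])
    data.frame(chrom = regions$chrom[i],
               position = seq(regions$start[i], regions$end[i] - 1, by = s))
  })
  pos <- do.call(rbind, pos)
  pos <- unique(pos[order(pos$chrom, pos$position), ])
  rownames(pos) <- NULL
  pos
}

#' Simulate per-sample aCGH probe tracks
#'
#' Probe positions follow the array-design spacing rules (common to all
#' samples). Each probe's value is the expected log2 ratio of the sample's
#' local copy number plus Gaussian noise; the reference sample's track is
#' pure noise around zero (self-self semantics, enforced by its
#' normal/normal truth genotypes).
#'
#' @param truth a `truth_set` from [draw_truth_genotypes()].
#' @param syn a `synthetic_genome` from [generate_genome()].
#' @param config a [simulation_config()]; defaults to `syn$config`.
#' @return named list of [probe_track()] objects, one per sample.
#' @export
simulate_acgh <- function(truth, syn, config = syn$config) {
  pos <- array_probe_positions(syn)
  samples <- unique(truth$sample)
  tracks <- vector("list", length(samples))
  names(tracks) <- samples
  loci <- unique(truth[, c("locus", "chrom", "start", "end")])
  probe_idx <- lapply(seq_len(nrow(loci)), function(i) {
    which(pos$chrom == loci$chrom[i] & pos$position >= loci$start[i] &
            pos$position < loci$end[i])
  })
  names(probe_idx) <- loci$locus
  for (s in samples) {
    mu <- numeric(nrow(pos))
    trows <- truth[truth$sample == s & truth$copy != 2, , drop = FALSE]
    for (i in seq_len(nrow(trows))) {
      mu[probe_idx[[trows$locus[i]]]] <- trows$expected_log2[i]
    }
    noise <- with_seed(subseed(config$seed, paste0("acgh:", s)),
                       stats::rnorm(nrow(pos), 0, config$noise_sd))
    tracks[[s]] <- probe_track(pos$chrom, pos$position, mu + noise, source = s)
  }
  tracks
}

#' Simulate a self-self hybridization track
#'
#' Same array layout, no true CNVs: every probe is noise around zero. Every
#' call made on such a track is a false positive, so the post-filter call
#' count estimates the discovery false discovery rate.
#'
#' @param syn a `synthetic_genome`.
#' @param config a [simulation_config()]; defaults to `syn$config`.
#' @param id label used to derive the noise sub-seed.
#' @return a [probe_track()].
#' @export
simulate_self_self <- function(syn, config = syn$config, id = "selfself") {
  pos <- array_probe_positions(syn)
  noise <- with_seed(subseed(config$seed, paste0("acgh:", id)),
                     stats::rnorm(nrow(pos), 0, config$noise_sd))
  probe_track(pos$chrom, pos$position, noise, source = id)
}

#' Implant perfect-homology motifs at CNV breakpoints
#'
#' For each chosen locus, one random motif is written into both 400 bp
#' breakpoint windows (centered on the locus start and end), creating a
#' stretch of perfect homology between the paired breakpoints, the
#' sequence signature expected under CNV formation by non-allelic
#' homologous recombination.
#'
#' @param genome a `genome_sequence`.
#' @param loci interval set of CNV loci.
#' @param motif_length motif length in bp; must be smaller than `window`;
#'   0 leaves the genome unchanged.
#' @param which_loci integer locus row indices to implant (default: all).
#' @param window breakpoint window size (bp).
#' @param seed integer seed for motif generation.
#' @return the modified `genome_sequence`.
#' @export
implant_breakpoint_homology <- function(genome, loci, motif_length,
                                        which_loci = seq_len(nrow(loci)),
                                        window = 400, seed = 1) {
  if (motif_length == 0) return(genome)
  if (motif_length >= window) {
    stop("motif length must be smaller than the breakpoint window",
         call. = FALSE)
  }
  half <- floor(motif_length / 2)
  targets <- data.frame(chrom = character(), start = numeric(),
                        end = numeric())
  with_seed(subseed(seed, "homology-implant"), {
    for (i in which_loci) {
      if (loci$end[i] - loci$start[i] < window + motif_length) {
        stop(sprintf("locus %d too short for homology implant", i),
             call. = FALSE)
      }
      motif <- random_dna(motif_length, 0.5)
      for (center in c(loci$start[i], loci$end[i])) {
        s <- center - half
        e <- s + motif_length
        if (s < 0 || e > genome$lengths[[loci$chrom[i]]]) {
          stop(sprintf("implant outside chromosome at locus %d", i),
               call. = FALSE)
        }
        clash <- targets$chrom == loci$chrom[i] & targets$start < e &
          targets$end > s
        if (any(clash)) stop("overlapping homology implants", call. = FALSE)
        targets <- rbind(targets, data.frame(chrom = loci$chrom[i],
                                             start = s, end = e))
        substr(genome$seq[[loci$chrom[i]]], s + 1, e) <- motif
      }
    }
  })
  genome
}
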