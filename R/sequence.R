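# Sequence arithmetic: GC fractions over windows, computed from cumulative
# base counts so that sliding-window scans are O(1) per window. N bases are
# excluded from GC denominators throughout.

# Cumulative GC and N counts for one chromosome string. Returns a list with
# `gc` and `n`, each of length nchar(seq) + 1 (zero-padded prefix sums).
base_cumsums <- function(seq) {
  raw <- charToRaw(seq)
  is_gc <- raw == as.raw(71L) | raw == as.raw(67L)   # G, C
  is_n <- raw == as.raw(78L)                         # N
  list(gc = c(0, cumsum(is_gc)), n = c(0, cumsum(is_n)))
}

# GC fraction of [start, end) windows (0-based half-open, vectorized) given
# precomputed cumsums. Windows that are all N return NA.
window_gc_from_cumsums <- function(cs, start, end) {
  gc <- cs$gc[end + 1] - cs$gc[start + 1]
  nn <- cs$n[end + 1] - cs$n[start + 1]
  denom <- (end - start) - nn
  ifelse(denom > 0, gc / denom, NA_real_)
}

# Fraction of N bases in [start, end) windows.
window_n_fraction <- function(cs, start, end) {
  (cs$n[end + 1] - cs$n[start + 1]) / (end - start)
}

#' GC fraction of genomic windows
#'
#' @param genome a `genome_sequence`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window coordinates (vectorized).
#' @return numeric GC fractions; `NA` for all-N windows.
#' @export
window_gc <- function(genome, chrom, start, end) {
  cs <- base_cumsums(genome$seq[[chrom]])
  window_gc_from_cumsums(cs, start, end)
}

# Extract [start, end) as a character string (0-based half-open).
subsequence <- function(genome, chrom, start, end) {
  substr(genome$seq[[chrom]], start + 1, end)
}
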