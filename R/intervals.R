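#' Interval sets
#'
#' A lightweight container for labelled genomic intervals (CNV regions,
#' control regions, repeats, assembly gaps, genes). Coordinates are 0-based
#' half-open throughout the package, matching BED. Overlap machinery is
#' delegated to IRanges; conversion to 1-based closed coordinates happens
#' only at that boundary.
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open coordinates, `start < end`.
#' @param label optional character labels (gene names, repeat families, ...).
#' @return a `data.frame` of class `interval_set` with columns
#'   `chrom`, `start`, `end`, `label`.
#' @examples
#' interval_set("chr1", 0, 100, "geneA")
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), label = NA_character_) {
  n <- length(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != n || length(end) != n) {
    stop("chrom, start and end must have equal length", call. = FALSE)
  }
  label <- rep_len(as.character(label), n)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval coordinates must be non-missing numbers", call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("empty or inverted interval at record %d: start %s >= end %s",
                 bad[1], format(start[bad[1]], scientific = FALSE),
                 format(end[bad[1]], scientific = FALSE)), call. = FALSE)
  }
  if (any(start < 0)) stop("negative interval start", call. = FALSE)
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("interval_set", "data.frame")
  out
}

# Coerce a plain data.frame with chrom/start/end (and optional label).
as_interval_set <- function(df) {
  interval_set(df$chrom, df$start, df$end,
               if ("label" %in% names(df)) df$label else NA_character_)
}

# 1-based closed IRanges for one chromosome's records of `set`.
iranges_on <- function(set, chrom) {
  rows <- set[set$chrom == chrom, , drop = FALSE]
  IRanges::IRanges(start = rows$start + 1, end = rows$end)
}

#' Fraction of an interval covered by a set of intervals
#'
#' Used by the within-sample merging rule: the open gap between two CNV
#' segments is joined when more than a given fraction of it is covered by
#' repeats or assembly gaps.
#'
#' @param set an [interval_set()].
#' @param chrom chromosome of the query interval.
#' @param start,end query interval, 0-based half-open.
#' @return covered fraction in `[0, 1]`.
#' @export
covered_fraction <- function(set, chrom, start, end) {
  if (end <= start) return(0)
  ir <- iranges_on(set, chrom)
  if (length(ir) == 0L) return(0)
  q <- IRanges::IRanges(start + 1, end)
  ov <- IRanges::intersect(IRanges::reduce(ir), q)
  sum(IRanges::width(ov)) / (end - start)
}

# Row indices of `query` intervals overlapping (>= 1 bp) any interval of
# `subject`, handled per chromosome.
overlapping_rows <- function(query, subject) {
  hits <- logical(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- subject$chrom == ch
    if (!any(si)) next
    qr <- IRanges::IRanges(query$start[qi] + 1, query$end[qi])
    sr <- IRanges::IRanges(subject$start[si] + 1, subject$end[si])
    hits[qi] <- IRanges::overlapsAny(qr, sr)
  }
  which(hits)
}

# For each query row, indices (into subject) of overlapping subject rows.
overlap_pairs <- function(query, subject) {
  out <- vector("list", nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    qr <- IRanges::IRanges(query$start[qi] + 1, query$end[qi])
    sr <- IRanges::IRanges(subject$start[si] + 1, subject$end[si])
    h <- IRanges::findOverlaps(qr, sr)
    for (k in seq_along(h)) {
      q <- qi[S4Vectors::queryHits(h)[k]]
      out[[q]] <- c(out[[q]], si[S4Vectors::subjectHits(h)[k]])
    }
  }
  out
}
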