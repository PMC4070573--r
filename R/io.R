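#' Read a per-sample probe track
#'
#' A probe track is the raw aCGH signal for one hybridization: one row per
#' probe with chromosome, position (bp, 0-based) and log2 test/reference
#' ratio. Positions must be sorted within each chromosome and unique.
#'
#' @param path path to a tab-separated file with header columns
#'   `chrom`, `position`, `log2ratio`.
#' @return a `data.frame` of class `probe_track`.
#' @export
read_probe_track <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "character"),
                          stringsAsFactors = FALSE)
  if (!identical(names(df), c("chrom", "position", "log2ratio"))) {
    stop(sprintf("%s: expected columns chrom, position, log2ratio", path),
         call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(df$position))
  val <- suppressWarnings(as.numeric(df$log2ratio))
  bad <- which(is.na(pos) | is.na(val))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric probe record at line %d", path, bad[1] + 1L),
         call. = FALSE)
  }
  track <- probe_track(df$chrom, pos, val, source = path)
  track
}

#' Construct a probe track
#'
#' @param chrom,position,log2ratio parallel vectors, one entry per probe.
#' @param source optional provenance string.
#' @return a `data.frame` of class `probe_track`, ordered as given.
#' @export
probe_track <- function(chrom, position, log2ratio, source = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), position = as.numeric(position),
                   log2ratio = as.numeric(log2ratio), stringsAsFactors = FALSE)
  for (ch in unique(df$chrom)) {
    p <- df$position[df$chrom == ch]
    if (is.unsorted(p, strictly = FALSE)) {
      idx <- which(df$chrom == ch)[which(diff(p) < 0)[1] + 1L]
      stop(sprintf("unsorted probe positions on %s at line %d", ch, idx + 1L),
           call. = FALSE)
    }
    if (anyDuplicated(p)) {
      idx <- which(df$chrom == ch)[which(duplicated(p))[1]]
      stop(sprintf("duplicate probe position on %s at line %d", ch, idx + 1L),
           call. = FALSE)
    }
  }
  attr(df, "source") <- source
  class(df) <- c("probe_track", "data.frame")
  df
}

#' Write a probe track as TSV
#'
#' @param track a [probe_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_probe_track <- function(track, path) {
  df <- data.frame(chrom = track$chrom,
                   position = format(track$position, scientific = FALSE,
                                     trim = TRUE),
                   log2ratio = sprintf("%.6f", track$log2ratio))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of labelled intervals
#'
#' BED is 0-based half-open; so are all coordinates in this package, so no
#' shifting happens. An optional 4th column is kept as the label.
#'
#' @param path path to a BED file (>= 3 whitespace-separated columns).
#' @return an [interval_set()].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(interval_set())
  parts <- strsplit(trimws(lines), "[ \t]+")
  ncol <- vapply(parts, length, 1L)
  if (any(ncol < 3L)) {
    stop(sprintf("%s: fewer than 3 columns at line %d", path,
                 which(ncol < 3L)[1]), call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric coordinates at line %d", path, bad[1]),
         call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("%s: empty interval (start >= end) at line %d", path, bad[1]),
         call. = FALSE)
  }
  label <- ifelse(ncol >= 4L, vapply(parts, function(p) p[min(4L, length(p))], ""),
                  NA_character_)
  interval_set(chrom, start, end, label)
}

#' Write an interval set as BED
#'
#' @param set an [interval_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(set, path) {
  cols <- data.frame(chrom = set$chrom,
                     start = format(set$start, scientific = FALSE, trim = TRUE),
                     end = format(set$end, scientific = FALSE, trim = TRUE))
  has_label <- !all(is.na(set$label))
  if (has_label) cols$label <- ifelse(is.na(set$label), ".", set$label)
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' Sequences are upper-cased; only A/C/G/T/N are accepted (assembly gaps are
#' runs of N).
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return a `genome_sequence`: list with `seq` (named character vector of
#'   chromosome strings) and `lengths` (named numeric vector, bp).
#' @export
read_fasta <- function(path) {
  # read as raw strings: DNAStringSet would silently drop invalid codes,
  # and these must be hard errors
  set <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(set) == 0L)) {
    stop(sprintf("%s: empty FASTA record", path), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_sequence(seqs)
}

#' Construct a genome sequence object
#'
#' @param seqs named character vector, one upper-case A/C/G/T/N string per
#'   chromosome.
#' @return a `genome_sequence` object.
#' @export
genome_sequence <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("chromosome names must be present and unique", call. = FALSE)
  }
  seqs <- toupper(seqs)
  for (ch in names(seqs)) {
    if (!nzchar(seqs[[ch]])) stop(sprintf("empty sequence for %s", ch),
                                  call. = FALSE)
    if (grepl("[^ACGTN]", seqs[[ch]])) {
      stop(sprintf("invalid character in sequence of %s (only A/C/G/T/N)", ch),
           call. = FALSE)
    }
  }
  out <- list(seq = seqs, lengths = stats::setNames(nchar(seqs), names(seqs)))
  class(out) <- "genome_sequence"
  out
}

#' Write a genome as FASTA
#'
#' @param genome a `genome_sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with header columns `sample`, `group`, `population`,
#'   `reference` (TRUE/FALSE); exactly one reference sample.
#' @return a `data.frame` of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sample_sheet(df$sample, df$group, df$population, df$reference)
}

#' Construct a sample sheet
#'
#' @param sample sample identifiers (unique).
#' @param group one of `"dog"`, `"wolf"`, `"outgroup"` per sample; the dingo
#'   belongs to the dog group, gray wolves to `"wolf"`, and red wolf, coyote
#'   and golden jackal to `"outgroup"`.
#' @param population free-form population label.
#' @param reference logical; exactly one sample is the hybridization
#'   reference.
#' @return a `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample, group, population = NA_character_,
                         reference = FALSE) {
  n <- length(sample)
  group <- as.character(group)
  if (anyDuplicated(sample)) stop("duplicate sample ids", call. = FALSE)
  if (!all(group %in% c("dog", "wolf", "outgroup"))) {
    stop("group labels must be dog, wolf or outgroup", call. = FALSE)
  }
  reference <- rep_len(as.logical(reference), n)
  if (sum(reference) != 1L) {
    stop("exactly one sample must be flagged as the reference", call. = FALSE)
  }
  out <- data.frame(sample = as.character(sample), group = group,
                    population = rep_len(as.character(population), n),
                    reference = reference, stringsAsFactors = FALSE)
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Write a sample sheet as TSV
#'
#' @param sheet a [sample_sheet()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
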