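# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stage name
#'
#' Every stochastic stage of the pipeline draws its own RNG stream from a
#' sub-seed that depends only on the master seed and the stage label, so a
#' stage's output does not depend on how many random numbers earlier stages
#' consumed.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
subseed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- as.double(master) %% 2147483647
  for (c in codes) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under `seed` and restore the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Percentage of num/den printed to one decimal, as in the summary tables.
fmt_percent1 <- function(num, den) {
  sprintf("%.1f", round(100 * num / den, 1))
}

# Floor-truncate a percentage to two decimals (used for the control-region
# false discovery rate, where 17/966 must print as 1.75, not 1.76).
truncate_percent2 <- function(num, den) {
  floor(100 * num / den * 100) / 100
}

# Maximal runs of TRUE in a logical vector -> data.frame(start_idx, end_idx)
# (end inclusive). Zero-row frame when none.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_idx = starts[keep], end_idx = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
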