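# Internal helpers: seed derivation, logging, validation.

#' @importFrom withr with_seed
NULL

ELIGIBLE_BIRADS <- c("3", "4A", "4B", "4C", "5")
EXCLUSION_STATUSES <- c("inconclusive", "unreported", "other_category")

# Derive independent sub-seeds from a master seed. All package randomness
# flows through seeds produced here so a single integer reproduces a run.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

bs_log <- function(...) {
  message(sprintf(...))
}

bs_stop <- function(..., class = "breathstrat_error") {
  stop(errorCondition(sprintf(...), class = c(class, "error", "condition")))
}

config_stop <- function(...) {
  bs_stop(..., class = "breathstrat_config_error")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 1
}

# Split `total` items over `n` bins as evenly as possible, bounded by
# [lo, hi] per bin. Used to distribute replicate counts over participants.
distribute_counts <- function(total, n, lo = 1L, hi = 5L) {
  base <- total %/% n
  rem <- total - base * n
  counts <- rep(base, n)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  if (any(counts < lo) || any(counts > hi)) {
    bs_stop("cannot place %d items into %d bins within [%d, %d] per bin",
            total, n, lo, hi)
  }
  as.integer(counts)
}
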