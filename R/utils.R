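## Small internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

## Evaluate `expr` under `seed` without disturbing the caller's RNG state;
## seed = NULL means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

## Deterministic per-stage substream derived from one root seed.
## Kept strictly below 2^31 (R integers are 32-bit).
stageSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offs <- c(simulate_parents = 11L, simulate_f1 = 23L, parent_counts = 37L,
            deep_counts = 41L, low_counts = 53L, bin_coverage = 67L,
            phenotypes = 79L, perm = 97L, pair_perm = 101L)
  k <- if (stage %in% names(offs)) offs[[stage]] else
    (sum(utf8ToInt(stage)) %% 1000L)
  ## arithmetic in doubles: seed * 1009 can exceed .Machine$integer.max
  as.integer((as.numeric(seed) * 1009 + k * 7919) %% 2147483587)
}

markerId <- function(chrom, start, end) {
  sprintf("%s_%d_%d", chrom, as.integer(start), as.integer(end))
}

stopifNot1 <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

## Check a marker data.frame is sorted by (chrom, start) and
## non-overlapping within chromosomes.  Returns TRUE or a message.
checkMarkerFrame <- function(mk, need = c("marker_id", "chrom", "start", "end")) {
  if (!all(need %in% names(mk)))
    return(sprintf("marker table must have columns %s",
                   paste(need, collapse = ", ")))
  if (nrow(mk) == 0) return(TRUE)
  if (any(mk$start > mk$end)) return("marker start > end")
  ord <- order(mk$chrom, mk$start)
  if (!identical(ord, seq_len(nrow(mk))))
    return("markers must be sorted by (chrom, start)")
  by_chr <- split(mk, mk$chrom)
  for (sub in by_chr) {
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)]))
      return("markers overlap within a chromosome")
  }
  TRUE
}

## Majority vote over counts for two alternatives; tie or all-zero -> NA.
majorityCall <- function(n1, n2, label1, label2) {
  out <- rep(NA_character_, length(n1))
  out[n1 > n2] <- label1
  out[n2 > n1] <- label2
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
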