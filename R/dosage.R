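## Dosage genotyping from binned read coverage.
##
## Copy number is read off relative coverage: each line's bin coverage
## is first scaled by that line's genome-wide mean (removing library
## size), then divided by the population mean of the same quantity at
## the bin (removing bin-specific mappability/content effects).  A
## euploid line sits at ratio ~1 everywhere; one missing paternal copy
## halves the ratio (0.5) and one extra copy raises it to 1.5.  The
## 0.75/1.25 cutoffs are the midpoints between those states.

#' Normalize bin coverage to relative copy ratios
#'
#' `r(l,b) = [cov(l,b) / mean_b' cov(l,b')] / popmean_{l' != l}` of the
#' same per-line-normalized value at bin b.  The population mean
#' excludes the focal line (leave-one-out), so a large indel cannot
#' bias its own baseline in small populations.  A line with zero total
#' coverage is flagged NA throughout and excluded from baselines.
#'
#' @param covObj a [BinCoverage-class] object.
#' @return numeric matrix (bins x lines) of copy ratios; attribute
#'   `flagged` lists zero-coverage lines.
#' @export
normalizeCoverage <- function(covObj) {
  cv <- covObj@cov
  stopifNot1(ncol(cv) >= 2, "need at least 2 lines to normalize")
  tot <- colMeans(cv)
  flagged <- colnames(cv)[tot == 0]
  v <- sweep(cv, 2, ifelse(tot == 0, NA_real_, tot), "/")
  nOk <- rowSums(!is.na(v))
  rs <- rowSums(v, na.rm = TRUE)
  loo <- (rs - ifelse(is.na(v), 0, v)) / (nOk - !is.na(v))
  r <- v / loo
  attr(r, "flagged") <- flagged
  r
}

#' Call per-bin paternal dosage genotypes from copy ratios
#'
#' Ratio below `lowCut` calls 0 (deletion), above `highCut` calls 2
#' (insertion), otherwise 1.  Dosage is capped at 2 (ratios beyond 1.75
#' still call 2).  Isolated non-regular calls are noise-suppressed: a
#' run of consecutive same-valued non-1 bins shorter than `minRun` is
#' reset to 1 (the smallest real indels span multiple bins).
#'
#' @param ratios copy-ratio matrix from [normalizeCoverage()].
#' @param bins bin annotation data.frame (marker_id, chrom, start, end).
#' @param lowCut,highCut ratio cutoffs (defaults 0.75 / 1.25, midpoints
#'   between copy ratios 0.5, 1.0, 1.5).
#' @param minRun minimum consecutive-bin run for a non-regular call.
#' @return a [DosageCalls-class] object.
#' @export
callDosage <- function(ratios, bins, lowCut = 0.75, highCut = 1.25,
                       minRun = 2) {
  stopifNot1(lowCut < highCut, "lowCut must be < highCut")
  raw <- matrix(1L, nrow(ratios), ncol(ratios), dimnames = dimnames(ratios))
  raw[ratios < lowCut] <- 0L
  raw[ratios > highCut] <- 2L
  raw[is.na(ratios)] <- NA_integer_

  chrIdx <- split(seq_len(nrow(bins)), bins$chrom)
  for (j in seq_len(ncol(raw))) {
    for (i in chrIdx) {
      v <- raw[i, j]
      sent <- ifelse(is.na(v), -1L, v)
      r <- rle(sent)
      drop <- r$values %in% c(0L, 2L) & r$lengths < minRun
      if (any(drop)) {
        r$values[drop] <- 1L
        v2 <- inverse.rle(r)
        v2[v2 == -1L] <- NA_integer_
        raw[i, j] <- v2
      }
    }
  }
  DosageCalls(bins[, c("marker_id", "chrom", "start", "end")], raw)
}

#' Score dosage calls against the simulation truth
#'
#' Truth is the paternal copy number at each bin midpoint.  Sensitivity
#' is the fraction of truly non-regular (copy 0 or 2) bins called with
#' their true dosage; the false-call rate is the fraction of truly
#' regular bins called non-regular.
#'
#' @param dosage a [DosageCalls-class] object.
#' @param pop an [F1Population-class] object.
#' @return list(sensitivity, falseRate, nIndelBins, nRegularBins).
#' @export
dosageCallMetrics <- function(dosage, pop) {
  mk <- dosage@markers
  lines <- lineIds(dosage)
  truth <- matrix(NA_integer_, nrow(mk), length(lines))
  for (ch in unique(mk$chrom)) {
    i <- which(mk$chrom == ch)
    mids <- (mk$start[i] + mk$end[i]) %/% 2L
    truth[i, ] <- t(truePnCopiesAt(pop, ch, mids)[lines, , drop = FALSE])
  }
  called <- dosage@calls
  ok <- !is.na(called)
  indel <- truth != 1L
  reg <- truth == 1L
  list(sensitivity = sum(ok & indel & called == truth) / sum(indel),
       falseRate = sum(ok & reg & called != 1L) / sum(reg),
       nIndelBins = sum(indel), nRegularBins = sum(reg))
}
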