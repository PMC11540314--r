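## Shared small-scale fixtures, built once per test run.
## 2 chromosomes x 500 kb keeps every stage in the sub-second range
## while leaving enough informative SNPs (~200 per parent) for
## multi-marker bins.

fxParents <- simulateParents(nChrom = 2, chromLen = 5e5, hetDensity = 4e-4,
                             seed = 101)
fxPop <- simulateF1(fxParents, nLines = 80, recombPerChrom = 1,
                    indelRate = 1.5, indelSizeRange = c(1e5, 2e5),
                    pDeletion = 0.665, seed = 102)
fxInfoPd <- selectInformativeSnps(exactParentGenotypes(fxParents, "Pd"),
                                  exactParentGenotypes(fxParents, "Pn"),
                                  focal = "Pd")
fxInfoPn <- selectInformativeSnps(exactParentGenotypes(fxParents, "Pd"),
                                  exactParentGenotypes(fxParents, "Pn"),
                                  focal = "Pn")
fxTruthCm <- truthCommonMarkers(fxParents, fxPop, binSize = 30)

## A deterministic BinnedGenotypes builder for hand-made cases.
makeBinned <- function(focal = "Pn", markers, callRows) {
  lab <- if (focal == "Pn") c("N1", "N2") else c("D1", "D2")
  calls <- do.call(rbind, callRows)
  colnames(calls) <- paste0("L", sprintf("%03d", seq_len(ncol(calls))))
  BinnedGenotypes(focal, markers, calls)
}

mkFrame <- function(chrom, start, end, snp_count = NA_integer_) {
  data.frame(marker_id = markerId(chrom, start, end), chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             snp_count = snp_count, stringsAsFactors = FALSE)
}

## Random CommonMarkers instance honouring the dose-0 invariant.
randomCommonMarkers <- function(nMarkers = 6, nLines = 5) {
  chrom <- rep("Chr01", nMarkers)
  start <- seq(1, by = 1e4, length.out = nMarkers)
  mk <- mkFrame(chrom, start, start + 5e3)
  lines <- sprintf("L%03d", seq_len(nLines))
  pd <- matrix(sample(c("D1", "D2", NA), nMarkers * nLines, TRUE),
               nMarkers, nLines, dimnames = list(mk$marker_id, lines))
  dose <- matrix(sample(c(0:2, NA), nMarkers * nLines, TRUE,
                        prob = c(.1, .6, .1, .2)),
                 nMarkers, nLines, dimnames = list(mk$marker_id, lines))
  pn <- matrix(sample(c("N1", "N2", NA), nMarkers * nLines, TRUE),
               nMarkers, nLines, dimnames = list(mk$marker_id, lines))
  pn[!is.na(dose) & dose == 0] <- NA
  CommonMarkers(mk, pd, pn, dose)
}

## Brute-force Benjamini-Hochberg step-up, straight from the
## definition: p_adj(i) = min_{j >= i} p(j) * m / j on the sorted
## vector, clipped at 1, in input order.  Independent oracle for
## bhAdjust().
bhBruteForce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
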