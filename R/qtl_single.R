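## Single-channel QTL scans.
##
## The model is the single-marker regression Y_i = b0 + b1 * gt_i + e_i
## fitted marker by marker within one channel (Pd haplotype, Pn
## haplotype, or paternal dosage).  Genome-wide significance comes from
## a permutation null: the trait values are shuffled among lines, the
## whole scan refitted and the maximum |t| recorded; the 95th and 99th
## percentiles of the permuted maxima are the 5% ("significant") and 1%
## ("confirmed") thresholds.  Because trait orientations are arbitrary
## (deletions typically lower biomass traits), the two-sided max |t| is
## used.  Runs of adjacent significant markers merge into one QTL.

#' Numeric genotype encoding of one channel
#'
#' Pd: D1 -> 0, D2 -> 1.  Pn: N1 -> 0, N2 -> 1 (NA inside deletions).
#' dosage: the paternal copy number 0/1/2.
#'
#' @param cm a [CommonMarkers-class] object.
#' @param channel `"Pd"`, `"Pn"` or `"dosage"`.
#' @return numeric matrix lines x markers (NA = missing).
#' @export
encodeChannel <- function(cm, channel = c("Pd", "Pn", "dosage")) {
  channel <- match.arg(channel)
  g <- switch(channel,
    Pd = (cm@pd == "D2") + 0,
    Pn = (cm@pn == "N2") + 0,
    dosage = cm@dose + 0)
  t(g)
}

## Closed-form OLS sums for y (complete) against each column of G
## (NAs allowed).  Returns per-marker n, beta, and t.
scanCore <- function(y, G) {
  W <- !is.na(G)
  Gz <- G; Gz[!W] <- 0
  n <- colSums(W)
  Sx <- colSums(Gz); Sxx <- colSums(Gz^2)
  Sy <- as.vector(crossprod(W, y))
  Syy <- as.vector(crossprod(W, y^2))
  Sxy <- as.vector(crossprod(Gz, y))
  SxxC <- Sxx - Sx^2 / n
  SxyC <- Sxy - Sx * Sy / n
  SyyC <- Syy - Sy^2 / n
  beta <- SxyC / SxxC
  sse <- pmax(SyyC - beta * SxyC, 0)
  tval <- beta / sqrt((sse / (n - 2)) / SxxC)
  list(n = n, beta = beta, beta0 = (Sy - beta * Sx) / n, t = tval,
       residSd = sqrt(sse / (n - 2)), SxxC = SxxC)
}

## Marker validity: enough complete pairs, polymorphic, and the minor
## genotype class populated.
markerValidity <- function(G, minN, minMinor) {
  reason <- rep(NA_character_, ncol(G))
  for (j in seq_len(ncol(G))) {
    v <- G[, j][!is.na(G[, j])]
    if (length(v) < minN) { reason[j] <- "insufficient data"; next }
    tab <- table(v)
    if (length(tab) < 2) { reason[j] <- "monomorphic"; next }
    if (length(v) - max(tab) < minMinor) reason[j] <- "minor genotype below floor"
  }
  reason
}

#' Fit the single-marker model at one marker
#'
#' Ordinary least squares of the trait on one numeric genotype with an
#' intercept; two-sided p from the Student t distribution with
#' `n_used - 2` degrees of freedom.
#'
#' @param y numeric trait values.
#' @param g numeric genotypes (same length).
#' @param minN minimum complete pairs (default 20).
#' @return list with beta0, beta1, t_value, p_value, n_used,
#'   residual_sd, and `reason` (NA when fitted; `"monomorphic"` or
#'   `"insufficient data"` when skipped).
#' @export
fitSingleMarker <- function(y, g, minN = 20) {
  cc <- !is.na(y) & !is.na(g)
  y <- y[cc]; g <- g[cc]
  out <- list(beta0 = NA_real_, beta1 = NA_real_, t_value = NA_real_,
              p_value = NA_real_, n_used = length(y),
              residual_sd = NA_real_, reason = NA_character_)
  if (length(y) < minN) { out$reason <- "insufficient data"; return(out) }
  if (length(unique(g)) < 2) { out$reason <- "monomorphic"; return(out) }
  f <- scanCore(y, matrix(g, ncol = 1))
  out$beta0 <- f$beta0; out$beta1 <- f$beta
  out$t_value <- f$t; out$residual_sd <- f$residSd
  out$p_value <- 2 * pt(-abs(f$t), length(y) - 2)
  out
}

#' Per-marker scan statistics for one trait and channel
#'
#' @param y numeric trait values aligned to the rows of `G` (NAs
#'   dropped internally together with the matching genotype rows).
#' @param G lines x markers numeric genotype matrix.
#' @param minN minimum complete pairs per marker.
#' @param minMinor minimum minor-genotype count per marker.
#' @return data.frame (marker, n, beta, t, p, reason); skipped markers
#'   carry NA statistics and a reason.
#' @export
scanMarkers <- function(y, G, minN = 20, minMinor = 5) {
  keep <- !is.na(y)
  y <- y[keep]; G <- G[keep, , drop = FALSE]
  reason <- markerValidity(G, minN, minMinor)
  f <- scanCore(y, G)
  valid <- is.na(reason)
  out <- data.frame(marker = colnames(G) %||% as.character(seq_len(ncol(G))),
                    n = f$n, beta = ifelse(valid, f$beta, NA),
                    t = ifelse(valid, f$t, NA), stringsAsFactors = FALSE)
  out$p <- 2 * pt(-abs(out$t), out$n - 2)
  out$reason <- reason
  rownames(out) <- NULL
  out
}

#' Genome-wide permutation thresholds for a scan
#'
#' The trait is shuffled among the observed lines, every valid marker
#' refitted, and the maximum |t| of each permuted scan collected; the
#' returned thresholds are the 95th and 99th percentiles of those
#' maxima.  Marker validity (which depends only on the genotype
#' pattern, not the trait values) is fixed across permutations.
#'
#' @inheritParams scanMarkers
#' @param nPerm number of permutations (default 1000).
#' @param seed optional integer seed (same seed, same thresholds).
#' @return list(t95, t99, maxima).
#' @export
permutationThreshold <- function(y, G, nPerm = 1000, seed = NULL,
                                 minN = 20, minMinor = 5) {
  stopifNot1(nPerm >= 1, "nPerm must be >= 1")
  keep <- !is.na(y)
  y <- y[keep]; G <- G[keep, , drop = FALSE]
  valid <- is.na(markerValidity(G, minN, minMinor))
  if (!any(valid)) {
    warning("no valid markers; permutation maxima set to 0", call. = FALSE)
    maxima <- rep(0, nPerm)
  } else {
    Gv <- G[, valid, drop = FALSE]
    W <- !is.na(Gv); Gz <- Gv; Gz[!W] <- 0
    n <- colSums(W); Sx <- colSums(Gz); Sxx <- colSums(Gz^2)
    SxxC <- Sxx - Sx^2 / n
    maxima <- withSeed(seed, {
      Yp <- vapply(seq_len(nPerm), function(b) sample(y), y)
      SyM <- crossprod(W, Yp)
      SyyM <- crossprod(W, Yp^2)
      SxyM <- crossprod(Gz, Yp)
      SxyC <- SxyM - (Sx / n) * SyM
      SyyC <- SyyM - SyM^2 / n
      beta <- SxyC / SxxC
      sse <- pmax(SyyC - beta * SxyC, 0)
      tM <- abs(beta) / sqrt((sse / (n - 2)) / SxxC)
      apply(tM, 2, max, na.rm = TRUE)
    })
    maxima[!is.finite(maxima)] <- 0
  }
  qs <- quantile(maxima, c(0.95, 0.99), names = FALSE)
  list(t95 = qs[1], t99 = qs[2], maxima = maxima)
}

#' Merge significant markers into QTLs
#'
#' Maximal runs of consecutive same-chromosome markers with |t| above
#' the 5% threshold become one QTL; a QTL is "confirmed" when its peak
#' |t| also clears the 1% threshold, otherwise "significant".
#'
#' @param stats per-marker statistics from [scanMarkers()], aligned to
#'   `markers`.
#' @param markers marker annotation data.frame.
#' @param t95,t99 permutation thresholds.
#' @return data.frame, one row per QTL, with a `members` list column of
#'   member marker ids.
#' @export
callQtls <- function(stats, markers, t95, t99) {
  sig <- !is.na(stats$t) & abs(stats$t) > t95
  idx <- which(sig)
  if (!length(idx)) {
    out <- data.frame(chrom = character(), start_marker = character(),
                      end_marker = character(), peak_marker = character(),
                      peak_stat = numeric(), significance = character(),
                      stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  newRun <- c(TRUE, diff(idx) > 1 |
                markers$chrom[idx[-1]] != markers$chrom[idx[-length(idx)]])
  runs <- unname(split(idx, cumsum(newRun)))
  peak <- vapply(runs, function(i) i[which.max(abs(stats$t[i]))], 0L)
  out <- data.frame(
    chrom = markers$chrom[peak],
    start_marker = markers$marker_id[vapply(runs, head, 0L, n = 1L)],
    end_marker = markers$marker_id[vapply(runs, tail, 0L, n = 1L)],
    peak_marker = markers$marker_id[peak],
    peak_stat = stats$t[peak],
    significance = ifelse(abs(stats$t[peak]) > t99, "confirmed", "significant"),
    stringsAsFactors = FALSE)
  out$members <- lapply(runs, function(i) markers$marker_id[i])
  rownames(out) <- NULL
  out
}

#' Variance explained by a set of markers (adjusted R-squared)
#'
#' Multiple OLS of the trait on all named markers jointly;
#' collinear/aliased columns are dropped by the fit.
#'
#' @param y numeric trait values.
#' @param G lines x markers numeric genotype matrix.
#' @param members marker (column) names to include.
#' @return adjusted R-squared fraction (can be slightly negative under
#'   independence).
#' @export
varianceExplained <- function(y, G, members) {
  stopifNot1(length(members) >= 1, "need at least one marker")
  X <- G[, members, drop = FALSE]
  cc <- complete.cases(X) & !is.na(y)
  stopifNot1(sum(cc) >= length(members) + 2,
             "too few complete cases for %d predictor(s)", length(members))
  fit <- lm(y[cc] ~ X[cc, , drop = FALSE])
  summary(fit)$adj.r.squared
}

#' Single-channel QTL scan for one trait
#'
#' Runs [scanMarkers()], computes permutation thresholds, merges
#' significant markers into QTLs and attaches the variance explained by
#' each QTL's member markers (multivariate adjusted R-squared).
#'
#' @param cm a [CommonMarkers-class] object.
#' @param pheno phenotype data.frame (`line_id` + trait columns).
#' @param trait trait name.
#' @param channel `"Pd"`, `"Pn"` or `"dosage"`.
#' @param nPerm permutations for the thresholds.
#' @param seed optional integer seed.
#' @param minN,minMinor marker validity floors.
#' @return a [QtlScan-class] object; its `qtls` slot is ready for
#'   [writeQtlResults()].
#' @export
qtlScan <- function(cm, pheno, trait, channel, nPerm = 1000, seed = NULL,
                    minN = 20, minMinor = 5) {
  lines <- lineIds(cm)
  stopifNot1(trait %in% names(pheno), "trait '%s' not in phenotypes", trait)
  y <- pheno[[trait]][match(lines, pheno$line_id)]
  G <- encodeChannel(cm, channel)
  stats <- scanMarkers(y, G, minN, minMinor)
  thr <- permutationThreshold(y, G, nPerm, seed, minN, minMinor)
  qtls <- callQtls(stats, cm@markers, thr$t95, thr$t99)
  ve <- vapply(seq_len(nrow(qtls)), function(r)
    varianceExplained(y, G, qtls$members[[r]]), 0)
  qdf <- if (nrow(qtls)) data.frame(
    trait = trait, channel_or_group = channel, qtls[, setdiff(names(qtls), "members")],
    threshold = thr$t95, variance_explained = ve,
    stringsAsFactors = FALSE) else emptyQtlFrame()
  if (nrow(qtls)) qdf$members <- qtls$members
  new("QtlScan", trait = trait, channel = channel, stats = stats,
      t95 = thr$t95, t99 = thr$t99, maxima = thr$maxima, qtls = qdf)
}

emptyQtlFrame <- function() {
  data.frame(trait = character(), channel_or_group = character(),
             chrom = character(), start_marker = character(),
             end_marker = character(), peak_marker = character(),
             peak_stat = numeric(), significance = character(),
             threshold = numeric(), variance_explained = numeric(),
             stringsAsFactors = FALSE)
}

#' Variance explained jointly by the peak markers of several QTLs
#'
#' @param y numeric trait values aligned to the rows of `G`.
#' @param G lines x markers numeric genotype matrix.
#' @param peaks peak marker ids (one per QTL).
#' @return adjusted R-squared of the joint multivariate fit.
#' @export
allQtlVariance <- function(y, G, peaks) {
  varianceExplained(y, G, unique(peaks))
}
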