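## Low-coverage genotyping against the phased parental haplotypes.
##
## At ~0.5x depth most informative SNPs have zero or one read per line,
## and a read is only useful when its allele is haplotype-diagnostic:
## given the other parent's genotype at the site, the allele identifies
## which focal haplotype was transmitted.  Sparse per-SNP observations
## are pooled into bins of `binSize` consecutive informative SNPs and
## combined by majority vote (ties and empty bins are NA).

## Bin a sorted SNP table into runs of `binSize` consecutive SNPs per
## chromosome; the last bin of a chromosome may be smaller.
makeSnpBins <- function(snps, binSize = 50) {
  stopifNot1(binSize >= 1, "binSize must be >= 1")
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  acc <- list(); binIndex <- integer(nrow(snps)); off <- 0L
  for (ch in unique(snps$chrom)) {
    w <- which(snps$chrom == ch)
    g <- (seq_along(w) - 1L) %/% as.integer(binSize)
    starts <- tapply(snps$pos[w], g, min)
    ends <- tapply(snps$pos[w], g, max)
    cnt <- tapply(snps$pos[w], g, length)
    acc[[ch]] <- data.frame(
      marker_id = markerId(ch, starts, ends), chrom = ch,
      start = as.integer(starts), end = as.integer(ends),
      snp_count = as.integer(cnt), stringsAsFactors = FALSE)
    binIndex[w] <- off + g + 1L
    off <- off + length(starts)
  }
  markers <- do.call(rbind, acc)
  rownames(markers) <- NULL
  list(markers = markers, binIndex = binIndex, order = order(snps$chrom, snps$pos))
}

#' Record haplotype-diagnostic read observations per SNP
#'
#' A focal allele is diagnostic at a site when the other parent does
#' not carry it: seeing it in a read proves which focal haplotype the
#' line inherited.  Reads carrying non-diagnostic alleles (shared with
#' the other parent, or matching neither parent: sequencing error) are
#' ignored, so at 0.5x coverage most line x SNP cells yield no record.
#'
#' @param counts low-coverage allele-count data.frame (all lines).
#' @param phased a [PhasedHaplotypes-class] object for the focal parent.
#' @param snps the informative-SNP table the phasing used (provides the
#'   other parent's genotype).
#' @return data.frame (line_id, chrom, pos, block, nH1, nH2) of sites
#'   with at least one diagnostic read; nH1/nH2 count reads supporting
#'   block haplotype 1/2.
#' @export
callSnpHaplotypes <- function(counts, phased, snps) {
  hp <- phased@haplotypes
  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  hIdx <- match(key(counts), key(hp))
  keep <- !is.na(hIdx)
  cc <- counts[keep, , drop = FALSE]; hIdx <- hIdx[keep]
  sIdx <- match(key(hp)[hIdx], key(snps))

  m <- as.matrix(cc[, BASES])
  rows <- seq_len(nrow(cc))
  h1 <- hp$hap1[hIdx]; h2 <- hp$hap2[hIdx]
  o1 <- snps$o1[sIdx]; o2 <- snps$o2[sIdx]
  diag1 <- h1 != o1 & h1 != o2
  diag2 <- h2 != o1 & h2 != o2
  nH1 <- ifelse(diag1, m[cbind(rows, match(h1, BASES))], 0L)
  nH2 <- ifelse(diag2, m[cbind(rows, match(h2, BASES))], 0L)
  has <- (nH1 + nH2) > 0
  out <- data.frame(line_id = cc$line_id[has], chrom = cc$chrom[has],
                    pos = cc$pos[has], block = hp$block[hIdx][has],
                    nH1 = as.integer(nH1[has]), nH2 = as.integer(nH2[has]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bin per-SNP haplotype observations into marker genotypes
#'
#' Bins are consecutive runs of `binSize` phased informative SNPs; the
#' bin genotype of a line is the majority of its diagnostic-read
#' observations in the bin, with ties and empty bins NA.  The vote sums
#' read counts, so it is invariant to the order of observations.
#'
#' @param obs per-SNP observations from [callSnpHaplotypes()].
#' @param phased the [PhasedHaplotypes-class] object that produced them.
#' @param binSize informative SNPs per bin (default 50).
#' @param lines line ids for the output columns (default: lines seen in
#'   `obs`); lines without observations get all-NA columns.
#' @return a [BinnedGenotypes-class] object; haplotype 1 of a block maps
#'   to label D1 (focal Pd) or N1 (focal Pn).
#' @export
binGenotypes <- function(obs, phased, binSize = 50,
                         lines = sort(unique(obs$line_id))) {
  hp <- phased@haplotypes
  bins <- makeSnpBins(hp, binSize)
  mk <- bins$markers
  ## dominant phase block of each bin; a bin spanning a block break
  ## votes only with its majority block's SNPs, because haplotype-1
  ## anchors are arbitrary across blocks and mixing them would scramble
  ## the vote
  domBlock <- vapply(
    split(hp$block, factor(bins$binIndex, levels = seq_len(nrow(mk)))),
    function(b) as.integer(names(which.max(table(b)))), 0L)
  mk$block <- unname(domBlock)

  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  hIdx <- match(key(obs), key(hp))
  bIdx <- bins$binIndex[hIdx]
  lIdx <- match(obs$line_id, lines)
  keep <- !is.na(bIdx) & !is.na(lIdx) &
    hp$block[hIdx] == mk$block[bIdx]

  nb <- nrow(mk); nl <- length(lines)
  cell <- (bIdx[keep] - 1L) * nl + lIdx[keep]
  s1 <- rowsum(obs$nH1[keep], cell)
  s2 <- rowsum(obs$nH2[keep], cell)
  tot1 <- tot2 <- matrix(0L, nl, nb)
  tot1[as.integer(rownames(s1))] <- s1
  tot2[as.integer(rownames(s2))] <- s2

  lab <- hapLabels(phased@focalParent)
  callsLN <- matrix(majorityCall(tot1, tot2, lab[1], lab[2]), nl, nb)
  calls <- t(callsLN)
  dimnames(calls) <- list(mk$marker_id, lines)
  BinnedGenotypes(phased@focalParent, mk, calls)
}

#' Per-line mean read depth from an allele-count table
#'
#' @param counts allele-count data.frame.
#' @param nSites total number of assayed sites (zero-depth rows are
#'   usually absent from the table).
#' @return named numeric vector of mean depth per line.
#' @export
lineDepths <- function(counts, nSites) {
  tot <- rowsum(rowSums(counts[, BASES]), counts$line_id)
  setNames(as.numeric(tot) / nSites, rownames(tot))
}

## Haplotype switches between consecutive non-NA bins, worst chromosome.
maxSwitchesPerChrom <- function(bg) {
  mk <- bg@markers
  apply(bg@calls, 2, function(v) {
    worst <- 0L
    for (ch in unique(mk$chrom)) {
      x <- v[mk$chrom == ch]
      x <- x[!is.na(x)]
      if (length(x) > 1) worst <- max(worst, sum(x[-1] != x[-length(x)]))
    }
    worst
  })
}

#' Select usable lines by depth, concordance and recombination pattern
#'
#' Automates the visual line QC: among lines genotyped both from
#' low-coverage genomic data and from the deep reference, a per-line
#' depth threshold is chosen as the smallest depth at which every
#' deeper overlap line (a) agrees with its reference genotypes in at
#' least `minConcordance` of doubly-called bins and (b) shows at most
#' `maxSwitches` haplotype switches per chromosome (the expected
#' recombination pattern).  All lines at or above the threshold are
#' retained.
#'
#' @param genomic [BinnedGenotypes-class] from the low-coverage data.
#' @param reference [BinnedGenotypes-class] from the deep subset (same
#'   markers).
#' @param depthPerLine named per-line mean depth (see [lineDepths()]).
#' @param minConcordance minimum genomic-vs-reference bin concordance.
#' @param maxSwitches maximum switches per chromosome.
#' @return list with `selected` (line ids), `threshold` (depth), and
#'   `diagnostics` (per overlap line: depth, concordance, max_switches,
#'   pass).
#' @export
qcSelectLines <- function(genomic, reference, depthPerLine,
                          minConcordance = 0.9, maxSwitches = 4) {
  overlap <- intersect(lineIds(genomic), lineIds(reference))
  stopifNot1(length(overlap) > 0, "no lines shared with the reference")
  stopifNot1(identical(genomic@markers$marker_id,
                       reference@markers$marker_id),
             "genomic and reference tables must share the marker set")
  ## concordance is judged away from recombination breakpoints: the
  ## bin pair flanking each reference haplotype switch is masked, since
  ## a crossover inside a bin makes its majority call legitimately
  ## depth-dependent
  mkc <- genomic@markers$chrom
  conc <- vapply(overlap, function(li) {
    g <- genomic@calls[, li]; r <- reference@calls[, li]
    mask <- rep(FALSE, length(r))
    for (ch in unique(mkc)) {
      i <- which(mkc == ch)
      rc <- r[i]
      obsIdx <- which(!is.na(rc))
      if (length(obsIdx) > 1) {
        sw <- which(rc[obsIdx][-1] != rc[obsIdx][-length(obsIdx)])
        mask[i[obsIdx[sw]]] <- TRUE
        mask[i[obsIdx[sw + 1]]] <- TRUE
      }
    }
    both <- !is.na(g) & !is.na(r) & !mask
    if (!any(both)) return(NA_real_)
    mean(g[both] == r[both])
  }, 0)
  sw <- maxSwitchesPerChrom(genomic)[overlap]
  depth <- depthPerLine[overlap]
  pass <- !is.na(conc) & conc >= minConcordance & sw <= maxSwitches
  diag <- data.frame(line = overlap, depth = as.numeric(depth),
                     concordance = conc, max_switches = as.integer(sw),
                     pass = pass, stringsAsFactors = FALSE)
  rownames(diag) <- NULL

  thr <- NA_real_
  for (d in sort(unique(depth))) {
    if (all(pass[depth >= d])) { thr <- d; break }
  }
  if (is.na(thr)) {
    stop(paste0("no depth threshold satisfies the QC criteria; worst lines: ",
                paste(utils::head(diag$line[!diag$pass], 5), collapse = ", ")),
         call. = FALSE)
  }
  all_depth <- depthPerLine[lineIds(genomic)]
  list(selected = lineIds(genomic)[!is.na(all_depth) & all_depth >= thr],
       threshold = thr, diagnostics = diag)
}

#' Accuracy of binned genotypes against the simulation truth
#'
#' Compares non-NA bin calls with the line's true haplotype at the bin
#' midpoint.  Because phase-block labels are arbitrary, agreement is
#' computed up to a global haplotype swap per (chromosome, block).
#'
#' @param binned a [BinnedGenotypes-class] object (with a `block`
#'   column in its markers, as produced by [binGenotypes()]).
#' @param pop an [F1Population-class] object.
#' @return list: `accuracy` (fraction of non-NA calls matching truth),
#'   `naRate`, and `n` (non-NA calls scored).
#' @export
binGenotypeAccuracy <- function(binned, pop) {
  mk <- binned@markers
  lab <- hapLabels(binned@focalParent)
  lines <- lineIds(binned)
  match_n <- total_n <- 0
  for (ch in unique(mk$chrom)) {
    i <- which(mk$chrom == ch)
    mids <- (mk$start[i] + mk$end[i]) %/% 2L
    hap <- trueHaplotypeAt(pop, binned@focalParent, ch, mids)[lines, , drop = FALSE]
    truth <- t(matrix(lab[hap], nrow(hap), ncol(hap)))   # bins x lines
    blocks <- if ("block" %in% names(mk)) mk$block[i] else rep(1L, length(i))
    for (b in unique(blocks)) {
      j <- i[blocks == b]
      cl <- binned@calls[j, , drop = FALSE]
      tr <- truth[blocks == b, , drop = FALSE]
      ok <- !is.na(cl)
      m <- sum(cl[ok] == tr[ok]); t0 <- sum(ok)
      match_n <- match_n + max(m, t0 - m)   # orientation-free
      total_n <- total_n + t0
    }
  }
  list(accuracy = if (total_n) match_n / total_n else NA_real_,
       naRate = mean(is.na(binned@calls)), n = total_n)
}
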