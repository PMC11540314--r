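## Parental haplotype phasing from a deep-coverage progeny subset.
##
## Each deep line inherits exactly one focal-parent allele at every
## informative SNP.  Observing which allele that was across many lines
## at two adjacent SNPs reveals whether the alleles listed first at the
## two sites ride on the same parental homolog (cis) or opposite ones
## (trans).  A link is accepted when at least floor(consistency * N)
## of the N doubly-observed lines agree with the majority orientation
## (floor semantics reproduce the 109-of-122 acceptance count at the
## default 0.9); accepted links chain SNPs into phase blocks.

#' Line-count threshold of the phasing consistency rule
#'
#' @param n number of lines observed at both SNPs of a link.
#' @param consistency required consistency fraction (default 0.9).
#' @return integer: minimum number of supporting lines,
#'   `floor(consistency * n)`.
#' @export
consistencyThreshold <- function(n, consistency = 0.9) {
  as.integer(floor(consistency * n))
}

#' Infer the inherited focal-parent allele per deep line and SNP
#'
#' At each line x informative SNP with total depth >= `depthMin`, the
#' observed allele set is explained as {focal allele f, other-parent
#' allele o}: an allele counts as observed when it carries at least
#' `minFrac` of reads and `minReads` reads.  If exactly one focal
#' allele f (paired with one of the other parent's alleles) reproduces
#' the observed set, f is recorded; ambiguous or inconsistent sites
#' (e.g. both focal alleles seen where the other parent is homozygous
#' for a third base) are missing.  Replicate count rows per line are
#' pooled before calling.
#'
#' @param counts allele-count data.frame for the deep subset.
#' @param snps informative-SNP table from [selectInformativeSnps()].
#' @param depthMin minimum total read depth per line and site
#'   (default 20).
#' @param minFrac,minReads allele-presence thresholds.
#' @return character matrix lines x SNPs (columns `chrom:pos`, ordered
#'   as `snps`) holding the inherited focal allele or NA.
#' @export
inferInheritedAlleles <- function(counts, snps, depthMin = 20,
                                  minFrac = 0.2, minReads = 2) {
  lines <- sort(unique(counts$line_id))
  siteKey <- paste(snps$chrom, snps$pos, sep = ":")
  out <- matrix(NA_character_, length(lines), length(siteKey),
                dimnames = list(lines, siteKey))

  cKey <- paste(counts$chrom, counts$pos, sep = ":")
  sIdx <- match(cKey, siteKey)
  keep <- !is.na(sIdx)
  if (!any(keep)) return(out)
  cc <- counts[keep, , drop = FALSE]
  sIdx <- sIdx[keep]

  ## pool replicate observations per (line, site)
  grp <- paste(cc$line_id, sIdx)
  if (anyDuplicated(grp)) {
    agg <- rowsum(as.matrix(cc[, BASES]), grp)
    first <- !duplicated(grp)
    ord <- match(rownames(agg), grp[first])
    cc <- cc[which(first)[ord], , drop = FALSE]
    cc[, BASES] <- agg
    sIdx <- sIdx[which(first)[ord]]
  }

  m <- as.matrix(cc[, BASES])
  depth <- rowSums(m)
  dOk <- depth >= depthMin
  if (!any(dOk)) return(out)
  m <- m[dOk, , drop = FALSE]; depth <- depth[dOk]
  sIdx <- sIdx[dOk]; lineId <- cc$line_id[dOk]

  pres <- m >= pmax(minFrac * depth, minReads)
  nPres <- rowSums(pres)
  bi <- function(al) match(al, BASES)      # base index
  a1 <- bi(snps$a1[sIdx]); a2 <- bi(snps$a2[sIdx])
  o1 <- bi(snps$o1[sIdx]); o2 <- bi(snps$o2[sIdx])
  n <- length(sIdx)
  rows <- seq_len(n)
  cand <- function(f, o) {
    pres[cbind(rows, f)] & pres[cbind(rows, o)] &
      nPres == 1L + (f != o)
  }
  f1ok <- cand(a1, o1) | cand(a1, o2)
  f2ok <- cand(a2, o1) | cand(a2, o2)
  call <- rep(NA_character_, n)
  call[f1ok & !f2ok] <- snps$a1[sIdx][f1ok & !f2ok]
  call[f2ok & !f1ok] <- snps$a2[sIdx][f2ok & !f1ok]
  has <- !is.na(call)
  out[cbind(match(lineId[has], lines), sIdx[has])] <- call[has]
  out
}

#' Phase one chromosome's informative SNPs into blocks
#'
#' For every adjacent SNP pair, lines observed at both sites vote for
#' the cis (first-listed-with-first-listed) or trans orientation; the
#' majority orientation is accepted when its support reaches
#' [consistencyThreshold()] of the votes and at least `minLines` lines
#' voted.  Accepted links chain into phase blocks; a rejected link
#' starts a new block.  Haplotype 1 of each block is anchored to the
#' first-listed allele (`a1`) of the block's first SNP.
#'
#' @param mat inherited-allele matrix from [inferInheritedAlleles()].
#' @param snps informative-SNP table.
#' @param chrom chromosome to phase.
#' @param consistency consistency fraction (default 0.9).
#' @param minLines minimum doubly-observed lines per link.
#' @return list with `haplotypes` (chrom, pos, block, hap1, hap2) and
#'   `links` (pos1, pos2, n, support, orientation, accepted).
#' @export
phaseChromosome <- function(mat, snps, chrom, consistency = 0.9,
                            minLines = 10) {
  sub <- snps[snps$chrom == chrom, , drop = FALSE]
  sub <- sub[order(sub$pos), , drop = FALSE]
  keys <- paste(sub$chrom, sub$pos, sep = ":")
  ns <- nrow(sub)
  if (ns < 2) {
    warning(sprintf("chromosome %s has < 2 informative SNPs; %s",
                    chrom, "emitting single-site block(s)"), call. = FALSE)
    hap <- data.frame(chrom = sub$chrom, pos = sub$pos,
                      block = seq_len(ns), hap1 = sub$a1, hap2 = sub$a2,
                      stringsAsFactors = FALSE)
    return(list(haplotypes = hap,
                links = data.frame(pos1 = integer(), pos2 = integer(),
                                   n = integer(), support = integer(),
                                   orientation = character(),
                                   accepted = logical())))
  }
  obs <- mat[, keys, drop = FALSE]
  links <- data.frame(pos1 = sub$pos[-ns], pos2 = sub$pos[-1],
                      n = 0L, support = 0L,
                      orientation = NA_character_, accepted = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_len(ns - 1)) {
    cs <- obs[, i]; ct <- obs[, i + 1]
    both <- !is.na(cs) & !is.na(ct)
    cis <- sum(both & ((cs == sub$a1[i] & ct == sub$a1[i + 1]) |
                         (cs == sub$a2[i] & ct == sub$a2[i + 1])))
    trans <- sum(both & ((cs == sub$a1[i] & ct == sub$a2[i + 1]) |
                           (cs == sub$a2[i] & ct == sub$a1[i + 1])))
    nObs <- cis + trans
    support <- max(cis, trans)
    links$n[i] <- nObs
    links$support[i] <- support
    links$orientation[i] <- if (cis >= trans) "cis" else "trans"
    links$accepted[i] <- nObs >= minLines && cis != trans &&
      support >= consistencyThreshold(nObs, consistency)
  }
  ## chain accepted links into blocks
  block <- integer(ns); block[1] <- 1L
  hap1 <- hap2 <- character(ns)
  hap1[1] <- sub$a1[1]; hap2[1] <- sub$a2[1]
  for (i in 2:ns) {
    if (links$accepted[i - 1]) {
      block[i] <- block[i - 1]
      cis <- links$orientation[i - 1] == "cis"
      prev1 <- hap1[i - 1] == sub$a1[i - 1]   # does hap1 carry a1 upstream?
      take1 <- prev1 == cis
      hap1[i] <- if (take1) sub$a1[i] else sub$a2[i]
      hap2[i] <- if (take1) sub$a2[i] else sub$a1[i]
    } else {
      block[i] <- block[i - 1] + 1L
      hap1[i] <- sub$a1[i]; hap2[i] <- sub$a2[i]
    }
  }
  list(haplotypes = data.frame(chrom = chrom, pos = sub$pos, block = block,
                               hap1 = hap1, hap2 = hap2,
                               stringsAsFactors = FALSE),
       links = links)
}

#' Phase all chromosomes of one focal parent
#'
#' @param mat inherited-allele matrix from [inferInheritedAlleles()].
#' @param snps informative-SNP table (carries the focal parent).
#' @param consistency consistency fraction (default 0.9).
#' @param minLines minimum doubly-observed lines per link.
#' @return a [PhasedHaplotypes-class] object.
#' @export
phaseHaplotypes <- function(mat, snps, consistency = 0.9, minLines = 10) {
  chroms <- unique(snps$chrom)
  haps <- list(); links <- list()
  for (ch in chroms) {
    r <- phaseChromosome(mat, snps, ch, consistency, minLines)
    haps[[ch]] <- r$haplotypes
    if (nrow(r$links)) links[[ch]] <- cbind(chrom = ch, r$links)
  }
  lk <- if (length(links)) do.call(rbind, links) else
    data.frame(chrom = character(), pos1 = integer(), pos2 = integer(),
               n = integer(), support = integer(),
               orientation = character(), accepted = logical())
  rownames(lk) <- NULL
  hp <- do.call(rbind, haps)
  rownames(hp) <- NULL
  new("PhasedHaplotypes",
      focalParent = attr(snps, "focalParent") %||% "Pd",
      haplotypes = hp, links = lk)
}

#' True cis/trans orientation of adjacent informative-SNP links
#'
#' Computes, from the simulated parental genomes, the true orientation
#' of each adjacent link of an informative-SNP table (used to score
#' phasing accuracy).
#'
#' @param parents a [HybridParents-class] object.
#' @param snps informative-SNP table for one focal parent.
#' @return data.frame (chrom, pos1, pos2, orientation).
#' @export
trueLinkOrientation <- function(parents, snps) {
  focal <- attr(snps, "focalParent") %||% "Pd"
  s <- parents@sites
  h1 <- if (focal == "Pd") s$pd1 else s$pn1
  key <- paste(s$chrom, s$pos)
  i <- match(paste(snps$chrom, snps$pos), key)
  onH1 <- snps$a1 == h1[i]     # does first-listed allele sit on homolog 1?
  acc <- list()
  for (ch in unique(snps$chrom)) {
    w <- which(snps$chrom == ch)
    w <- w[order(snps$pos[w])]
    if (length(w) < 2) next
    a <- onH1[w]
    acc[[ch]] <- data.frame(
      chrom = ch, pos1 = snps$pos[w][-length(w)], pos2 = snps$pos[w][-1],
      orientation = ifelse(a[-length(a)] == a[-1], "cis", "trans"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}
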