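## Informative-SNP selection.
##
## A site can reveal which of the focal parent's two haplotypes an F1
## inherited only if the focal parent is heterozygous there AND the
## other parent's genotype does not mimic the focal allele pair: the
## other parent must be homozygous, or heterozygous with a different
## (unordered) allele combination.  Species-diagnostic SNPs (fixed
## differences between the parents) carry no within-parent information
## and are not used.

#' Call a parent's genotypes from high-coverage allele counts
#'
#' An allele is accepted as present when it holds at least
#' `minFrac` of the site's reads and at least `minReads` reads; a site
#' is heterozygous iff exactly two alleles are present.  Sites with
#' zero or more than two present alleles are dropped.
#'
#' @param counts allele-count data.frame (one parent; columns chrom,
#'   pos, A, C, G, T).
#' @param minFrac minimum read fraction for an allele to count.
#' @param minReads minimum read count for an allele to count.
#' @return genotype data.frame (chrom, pos, a1, a2, depth) with
#'   `a1 <= a2`; homozygous sites have `a1 == a2`.
#' @export
callParentGenotypes <- function(counts, minFrac = 0.2, minReads = 3) {
  m <- as.matrix(counts[, BASES])
  depth <- rowSums(m)
  pres <- m >= pmax(minFrac * depth, minReads)
  nPres <- rowSums(pres)
  keep <- nPres %in% 1:2
  idx <- which(keep)
  a1 <- a2 <- character(length(idx))
  pm <- pres[idx, , drop = FALSE]
  first <- max.col(pm, ties.method = "first")
  last <- max.col(pm, ties.method = "last")
  a1 <- BASES[first]
  a2 <- BASES[last]           # == a1 at homozygous sites
  out <- data.frame(chrom = counts$chrom[idx], pos = counts$pos[idx],
                    a1 = pmin(a1, a2), a2 = pmax(a1, a2),
                    depth = depth[idx], stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Select the SNPs that distinguish a parent's two haplotypes
#'
#' Retains positions where the focal parent is heterozygous and the
#' other parent is either homozygous or heterozygous with a different
#' unordered allele pair.  Positions genotyped in only one parent are
#' excluded and counted (attribute `nSingleParent`), not an error.
#'
#' @param pdGeno,pnGeno genotype data.frames for the two parents
#'   (columns chrom, pos, a1, a2, depth), e.g. from
#'   [callParentGenotypes()] or [exactParentGenotypes()].
#' @param focal which parent's haplotypes the table should distinguish.
#' @param minDepth minimum genotyping depth required in both parents.
#' @return informative-SNP data.frame sorted by (chrom, pos) with
#'   columns chrom, pos, a1, a2 (focal allele pair, `a1 < a2`), o1, o2
#'   (other parent's genotype); attributes `focalParent` and
#'   `nSingleParent`.
#' @export
selectInformativeSnps <- function(pdGeno, pnGeno, focal = c("Pd", "Pn"),
                                  minDepth = 10) {
  focal <- match.arg(focal)
  fg <- if (focal == "Pd") pdGeno else pnGeno
  og <- if (focal == "Pd") pnGeno else pdGeno
  fg <- fg[fg$depth >= minDepth, ]
  og <- og[og$depth >= minDepth, ]
  key <- function(d) paste(d$chrom, d$pos)
  m <- match(key(fg), key(og))
  nSingle <- sum(is.na(m)) + sum(!key(og) %in% key(fg))
  ok <- !is.na(m)
  fg <- fg[ok, ]; og <- og[m[ok], ]

  focalHet <- fg$a1 != fg$a2
  samePair <- fg$a1 == og$a1 & fg$a2 == og$a2   # both stored sorted
  keep <- focalHet & !samePair                  # other hom, or het w/ diff pair
  out <- data.frame(chrom = fg$chrom[keep], pos = fg$pos[keep],
                    a1 = fg$a1[keep], a2 = fg$a2[keep],
                    o1 = og$a1[keep], o2 = og$a2[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "focalParent") <- focal
  attr(out, "nSingleParent") <- nSingle
  out
}
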