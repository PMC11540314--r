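## Synthetic F1 experiment with a truth ledger.
##
## The generator is the forward direction of everything the analysis
## assumes: two outbred parents with phased heterozygous sites, F1
## meioses with Poisson crossovers, paternal-only large indels, Poisson
## read sampling with per-read substitution error, per-bin coverage
## proportional to copy number, and phenotypes built from planted QTL
## effects plus Gaussian noise.

#' Simulate the two parental genomes
#'
#' Polymorphic sites are laid down as a Poisson process and each site is
#' assigned a joint parental configuration so that all informative and
#' non-informative classes occur: het in one parent only (vs a
#' homozygote), shared heterozygote (same allele pair in both parents,
#' uninformative), and heterozygotes with different allele pairs.  The
#' class mix is chosen so each parent's heterozygous-site density equals
#' `hetDensity` in expectation.
#'
#' @param nChrom number of chromosomes (>= 1).
#' @param chromLen chromosome length in bp (>= 1e5); scalar or vector.
#' @param hetDensity expected heterozygous sites per bp per parent.
#' @param seed optional integer seed (same seed, identical genomes).
#' @param classProbs site-class probabilities
#'   `(pdOnly, pnOnly, sharedHet, diffHet)`; must sum to 1.
#' @return a [HybridParents-class] object.
#' @export
simulateParents <- function(nChrom = 5, chromLen = 2e6, hetDensity = 2e-4,
                            seed = NULL,
                            classProbs = c(pdOnly = 0.44, pnOnly = 0.44,
                                           sharedHet = 0.06, diffHet = 0.06)) {
  stopifNot1(nChrom >= 1, "nChrom must be >= 1")
  stopifNot1(all(chromLen >= 1e5), "chromLen must be >= 1e5")
  stopifNot1(hetDensity > 0, "hetDensity must be > 0")
  stopifNot1(abs(sum(classProbs) - 1) < 1e-8, "classProbs must sum to 1")
  chromLen <- rep_len(chromLen, nChrom)
  chroms <- data.frame(chrom = sprintf("Chr%02d", seq_len(nChrom)),
                       length = as.integer(chromLen))
  ## each parent is het at classes touching it; rate scaled so that the
  ## per-parent het density matches hetDensity
  pHet <- classProbs[["pdOnly"]] + classProbs[["sharedHet"]] +
    classProbs[["diffHet"]]
  rho <- hetDensity / pHet

  withSeed(seed, {
    out <- vector("list", nChrom)
    for (i in seq_len(nChrom)) {
      n <- rpois(1, rho * chromLen[i])
      n <- min(n, chromLen[i])
      pos <- sort(sample.int(chromLen[i], n))
      cls <- sample(names(classProbs), n, replace = TRUE, prob = classProbs)
      ref <- sample(BASES, n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")
      thirdBase <- function(r, a)
        mapply(function(x, y) sample(setdiff(BASES, c(x, y)), 1), r, a)
      flip <- function(a, b, swap) ifelse(swap, b, a)

      swapPd <- runif(n) < 0.5    # random phase per site
      swapPn <- runif(n) < 0.5
      pd1 <- pd2 <- pn1 <- pn2 <- ref

      isPd <- cls %in% c("pdOnly", "sharedHet", "diffHet")
      pd1[isPd] <- flip(ref, alt, swapPd)[isPd]
      pd2[isPd] <- flip(alt, ref, swapPd)[isPd]
      isPn <- cls %in% c("pnOnly", "sharedHet")
      pn1[isPn] <- flip(ref, alt, swapPn)[isPn]
      pn2[isPn] <- flip(alt, ref, swapPn)[isPn]
      ## het with a different allele pair: {ref, b}, b outside {ref, alt}
      isDiff <- cls == "diffHet"
      if (any(isDiff)) {
        b <- thirdBase(ref[isDiff], alt[isDiff])
        pn1[isDiff] <- flip(ref[isDiff], b, swapPn[isDiff])
        pn2[isDiff] <- flip(b, ref[isDiff], swapPn[isDiff])
      }
      ## pdOnly/pnOnly: other parent homozygous for ref or alt
      homAlt <- runif(n) < 0.3
      i1 <- cls == "pdOnly" & homAlt
      pn1[i1] <- pn2[i1] <- alt[i1]
      i2 <- cls == "pnOnly" & homAlt
      pd1[i2] <- pd2[i2] <- alt[i2]

      out[[i]] <- data.frame(chrom = chroms$chrom[i], pos = pos,
                             pd1 = pd1, pd2 = pd2, pn1 = pn1, pn2 = pn2,
                             stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, out)
    rownames(sites) <- NULL
    new("HybridParents", chroms = chroms, sites = sites)
  })
}

#' Simulate F1 lines: meioses and induced indels
#'
#' Each line receives one independent meiosis per parent per chromosome
#' (crossover count Poisson(`recombPerChrom`), breakpoints uniform, no
#' interference) and Poisson(`indelRate`) large indels, all placed on
#' the paternally inherited (*P. nigra*) chromosomes.  Indels that would
#' overlap within a line are re-drawn, keeping the paternal copy number
#' in {0, 1, 2}.
#'
#' @param parents a [HybridParents-class] object.
#' @param nLines number of F1 lines (>= 1).
#' @param recombPerChrom expected crossovers per chromosome per meiosis.
#' @param indelRate mean indels per line.
#' @param indelSizeRange `(min, max)` indel size in bp.
#' @param pDeletion probability an indel is a deletion (vs insertion).
#' @param seed optional integer seed.
#' @return an [F1Population-class] object.
#' @export
simulateF1 <- function(parents, nLines = 343, recombPerChrom = 1,
                       indelRate = 2.5, indelSizeRange = c(250e3, 1e6),
                       pDeletion = 0.665, seed = NULL) {
  stopifNot1(nLines >= 1, "nLines must be >= 1")
  stopifNot1(recombPerChrom >= 0 && indelRate >= 0,
             "rates must be non-negative")
  stopifNot1(pDeletion >= 0 && pDeletion <= 1, "pDeletion must be in [0,1]")
  stopifNot1(indelSizeRange[1] <= max(parents@chroms$length),
             "indelSizeRange minimum exceeds every chromosome length")
  lines <- sprintf("L%03d", seq_len(nLines))
  chroms <- parents@chroms

  withSeed(seed, {
    nCell <- nLines * 2L * nrow(chroms)
    aStart <- aEnd <- aHap <- vector("list", nCell)
    aLine <- aParent <- aChrom <- character(nCell)
    aLen <- integer(nCell)
    k <- 0L
    for (li in lines) {
      for (pa in c("Pd", "Pn")) {
        for (ci in seq_len(nrow(chroms))) {
          len <- chroms$length[ci]
          ncx <- rpois(1, recombPerChrom)
          bp <- sort(unique(as.integer(ceiling(runif(ncx) * (len - 1)))))
          starts <- c(1L, bp + 1L)
          ends <- c(bp, len)
          h0 <- sample(1:2, 1)
          haps <- rep_len(c(h0, 3L - h0), length(starts))
          k <- k + 1L
          aStart[[k]] <- starts; aEnd[[k]] <- ends; aHap[[k]] <- haps
          aLine[k] <- li; aParent[k] <- pa; aChrom[k] <- chroms$chrom[ci]
          aLen[k] <- length(starts)
        }
      }
    }
    inheritance <- data.frame(
      line = rep(aLine, aLen), parent = rep(aParent, aLen),
      chrom = rep(aChrom, aLen),
      start = unlist(aStart), end = unlist(aEnd),
      hap = unlist(aHap), stringsAsFactors = FALSE)

    ## indels: Poisson count per line, overlapping draws rejected
    iacc <- list()
    for (li in lines) {
      nid <- rpois(1, indelRate)
      if (nid == 0) next
      cur <- data.frame()
      for (j in seq_len(nid)) {
        for (try in 1:100) {
          ci <- sample.int(nrow(chroms), 1, prob = chroms$length)
          len <- chroms$length[ci]
          lo <- min(indelSizeRange[1], len)
          hi <- min(indelSizeRange[2], len)
          size <- floor(runif(1, lo, hi + 1))
          start <- as.integer(ceiling(runif(1) * (len - size + 1)))
          end <- start + size - 1L
          clash <- nrow(cur) > 0 &&
            any(cur$chrom == chroms$chrom[ci] & cur$start <= end &
                  cur$end >= start)
          if (!clash) break
        }
        if (clash) next   # pathological geometry; drop this indel
        kind <- if (runif(1) < pDeletion) "deletion" else "insertion"
        cur <- rbind(cur, data.frame(line = li, chrom = chroms$chrom[ci],
                                     start = start, end = end, kind = kind,
                                     stringsAsFactors = FALSE))
      }
      if (nrow(cur)) iacc[[li]] <- cur
    }
    indels <- if (length(iacc)) do.call(rbind, iacc) else
      data.frame(line = character(), chrom = character(),
                 start = integer(), end = integer(), kind = character(),
                 stringsAsFactors = FALSE)
    rownames(indels) <- NULL
    new("F1Population", lines = lines, chroms = chroms,
        inheritance = inheritance, indels = indels)
  })
}

## ---------------------------------------------------------------------
## Truth lookups.

#' True inherited haplotype at positions
#'
#' @param pop an [F1Population-class] object.
#' @param parent `"Pd"` or `"Pn"`.
#' @param chrom chromosome name.
#' @param pos integer vector of positions.
#' @return integer matrix (lines x positions) of inherited haplotype 1/2.
#' @export
trueHaplotypeAt <- function(pop, parent, chrom, pos) {
  sub <- pop@inheritance[pop@inheritance$parent == parent &
                           pop@inheritance$chrom == chrom, ]
  out <- matrix(NA_integer_, length(pop@lines), length(pos),
                dimnames = list(pop@lines, NULL))
  for (li in pop@lines) {
    s <- sub[sub$line == li, ]
    idx <- findInterval(pos, s$start)
    out[li, ] <- s$hap[idx]
  }
  out
}

#' True paternal (*P. nigra*) copy number at positions
#'
#' 1 for the regular state, 0 inside a deletion, 2 inside an insertion.
#'
#' @inheritParams trueHaplotypeAt
#' @return integer matrix (lines x positions) with values 0/1/2.
#' @export
truePnCopiesAt <- function(pop, chrom, pos) {
  out <- matrix(1L, length(pop@lines), length(pos),
                dimnames = list(pop@lines, NULL))
  ind <- pop@indels[pop@indels$chrom == chrom, ]
  for (r in seq_len(nrow(ind))) {
    hit <- pos >= ind$start[r] & pos <= ind$end[r]
    if (any(hit))
      out[ind$line[r], hit] <- if (ind$kind[r] == "deletion") 0L else 2L
  }
  out
}

#' True genotype code for a QTL channel at one position
#'
#' The numeric coding used by both the phenotype generator and the QTL
#' scans: `Pd` D1→0/D2→1; `Pn` N1→0/N2→1 (0 when the paternal copy is
#' deleted); `dosage` the paternal copy number 0/1/2; `deletion` /
#' `insertion` the 0/1 indicator of that state.
#'
#' @param pop an [F1Population-class] object.
#' @param chrom,pos the locus.
#' @param channel one of `"Pd"`, `"Pn"`, `"dosage"`, `"deletion"`,
#'   `"insertion"`.
#' @return named numeric vector over lines.
#' @export
genotypeCodeAt <- function(pop, chrom, pos,
                           channel = c("Pd", "Pn", "dosage", "deletion",
                                       "insertion")) {
  channel <- match.arg(channel)
  cop <- truePnCopiesAt(pop, chrom, pos)[, 1]
  switch(channel,
    Pd = trueHaplotypeAt(pop, "Pd", chrom, pos)[, 1] - 1,
    Pn = (trueHaplotypeAt(pop, "Pn", chrom, pos)[, 1] - 1) * (cop > 0),
    dosage = as.numeric(cop),
    deletion = as.numeric(cop == 0),
    insertion = as.numeric(cop == 2))
}

## ---------------------------------------------------------------------
## Read-count simulation.

othersOf <- function(idx) {
  ## 4 x 3 lookup: the three non-self bases
  t(vapply(1:4, function(i) setdiff(1:4, i), integer(3)))[idx, , drop = FALSE]
}

## Draw ACGT counts for records carrying one maternal allele (1 copy)
## and `pnCopies` copies of one paternal allele.  Depth is Poisson in
## the total copy number; each read substitutes to a uniform other base
## with probability errorRate.
simCountsCore <- function(pdAllele, pnAllele, pnCopies, meanDepth, errorRate) {
  n <- length(pdAllele)
  copies <- 1L + pnCopies
  depth <- rpois(n, meanDepth * copies / 2)
  readsPd <- rbinom(n, depth, 1 / copies)
  readsPn <- depth - readsPd
  counts <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  addAllele <- function(reads, alleleIdx) {
    e <- rbinom(n, reads, errorRate)
    keep <- reads - e
    has <- keep > 0 & !is.na(alleleIdx)
    ij <- cbind(which(has), alleleIdx[has])
    counts[ij] <<- counts[ij] + keep[has]
    if (any(e > 0)) {
      e1 <- rbinom(n, e, 1 / 3)
      e2 <- rbinom(n, e - e1, 1 / 2)
      e3 <- e - e1 - e2
      oth <- othersOf(ifelse(is.na(alleleIdx), 1L, alleleIdx))
      for (j in 1:3) {
        ej <- list(e1, e2, e3)[[j]]
        hasE <- ej > 0
        ij <- cbind(which(hasE), oth[hasE, j])
        counts[ij] <<- counts[ij] + ej[hasE]
      }
    }
  }
  addAllele(readsPd, match(pdAllele, BASES))
  addAllele(readsPn, match(pnAllele, BASES))
  counts
}

## Per-line true alleles at all sites: list(pd, pn, copies) as vectors
## over sites (ordered as parents@sites).
lineAllelesAt <- function(parents, pop, line) {
  s <- parents@sites
  pdA <- character(nrow(s)); pnA <- character(nrow(s))
  cop <- rep(1L, nrow(s))
  for (ch in unique(s$chrom)) {
    i <- which(s$chrom == ch)
    pos <- s$pos[i]
    for (pa in c("Pd", "Pn")) {
      sub <- pop@inheritance[pop@inheritance$line == line &
                               pop@inheritance$parent == pa &
                               pop@inheritance$chrom == ch, ]
      hap <- sub$hap[findInterval(pos, sub$start)]
      if (pa == "Pd")
        pdA[i] <- ifelse(hap == 1L, s$pd1[i], s$pd2[i])
      else
        pnA[i] <- ifelse(hap == 1L, s$pn1[i], s$pn2[i])
    }
    ind <- pop@indels[pop@indels$line == line & pop@indels$chrom == ch, ]
    for (r in seq_len(nrow(ind))) {
      hit <- i[pos >= ind$start[r] & pos <= ind$end[r]]
      cop[hit] <- if (ind$kind[r] == "deletion") 0L else 2L
    }
  }
  pnA[cop == 0L] <- NA_character_
  list(pd = pdA, pn = pnA, copies = cop)
}

#' Simulate per-line allele counts at the polymorphic sites
#'
#' Per-site depth is Poisson(`meanDepth` x copies/2), where copies is
#' the line's total copy number at the site (2 regular, 1 inside a
#' deletion, 3 inside an insertion); each read is drawn from the line's
#' true allele copies and substituted to a uniform other base with
#' probability `errorRate`.
#'
#' @param parents a [HybridParents-class] object.
#' @param pop an [F1Population-class] object.
#' @param lines line ids to simulate (default: all).
#' @param meanDepth mean read depth per site for a euploid region.
#' @param errorRate per-read substitution probability (< 0.25).
#' @param seed optional integer seed.
#' @param dropZero drop rows with zero total reads (default TRUE).
#' @return allele-count data.frame (line_id, chrom, pos, A, C, G, T).
#' @export
simulateAlleleCounts <- function(parents, pop, lines = lineIds(pop),
                                 meanDepth = 0.5, errorRate = 0.005,
                                 seed = NULL, dropZero = TRUE) {
  stopifNot1(meanDepth > 0, "meanDepth must be > 0")
  stopifNot1(errorRate >= 0 && errorRate < 0.25,
             "errorRate must be in [0, 0.25)")
  s <- parents@sites
  withSeed(seed, {
    per <- lapply(lines, function(li) {
      al <- lineAllelesAt(parents, pop, li)
      counts <- simCountsCore(al$pd, al$pn, al$copies, meanDepth, errorRate)
      df <- data.frame(line_id = li, chrom = s$chrom, pos = s$pos,
                       counts, stringsAsFactors = FALSE)
      if (dropZero) df <- df[rowSums(counts) > 0, , drop = FALSE]
      df
    })
    out <- do.call(rbind, per)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a parent's own sequencing counts
#'
#' The parent is an ordinary diploid: both of its haplotypes are present
#' in one copy each.
#'
#' @param parents a [HybridParents-class] object.
#' @param parent `"Pd"` or `"Pn"`.
#' @param meanDepth mean depth per site (e.g. 45 for the maternal
#'   parent, 65 for the paternal parent).
#' @param errorRate per-read substitution probability.
#' @param seed optional integer seed.
#' @return allele-count data.frame with `line_id` set to the parent id.
#' @export
simulateParentCounts <- function(parents, parent = c("Pd", "Pn"),
                                 meanDepth = 45, errorRate = 0.005,
                                 seed = NULL) {
  parent <- match.arg(parent)
  s <- parents@sites
  a1 <- if (parent == "Pd") s$pd1 else s$pn1
  a2 <- if (parent == "Pd") s$pd2 else s$pn2
  withSeed(seed, {
    counts <- simCountsCore(a1, a2, rep(1L, nrow(s)), meanDepth, errorRate)
    out <- data.frame(line_id = parent, chrom = s$chrom, pos = s$pos,
                      counts, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-line per-bin read coverage
#'
#' Bins tile each chromosome; a bin's coverage is
#' Poisson(`meanCov` x copies/2) with copies the line's total copy
#' number at the bin midpoint.
#'
#' @param pop an [F1Population-class] object.
#' @param binSize bin width in bp.
#' @param meanCov expected reads per bin for a euploid line.
#' @param seed optional integer seed.
#' @return a [BinCoverage-class] object (bins x lines).
#' @export
simulateBinCoverage <- function(pop, binSize = 5e4, meanCov = 250,
                                seed = NULL) {
  stopifNot1(binSize > 0, "binSize must be > 0")
  bins <- tileBins(pop@chroms, binSize)
  withSeed(seed, {
    cov <- matrix(0, nrow(bins), length(pop@lines),
                  dimnames = list(bins$marker_id, pop@lines))
    for (ch in unique(bins$chrom)) {
      i <- which(bins$chrom == ch)
      mids <- (bins$start[i] + bins$end[i]) %/% 2L
      copies <- 1L + truePnCopiesAt(pop, ch, mids)   # lines x bins
      cov[i, ] <- t(matrix(rpois(length(copies), meanCov * copies / 2),
                           nrow(copies), ncol(copies)))
    }
    new("BinCoverage", bins = bins, cov = cov)
  })
}

## Fixed-width 1-based inclusive tiling of the genome.
tileBins <- function(chroms, binSize) {
  acc <- lapply(seq_len(nrow(chroms)), function(i) {
    starts <- seq(1L, chroms$length[i], by = as.integer(binSize))
    ends <- pmin(starts + as.integer(binSize) - 1L, chroms$length[i])
    data.frame(marker_id = markerId(chroms$chrom[i], starts, ends),
               chrom = chroms$chrom[i], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}

#' Simulate phenotypes from planted QTL effects
#'
#' The forward direction of the single-marker model: trait value =
#' `beta0` + sum of planted effects x genotype codes + Gaussian noise.
#' Genotype codes are taken from the line's truth at the QTL interval
#' midpoint (see [genotypeCodeAt()]).
#'
#' @param pop an [F1Population-class] object.
#' @param qtls data.frame of planted QTLs with columns `trait`, `chrom`,
#'   `start`, `end`, `channel`, `effect` (trait units per genotype
#'   unit).  May have zero rows.
#' @param beta0 intercept.
#' @param noiseSd residual standard deviation (per trait, recycled).
#' @param nullTraits extra trait names carrying pure noise.
#' @param seed optional integer seed.
#' @return phenotype data.frame (`line_id` + one column per trait).
#' @export
simulatePhenotypes <- function(pop, qtls, beta0 = 0, noiseSd = 1,
                               nullTraits = character(0), seed = NULL) {
  len <- setNames(pop@chroms$length, pop@chroms$chrom)
  if (nrow(qtls)) {
    stopifNot1(all(qtls$chrom %in% names(len)) &&
                 all(qtls$start >= 1) && all(qtls$end <= len[qtls$chrom]),
               "planted QTL outside the simulated genome")
  }
  traits <- unique(c(qtls$trait, nullTraits))
  nl <- length(pop@lines)
  withSeed(seed, {
    out <- matrix(rnorm(nl * length(traits), beta0, noiseSd), nl,
                  dimnames = list(pop@lines, traits))
    for (r in seq_len(nrow(qtls))) {
      mid <- (qtls$start[r] + qtls$end[r]) %/% 2L
      code <- genotypeCodeAt(pop, qtls$chrom[r], mid, qtls$channel[r])
      out[, qtls$trait[r]] <- out[, qtls$trait[r]] + qtls$effect[r] * code
    }
    data.frame(line_id = pop@lines, out, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
}

#' Absolute effect size for a standardized planted effect
#'
#' Converts a standardized effect (slope per standard deviation of the
#' genotype code, in residual-SD units) into the absolute trait-unit
#' effect used by [simulatePhenotypes()]: beta = e * noiseSd / sd(code).
#'
#' @param pop an [F1Population-class] object.
#' @param chrom,pos locus of the planted QTL.
#' @param channel genotype channel (see [genotypeCodeAt()]).
#' @param standardized standardized effect size.
#' @param noiseSd residual standard deviation of the trait.
#' @return absolute effect in trait units per genotype unit.
#' @export
plantedEffect <- function(pop, chrom, pos, channel, standardized,
                          noiseSd = 1) {
  code <- genotypeCodeAt(pop, chrom, pos, channel)
  s <- sd(code)
  stopifNot1(is.finite(s) && s > 0,
             "genotype code is constant at %s:%d (channel %s)",
             chrom, as.integer(pos), channel)
  standardized * noiseSd / s
}

#' Truth-derived common marker table
#'
#' Builds the unified (Pd, Pn, dosage) marker table directly from the
#' simulation truth, bypassing read-level genotyping: markers are bins
#' of `binSize` consecutive Pd-informative SNPs and each cell is the
#' line's true state at the marker midpoint.  Used to study the QTL
#' stages in isolation from genotyping noise.
#'
#' @param parents a [HybridParents-class] object.
#' @param pop an [F1Population-class] object.
#' @param binSize informative SNPs per marker bin.
#' @return a [CommonMarkers-class] object.
#' @export
truthCommonMarkers <- function(parents, pop, binSize = 50) {
  info <- selectInformativeSnps(exactParentGenotypes(parents, "Pd"),
                                exactParentGenotypes(parents, "Pn"),
                                focal = "Pd")
  mk <- makeSnpBins(info, binSize)$markers
  nl <- length(pop@lines)
  pd <- pn <- matrix(NA_character_, nrow(mk), nl,
                     dimnames = list(mk$marker_id, pop@lines))
  dose <- matrix(NA_integer_, nrow(mk), nl,
                 dimnames = list(mk$marker_id, pop@lines))
  for (ch in unique(mk$chrom)) {
    i <- which(mk$chrom == ch)
    mids <- (mk$start[i] + mk$end[i]) %/% 2L
    hd <- trueHaplotypeAt(pop, "Pd", ch, mids)
    hn <- trueHaplotypeAt(pop, "Pn", ch, mids)
    cop <- truePnCopiesAt(pop, ch, mids)
    pd[i, ] <- t(matrix(c("D1", "D2")[hd], nrow(hd), ncol(hd)))
    pnl <- matrix(c("N1", "N2")[hn], nrow(hn), ncol(hn))
    pnl[cop == 0L] <- NA_character_
    pn[i, ] <- t(pnl)
    dose[i, ] <- t(cop)
  }
  CommonMarkers(mk, pd, pn, dose)
}

#' Exact per-site parental genotypes from simulation truth
#'
#' @param parents a [HybridParents-class] object.
#' @param parent `"Pd"` or `"Pn"`.
#' @return genotype data.frame (chrom, pos, a1, a2, depth = Inf)
#'   directly comparable to [callParentGenotypes()] output.
#' @export
exactParentGenotypes <- function(parents, parent = c("Pd", "Pn")) {
  parent <- match.arg(parent)
  s <- parents@sites
  a1 <- if (parent == "Pd") s$pd1 else s$pn1
  a2 <- if (parent == "Pd") s$pd2 else s$pn2
  data.frame(chrom = s$chrom, pos = s$pos,
             a1 = pmin(a1, a2), a2 = pmax(a1, a2), depth = Inf,
             stringsAsFactors = FALSE)
}
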