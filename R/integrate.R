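## Flanking-marker imputation and the common marker list.
##
## Binned markers do not tile the genome: between the last SNP of one
## bin and the first SNP of the next lies an interval with no direct
## observation.  The gap inherits a genotype only when both flanking
## markers agree (e.g. N1 at Chr01_1_10000 and N1 at Chr01_20000_30000
## imputes N1 across Chr01_10001_19999); unequal or missing flanks, and
## the regions before the first / after the last marker of a
## chromosome, stay NA.

#' Impute genotypes between flanking binned markers
#'
#' @param binned a [BinnedGenotypes-class] object.
#' @return a `genotypeQuery` list with the original markers/calls, the
#'   inter-marker `gaps` (with ids `Chr_start_end`) and the per-line
#'   imputed `gapCalls`; query it with [genotypeAt()].
#' @export
imputeBetweenFlanks <- function(binned) {
  mk <- binned@markers
  cl <- binned@calls
  acc <- list(); gcalls <- list()
  for (ch in unique(mk$chrom)) {
    i <- which(mk$chrom == ch)
    if (length(i) < 2) next
    left <- i[-length(i)]; right <- i[-1]
    open <- mk$start[right] > mk$end[left] + 1L
    if (!any(open)) next
    l <- left[open]; r <- right[open]
    g <- data.frame(
      gap_id = markerId(ch, mk$end[l] + 1L, mk$start[r] - 1L),
      chrom = ch, start = mk$end[l] + 1L, end = mk$start[r] - 1L,
      stringsAsFactors = FALSE)
    v <- cl[l, , drop = FALSE]
    w <- cl[r, , drop = FALSE]
    eq <- !is.na(v) & !is.na(w) & v == w
    imp <- matrix(NA_character_, nrow(g), ncol(cl),
                  dimnames = list(g$gap_id, colnames(cl)))
    imp[eq] <- v[eq]
    acc[[ch]] <- g
    gcalls[[ch]] <- imp
  }
  gaps <- if (length(acc)) do.call(rbind, acc) else
    data.frame(gap_id = character(), chrom = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  rownames(gaps) <- NULL
  gapCalls <- if (length(gcalls)) do.call(rbind, gcalls) else
    matrix(NA_character_, 0, ncol(cl), dimnames = list(NULL, colnames(cl)))
  structure(list(markers = mk, calls = cl, gaps = gaps,
                 gapCalls = gapCalls, focalParent = binned@focalParent),
            class = "genotypeQuery")
}

#' Query genotypes at arbitrary positions
#'
#' Positions inside a marker return the marker call; positions inside
#' an inter-marker gap return the flank-imputed value; positions before
#' the first or after the last marker of a chromosome return NA.
#'
#' @param query a `genotypeQuery` from [imputeBetweenFlanks()].
#' @param chrom chromosome name.
#' @param pos single position (1-based).
#' @return named character vector over lines.
#' @export
genotypeAt <- function(query, chrom, pos) {
  lines <- colnames(query$calls)
  na <- setNames(rep(NA_character_, length(lines)), lines)
  mk <- query$markers
  i <- which(mk$chrom == chrom)
  if (!length(i)) return(na)
  k <- findInterval(pos, mk$start[i])
  if (k >= 1 && pos <= mk$end[i[k]]) return(query$calls[i[k], ])
  g <- which(query$gaps$chrom == chrom & query$gaps$start <= pos &
               query$gaps$end >= pos)
  if (length(g)) return(query$gapCalls[g[1], ])
  na
}

#' Build the unified common marker table
#'
#' The maternal (*P. deltoides*) binned markers are the reference
#' coordinates.  At each marker midpoint the paternal (*P. nigra*)
#' genotype is looked up through flanking-marker imputation and the
#' dosage is read from the bin containing the midpoint; a deleted
#' paternal segment (dose 0) carries no Pn haplotype, so `pn` is forced
#' NA there.
#'
#' @param pdBinned [BinnedGenotypes-class] for *P. deltoides*.
#' @param pnBinned [BinnedGenotypes-class] for *P. nigra*.
#' @param dosage [DosageCalls-class] on the same reference coordinates.
#' @param lines line ids to keep (default: lines common to all inputs).
#' @return a [CommonMarkers-class] object.
#' @export
buildCommonMarkers <- function(pdBinned, pnBinned, dosage,
                               lines = NULL) {
  stopifNot1(pdBinned@focalParent == "Pd" && pnBinned@focalParent == "Pn",
             "pdBinned/pnBinned must be focal Pd and Pn respectively")
  chr <- unique(pdBinned@markers$chrom)
  for (other in list(pnBinned@markers$chrom, dosage@markers$chrom)) {
    onlyOne <- union(setdiff(chr, other), setdiff(other, chr))
    stopifNot1(length(onlyOne) == 0,
               "chromosome(s) present in only one input: %s",
               paste(onlyOne, collapse = ", "))
  }
  if (is.null(lines))
    lines <- Reduce(intersect, list(lineIds(pdBinned), lineIds(pnBinned),
                                    lineIds(dosage)))
  stopifNot1(length(lines) > 0, "no lines shared across the three inputs")

  mk <- pdBinned@markers[, c("marker_id", "chrom", "start", "end",
                             "snp_count")]
  pd <- pdBinned@calls[, lines, drop = FALSE]
  pnQ <- imputeBetweenFlanks(pnBinned)
  dmk <- dosage@markers
  pn <- matrix(NA_character_, nrow(mk), length(lines),
               dimnames = list(mk$marker_id, lines))
  dose <- matrix(NA_integer_, nrow(mk), length(lines),
                 dimnames = list(mk$marker_id, lines))
  for (r in seq_len(nrow(mk))) {
    mid <- (mk$start[r] + mk$end[r]) %/% 2L
    pn[r, ] <- genotypeAt(pnQ, mk$chrom[r], mid)[lines]
    i <- which(dmk$chrom == mk$chrom[r])
    if (length(i)) {
      k <- findInterval(mid, dmk$start[i])
      if (k >= 1 && mid <= dmk$end[i[k]])
        dose[r, ] <- dosage@calls[i[k], lines]
    }
  }
  pn[!is.na(dose) & dose == 0L] <- NA_character_
  CommonMarkers(mk, pd, pn, dose)
}
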