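## Central S4 containers.
##
## All marker-indexed containers store markers as rows and F1 lines as
## columns (features x samples), with marker ids of the form
## Chr01_<start>_<end> (1-based, inclusive on both ends) as rownames.

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

## ---------------------------------------------------------------------
## HybridParents: the two outbred parental genomes.
##
## `sites` holds every polymorphic position with the four haplotype
## alleles pd1/pd2 (P. deltoides haplotypes 1/2) and pn1/pn2 (P. nigra);
## a parent homozygous at a site simply has its two columns equal.

setClass("HybridParents",
  representation(chroms = "data.frame", sites = "data.frame"))

setValidity("HybridParents", function(object) {
  if (!all(c("chrom", "length") %in% names(object@chroms)))
    return("chroms needs columns chrom, length")
  need <- c("chrom", "pos", "pd1", "pd2", "pn1", "pn2")
  if (!all(need %in% names(object@sites)))
    return(sprintf("sites needs columns %s", paste(need, collapse = ", ")))
  s <- object@sites
  if (nrow(s)) {
    if (any(s$pos < 1)) return("positions are 1-based (pos >= 1)")
    for (ch in unique(s$chrom)) {
      p <- s$pos[s$chrom == ch]
      if (is.unsorted(p, strictly = TRUE))
        return("positions must be strictly increasing within a chromosome")
    }
    al <- unlist(s[, c("pd1", "pd2", "pn1", "pn2")], use.names = FALSE)
    if (!all(al %in% BASES)) return("alleles must be A/C/G/T")
  }
  TRUE
})

setMethod("show", "HybridParents", function(object) {
  s <- object@sites
  cat(sprintf("HybridParents: %d chromosome(s), %d polymorphic site(s)\n",
              nrow(object@chroms), nrow(s)))
  cat(sprintf("  het in Pd: %d   het in Pn: %d\n",
              sum(s$pd1 != s$pd2), sum(s$pn1 != s$pn2)))
})

## ---------------------------------------------------------------------
## F1Population: inheritance mosaics and induced indels for each line.

setClass("F1Population",
  representation(lines = "character", chroms = "data.frame",
                 inheritance = "data.frame", indels = "data.frame"))

setValidity("F1Population", function(object) {
  inh <- object@inheritance
  need <- c("line", "parent", "chrom", "start", "end", "hap")
  if (!all(need %in% names(inh)))
    return(sprintf("inheritance needs columns %s", paste(need, collapse = ", ")))
  if (!all(inh$parent %in% c("Pd", "Pn"))) return("parent must be Pd or Pn")
  if (!all(inh$hap %in% c(1L, 2L))) return("hap must be 1 or 2")
  ind <- object@indels
  needi <- c("line", "chrom", "start", "end", "kind")
  if (!all(needi %in% names(ind)))
    return(sprintf("indels needs columns %s", paste(needi, collapse = ", ")))
  if (nrow(ind) && !all(ind$kind %in% c("deletion", "insertion")))
    return("indel kind must be deletion or insertion")
  if (nrow(ind)) {
    len <- setNames(object@chroms$length, object@chroms$chrom)
    if (any(ind$start < 1) || any(ind$end > len[ind$chrom]))
      return("indels must lie within chromosome bounds")
  }
  TRUE
})

setMethod("show", "F1Population", function(object) {
  carriers <- length(unique(object@indels$line))
  cat(sprintf("F1Population: %d line(s), %d indel(s) in %d carrier line(s)\n",
              length(object@lines), nrow(object@indels), carriers))
})

## ---------------------------------------------------------------------
## PhasedHaplotypes: per-chromosome phase blocks for one focal parent.

setClass("PhasedHaplotypes",
  representation(focalParent = "character", haplotypes = "data.frame",
                 links = "data.frame"))

setValidity("PhasedHaplotypes", function(object) {
  if (!object@focalParent %in% c("Pd", "Pn"))
    return("focalParent must be 'Pd' or 'Pn'")
  h <- object@haplotypes
  need <- c("chrom", "pos", "block", "hap1", "hap2")
  if (!all(need %in% names(h)))
    return(sprintf("haplotypes needs columns %s", paste(need, collapse = ", ")))
  if (nrow(h)) {
    if (any(h$hap1 == h$hap2)) return("hap1 and hap2 alleles must differ")
    key <- paste(h$chrom, h$block)
    for (k in unique(key)) {
      p <- h$pos[key == k]
      if (is.unsorted(p, strictly = TRUE))
        return("positions must be strictly increasing within a block")
    }
  }
  TRUE
})

setMethod("show", "PhasedHaplotypes", function(object) {
  h <- object@haplotypes
  cat(sprintf("PhasedHaplotypes (%s): %d SNP(s) in %d block(s) on %d chromosome(s)\n",
              object@focalParent, nrow(h),
              length(unique(paste(h$chrom, h$block))),
              length(unique(h$chrom))))
  if (nrow(object@links))
    cat(sprintf("  adjacent links: %d accepted / %d tested\n",
                sum(object@links$accepted), nrow(object@links)))
})

## ---------------------------------------------------------------------
## BinnedGenotypes: markers x lines haplotype calls for one parent.

setClass("BinnedGenotypes",
  representation(focalParent = "character", markers = "data.frame",
                 calls = "matrix"))

hapLabels <- function(focal) if (focal == "Pd") c("D1", "D2") else c("N1", "N2")

setValidity("BinnedGenotypes", function(object) {
  if (!object@focalParent %in% c("Pd", "Pn"))
    return("focalParent must be 'Pd' or 'Pn'")
  ok <- checkMarkerFrame(object@markers)
  if (!isTRUE(ok)) return(ok)
  if (nrow(object@calls) != nrow(object@markers))
    return("calls must have one row per marker")
  if (!identical(rownames(object@calls), object@markers$marker_id))
    return("rownames(calls) must equal markers$marker_id")
  lab <- hapLabels(object@focalParent)
  v <- object@calls[!is.na(object@calls)]
  if (length(v) && !all(v %in% lab))
    return(sprintf("calls must be %s or NA", paste(lab, collapse = "/")))
  TRUE
})

setMethod("show", "BinnedGenotypes", function(object) {
  cat(sprintf("BinnedGenotypes (%s): %d marker(s) x %d line(s), %.1f%% NA\n",
              object@focalParent, nrow(object@calls), ncol(object@calls),
              100 * mean(is.na(object@calls))))
})

#' Construct a BinnedGenotypes object
#'
#' @param focalParent `"Pd"` or `"Pn"`.
#' @param markers data.frame with columns `marker_id`, `chrom`, `start`,
#'   `end` and optionally `snp_count`, sorted and non-overlapping.
#' @param calls character matrix (markers x lines) with values `D1`/`D2`
#'   (or `N1`/`N2`) and `NA`.
#' @return A validated `BinnedGenotypes` object.
#' @export
BinnedGenotypes <- function(focalParent, markers, calls) {
  if (!"snp_count" %in% names(markers)) markers$snp_count <- NA_integer_
  rownames(markers) <- NULL
  rownames(calls) <- markers$marker_id
  new("BinnedGenotypes", focalParent = focalParent,
      markers = markers, calls = calls)
}

## ---------------------------------------------------------------------
## DosageCalls: markers x lines paternal copy-number genotypes 0/1/2.

setClass("DosageCalls",
  representation(markers = "data.frame", calls = "matrix"))

setValidity("DosageCalls", function(object) {
  ok <- checkMarkerFrame(object@markers)
  if (!isTRUE(ok)) return(ok)
  if (nrow(object@calls) != nrow(object@markers))
    return("calls must have one row per marker")
  if (!identical(rownames(object@calls), object@markers$marker_id))
    return("rownames(calls) must equal markers$marker_id")
  v <- object@calls[!is.na(object@calls)]
  if (length(v) && !all(v %in% 0:2)) return("dosage must be 0, 1, 2 or NA")
  TRUE
})

setMethod("show", "DosageCalls", function(object) {
  v <- object@calls
  cat(sprintf("DosageCalls: %d bin(s) x %d line(s); 0/1/2 = %d/%d/%d, NA = %d\n",
              nrow(v), ncol(v), sum(v == 0, na.rm = TRUE),
              sum(v == 1, na.rm = TRUE), sum(v == 2, na.rm = TRUE),
              sum(is.na(v))))
})

#' Construct a DosageCalls object
#'
#' @param markers data.frame with `marker_id`, `chrom`, `start`, `end`.
#' @param calls integer matrix (bins x lines) with values 0/1/2/NA.
#' @return A validated `DosageCalls` object.
#' @export
DosageCalls <- function(markers, calls) {
  rownames(markers) <- NULL
  storage.mode(calls) <- "integer"
  rownames(calls) <- markers$marker_id
  new("DosageCalls", markers = markers, calls = calls)
}

## ---------------------------------------------------------------------
## BinCoverage: raw per-bin read coverage (input to dosage calling).

setClass("BinCoverage",
  representation(bins = "data.frame", cov = "matrix"))

setValidity("BinCoverage", function(object) {
  ok <- checkMarkerFrame(object@bins)
  if (!isTRUE(ok)) return(ok)
  if (nrow(object@cov) != nrow(object@bins))
    return("cov must have one row per bin")
  if (any(object@cov < 0, na.rm = TRUE)) return("coverage must be >= 0")
  TRUE
})

setMethod("show", "BinCoverage", function(object) {
  cat(sprintf("BinCoverage: %d bin(s) x %d line(s), mean %.1f reads/bin\n",
              nrow(object@cov), ncol(object@cov), mean(object@cov)))
})

## ---------------------------------------------------------------------
## CommonMarkers: the unified per-line triple (Pd hap, Pn hap, dosage).

setClass("CommonMarkers",
  representation(markers = "data.frame", pd = "matrix", pn = "matrix",
                 dose = "matrix"))

setValidity("CommonMarkers", function(object) {
  ok <- checkMarkerFrame(object@markers)
  if (!isTRUE(ok)) return(ok)
  dims <- list(dim(object@pd), dim(object@pn), dim(object@dose))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    return("pd, pn and dose must have identical dimensions")
  if (nrow(object@pd) != nrow(object@markers))
    return("matrices must have one row per marker")
  for (m in list(object@pd, object@pn, object@dose))
    if (!identical(rownames(m), object@markers$marker_id))
      return("rownames must equal markers$marker_id")
  vd <- object@pd[!is.na(object@pd)]
  if (length(vd) && !all(vd %in% c("D1", "D2"))) return("pd must be D1/D2/NA")
  vn <- object@pn[!is.na(object@pn)]
  if (length(vn) && !all(vn %in% c("N1", "N2"))) return("pn must be N1/N2/NA")
  vo <- object@dose[!is.na(object@dose)]
  if (length(vo) && !all(vo %in% 0:2)) return("dose must be 0/1/2/NA")
  bad <- !is.na(object@dose) & object@dose == 0 & !is.na(object@pn)
  if (any(bad))
    return("deleted regions (dose 0) must carry no Pn haplotype (pn NA)")
  TRUE
})

setMethod("show", "CommonMarkers", function(object) {
  cat(sprintf("CommonMarkers: %d marker(s) x %d line(s)\n",
              nrow(object@pd), ncol(object@pd)))
  cat(sprintf("  NA%%: Pd %.1f, Pn %.1f, dose %.1f; dose 0/2 cells: %d/%d\n",
              100 * mean(is.na(object@pd)), 100 * mean(is.na(object@pn)),
              100 * mean(is.na(object@dose)),
              sum(object@dose == 0, na.rm = TRUE),
              sum(object@dose == 2, na.rm = TRUE)))
})

#' Construct a CommonMarkers object
#'
#' The container couples, for every line at every marker, the inherited
#' *P. deltoides* haplotype (D1/D2), the inherited *P. nigra* haplotype
#' (N1/N2) and the *P. nigra* copy number (0/1/2).  Its validity method
#' enforces the structural rule that a deleted paternal segment carries
#' no haplotype: `dose == 0` forces `pn` to be `NA`.
#'
#' @param markers data.frame with `marker_id`, `chrom`, `start`, `end`.
#' @param pd,pn character matrices (markers x lines).
#' @param dose integer matrix (markers x lines), values 0/1/2/NA.
#' @return A validated `CommonMarkers` object.
#' @export
CommonMarkers <- function(markers, pd, pn, dose) {
  if (!"snp_count" %in% names(markers)) markers$snp_count <- NA_integer_
  rownames(markers) <- NULL
  storage.mode(dose) <- "integer"
  rownames(pd) <- rownames(pn) <- rownames(dose) <- markers$marker_id
  new("CommonMarkers", markers = markers, pd = pd, pn = pn, dose = dose)
}

## ---------------------------------------------------------------------
## QtlScan: result of one single-channel scan (stats + thresholds + QTLs).

setClass("QtlScan",
  representation(trait = "character", channel = "character",
                 stats = "data.frame", t95 = "numeric", t99 = "numeric",
                 maxima = "numeric", qtls = "data.frame"))

setMethod("show", "QtlScan", function(object) {
  cat(sprintf("QtlScan: trait '%s', channel %s\n", object@trait, object@channel))
  cat(sprintf("  %d marker(s) tested, thresholds |t| > %.3f (5%%) / %.3f (1%%)\n",
              sum(!is.na(object@stats$t)), object@t95, object@t99))
  cat(sprintf("  %d QTL(s): %s\n", nrow(object@qtls),
              if (nrow(object@qtls)) paste(object@qtls$peak_marker, collapse = ", ")
              else "none"))
})

## ---------------------------------------------------------------------
## Accessor generics.

#' Marker annotation of a container
#' @param x a duoQTL container.
#' @return data.frame of marker annotation.
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' Line (sample) identifiers of a container
#' @param x a duoQTL container.
#' @return character vector of line ids.
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' Genotype/coverage call matrix of a single-channel container
#' @param x a duoQTL container.
#' @return the markers x lines matrix.
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' Focal parent of a container
#' @param x a duoQTL container.
#' @return `"Pd"` or `"Pn"`.
#' @export
setGeneric("focalParent", function(x) standardGeneric("focalParent"))

#' @describeIn markerInfo markers of binned genotypes
#' @export
setMethod("markerInfo", "BinnedGenotypes", function(x) x@markers)
#' @describeIn markerInfo dosage bins
#' @export
setMethod("markerInfo", "DosageCalls", function(x) x@markers)
#' @describeIn markerInfo coverage bins
#' @export
setMethod("markerInfo", "BinCoverage", function(x) x@bins)
#' @describeIn markerInfo common marker list
#' @export
setMethod("markerInfo", "CommonMarkers", function(x) x@markers)

#' @describeIn lineIds lines of binned genotypes
#' @export
setMethod("lineIds", "BinnedGenotypes", function(x) colnames(x@calls))
#' @describeIn lineIds lines of dosage calls
#' @export
setMethod("lineIds", "DosageCalls", function(x) colnames(x@calls))
#' @describeIn lineIds lines of bin coverage
#' @export
setMethod("lineIds", "BinCoverage", function(x) colnames(x@cov))
#' @describeIn lineIds lines of the common marker table
#' @export
setMethod("lineIds", "CommonMarkers", function(x) colnames(x@pd))
#' @describeIn lineIds lines of the population
#' @export
setMethod("lineIds", "F1Population", function(x) x@lines)

#' @describeIn calls haplotype calls
#' @export
setMethod("calls", "BinnedGenotypes", function(x) x@calls)
#' @describeIn calls dosage calls
#' @export
setMethod("calls", "DosageCalls", function(x) x@calls)
#' @describeIn calls raw coverage
#' @export
setMethod("calls", "BinCoverage", function(x) x@cov)

#' @describeIn focalParent of binned genotypes
#' @export
setMethod("focalParent", "BinnedGenotypes", function(x) x@focalParent)
#' @describeIn focalParent of phased haplotypes
#' @export
setMethod("focalParent", "PhasedHaplotypes", function(x) x@focalParent)

#' Channel matrices of a CommonMarkers table
#'
#' @param x a `CommonMarkers` object.
#' @return the markers x lines matrix for the requested channel.
#' @export
pdCalls <- function(x) x@pd

#' @rdname pdCalls
#' @export
pnCalls <- function(x) x@pn

#' @rdname pdCalls
#' @export
doseCalls <- function(x) x@dose
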