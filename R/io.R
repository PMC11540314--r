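## On-disk dialects.
##
## Genotype/count/marker tables are tab-separated; phenotypes are CSV.
## All genomic positions are 1-based and intervals are inclusive on both
## ends (marker ids Chr01_1_10000, Chr01_20000_30000, ...).  Missing
## values are serialized as the literal string "NA".  Every table written
## by the package starts with a '#' comment naming the package version
## and, when supplied, the seed that produced it.

ioHeader <- function(class, ...) {
  extra <- list(...)
  extra <- extra[!vapply(extra, is.null, TRUE)]
  kv <- if (length(extra))
    paste(sprintf("%s=%s", names(extra), unlist(extra)), collapse = " ")
  else ""
  sprintf("# duoQTL %s class=%s %s",
          as.character(packageVersion("duoQTL")), class, kv)
}

parseIoHeader <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) return(list())
  toks <- strsplit(trimws(sub("^#", "", first)), "\\s+")[[1]]
  kv <- grep("=", toks, value = TRUE)
  out <- strsplit(kv, "=", fixed = TRUE)
  setNames(lapply(out, `[`, 2), vapply(out, `[`, "", 1))
}

## ---------------------------------------------------------------------
## Allele counts: line_id, chrom, pos, A, C, G, T.

#' Read a parsed allele-count table
#'
#' Reads a tab-separated table of per-line, per-site nucleotide read
#' counts (the parsed-mpileup abstraction).  Structural problems
#' (missing columns, unparseable counts) are errors; rows violating row
#' invariants (pos < 1, negative counts, duplicated keys) are rejected
#' and reported with their file line numbers, never silently dropped.
#'
#' @param path file path; header must be
#'   `line_id  chrom  pos  A  C  G  T`.
#' @return data.frame of accepted records, with attribute `rejected`
#'   (data.frame of rejected rows and `file_line`/`reason`).
#' @export
readAlleleCounts <- function(path) {
  stopifNot1(file.exists(path), "file not found: %s", path)
  x <- read.delim(path, comment.char = "#", colClasses = "character",
                  check.names = FALSE)
  need <- c("line_id", "chrom", "pos", "A", "C", "G", "T")
  miss <- setdiff(need, names(x))
  stopifNot1(length(miss) == 0,
             "allele-count table is missing column(s): %s",
             paste(miss, collapse = ", "))
  x <- x[, need]
  ## file line number of each data row (header + any leading comment)
  nCom <- 0L
  con <- file(path, "r"); on.exit(close(con))
  while (startsWith(ln <- readLines(con, n = 1L), "#")) nCom <- nCom + 1L
  fline <- seq_len(nrow(x)) + nCom + 1L

  for (cc in c("pos", BASES)) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    bad <- which(is.na(v) | v != floor(v))
    stopifNot1(length(bad) == 0,
               "non-integer value in column '%s' (file line %s)",
               cc, paste(fline[bad], collapse = ", "))
    x[[cc]] <- as.integer(v)
  }
  reason <- rep(NA_character_, nrow(x))
  reason[x$pos < 1] <- "pos must be >= 1 (1-based)"
  neg <- rowSums(as.matrix(x[, BASES]) < 0) > 0
  reason[is.na(reason) & neg] <- "negative count"
  key <- paste(x$line_id, x$chrom, x$pos)
  reason[is.na(reason) & duplicated(key)] <- "duplicated (line_id, chrom, pos)"

  ok <- is.na(reason)
  rejected <- cbind(x[!ok, , drop = FALSE],
                    file_line = fline[!ok], reason = reason[!ok])
  rownames(rejected) <- NULL
  if (nrow(rejected))
    warning(sprintf("%d malformed row(s) rejected (see attr 'rejected')",
                    nrow(rejected)), call. = FALSE)
  out <- x[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a parsed allele-count table
#' @param x data.frame with columns line_id, chrom, pos, A, C, G, T.
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
writeAlleleCounts <- function(x, path, seed = NULL) {
  writeLines(ioHeader("AlleleCounts", seed = seed), path)
  suppressWarnings(write.table(
    x[, c("line_id", "chrom", "pos", BASES)], path, sep = "\t",
    quote = FALSE, row.names = FALSE, na = "NA", append = TRUE))
  invisible(path)
}

## ---------------------------------------------------------------------
## Phenotypes: CSV, first column line_id, one column per trait.

#' Read a phenotype table
#'
#' CSV with first column `line_id` and one numeric column per trait;
#' empty cells are missing values.
#'
#' @param path file path.
#' @return data.frame with `line_id` plus numeric trait columns.
#' @export
readPhenotypes <- function(path) {
  stopifNot1(file.exists(path), "file not found: %s", path)
  x <- read.csv(path, comment.char = "#", colClasses = "character",
                check.names = FALSE)
  stopifNot1(names(x)[1] == "line_id",
             "first column of a phenotype table must be 'line_id'")
  dup <- unique(x$line_id[duplicated(x$line_id)])
  stopifNot1(length(dup) == 0, "duplicated line_id: %s",
             paste(dup, collapse = ", "))
  stopifNot1(!anyDuplicated(names(x)), "trait names must be unique")
  for (j in seq_along(x)[-1]) {
    v <- x[[j]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    stopifNot1(length(bad) == 0,
               "non-numeric phenotype value '%s' at line_id=%s, trait=%s",
               if (length(bad)) v[bad[1]] else "", x$line_id[bad[1]],
               names(x)[j])
    x[[j]] <- num
  }
  x
}

#' Write a phenotype table
#' @param x data.frame with `line_id` plus numeric trait columns.
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(x, path, seed = NULL) {
  writeLines(ioHeader("Phenotypes", seed = seed), path)
  suppressWarnings(write.table(x, path, sep = ",", quote = FALSE,
                               row.names = FALSE, na = "", append = TRUE))
  invisible(path)
}

## ---------------------------------------------------------------------
## Marker tables (BinnedGenotypes / DosageCalls / CommonMarkers).

markerFrameOut <- function(mk) {
  mk$marker_id <- markerId(mk$chrom, mk$start, mk$end)
  if (!"snp_count" %in% names(mk)) mk$snp_count <- NA_integer_
  mk[, c("marker_id", "chrom", "start", "end", "snp_count")]
}

writeMarkerBody <- function(mk, cells, path, class, ...) {
  writeLines(ioHeader(class, ...), path)
  out <- cbind(markerFrameOut(mk), as.data.frame(cells, check.names = FALSE))
  suppressWarnings(write.table(out, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA", append = TRUE))
  invisible(path)
}

#' Write a marker table
#'
#' Serializes a marker-by-line container as a tab-separated table:
#' columns `marker_id` (Chr_start_end), `chrom`, `start`, `end`,
#' `snp_count`, then one column per line.  `CommonMarkers` cells hold
#' the triple `pd|pn|dose` with missing components as `NA`.
#' `readMarkerTable(writeMarkerTable(x))` reproduces `x`.
#'
#' @param x a `BinnedGenotypes`, `DosageCalls` or `CommonMarkers` object.
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
setGeneric("writeMarkerTable",
           function(x, path, seed = NULL) standardGeneric("writeMarkerTable"))

#' @describeIn writeMarkerTable binned haplotype genotypes
#' @export
setMethod("writeMarkerTable", "BinnedGenotypes", function(x, path, seed = NULL) {
  writeMarkerBody(x@markers, x@calls, path, "BinnedGenotypes",
                  focal = x@focalParent, seed = seed)
})

#' @describeIn writeMarkerTable dosage genotypes
#' @export
setMethod("writeMarkerTable", "DosageCalls", function(x, path, seed = NULL) {
  writeMarkerBody(x@markers, x@calls, path, "DosageCalls", seed = seed)
})

#' @describeIn writeMarkerTable the unified three-channel table
#' @export
setMethod("writeMarkerTable", "CommonMarkers", function(x, path, seed = NULL) {
  d <- ifelse(is.na(x@dose), "NA", as.character(x@dose))
  cells <- matrix(paste(ifelse(is.na(x@pd), "NA", x@pd),
                        ifelse(is.na(x@pn), "NA", x@pn), d, sep = "|"),
                  nrow = nrow(x@pd), dimnames = dimnames(x@pd))
  writeMarkerBody(x@markers, cells, path, "CommonMarkers", seed = seed)
})

#' Read a marker table written by [writeMarkerTable()]
#'
#' @param path file path; the class is recovered from the header comment.
#' @return a `BinnedGenotypes`, `DosageCalls` or `CommonMarkers` object.
#' @export
readMarkerTable <- function(path) {
  stopifNot1(file.exists(path), "file not found: %s", path)
  hdr <- parseIoHeader(path)
  cls <- hdr[["class"]]
  stopifNot1(!is.null(cls) &&
               cls %in% c("BinnedGenotypes", "DosageCalls", "CommonMarkers"),
             "not a duoQTL marker table (missing/unknown class header): %s",
             path)
  x <- read.delim(path, comment.char = "#", check.names = FALSE,
                  colClasses = "character")
  fixed <- c("marker_id", "chrom", "start", "end", "snp_count")
  stopifNot1(all(fixed %in% names(x)), "marker table missing fixed columns")
  mk <- data.frame(marker_id = x$marker_id, chrom = x$chrom,
                   start = as.integer(x$start), end = as.integer(x$end),
                   snp_count = as.integer(x$snp_count),
                   stringsAsFactors = FALSE)
  lineCols <- setdiff(names(x), fixed)
  cells <- as.matrix(x[, lineCols, drop = FALSE])
  rownames(cells) <- mk$marker_id
  if (cls == "BinnedGenotypes") {
    BinnedGenotypes(hdr[["focal"]], mk, cells)
  } else if (cls == "DosageCalls") {
    storage.mode(cells) <- "integer"
    DosageCalls(mk[, setdiff(names(mk), "snp_count")], cells)
  } else {
    parts <- strsplit(as.vector(cells), "|", fixed = TRUE)
    getp <- function(i) {
      v <- vapply(parts, `[`, "", i)
      v[v == "NA"] <- NA_character_
      matrix(v, nrow = nrow(cells), dimnames = dimnames(cells))
    }
    pd <- getp(1); pn <- getp(2)
    dose <- getp(3); storage.mode(dose) <- "integer"
    CommonMarkers(mk, pd, pn, dose)
  }
}

## ---------------------------------------------------------------------
## QTL result tables.

qtlResultCols <- c("trait", "channel_or_group", "chrom", "start_marker",
                   "end_marker", "peak_marker", "peak_stat", "threshold",
                   "significance", "variance_explained")

#' Write / read a QTL result table
#'
#' Tab-separated, one row per QTL: trait, channel (or combined-model
#' group), chromosome, first/last/peak member marker, peak statistic,
#' the significance threshold it beat, significance level, and the
#' adjusted-R^2 variance explained.  An empty QTL set writes a
#' header-only file.
#'
#' @param x data.frame of QTL results.
#' @param path file path.
#' @param seed optional seed recorded in the header comment.
#' @return `path` (write) or the data.frame (read).
#' @export
writeQtlResults <- function(x, path, seed = NULL) {
  miss <- setdiff(qtlResultCols, names(x))
  stopifNot1(length(miss) == 0, "QTL table missing column(s): %s",
             paste(miss, collapse = ", "))
  writeLines(ioHeader("QtlResults", seed = seed), path)
  suppressWarnings(write.table(x[, qtlResultCols], path, sep = "\t",
                               quote = FALSE, row.names = FALSE, na = "NA",
                               append = TRUE))
  invisible(path)
}

#' @rdname writeQtlResults
#' @export
readQtlResults <- function(path) {
  stopifNot1(file.exists(path), "file not found: %s", path)
  x <- read.delim(path, comment.char = "#", check.names = FALSE,
                  colClasses = "character")
  stopifNot1(all(qtlResultCols %in% names(x)),
             "not a duoQTL QTL result table: %s", path)
  for (cc in c("peak_stat", "threshold", "variance_explained"))
    x[[cc]] <- as.numeric(x[[cc]])
  rownames(x) <- NULL
  x
}
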