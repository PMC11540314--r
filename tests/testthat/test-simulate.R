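test_that("same seed and parameters reproduce every simulated object", {
  p1 <- simulateParents(nChrom = 2, chromLen = 2e5, seed = 5)
  p2 <- simulateParents(nChrom = 2, chromLen = 2e5, seed = 5)
  expect_identical(p1@sites, p2@sites)

  f1 <- simulateF1(p1, nLines = 10, indelSizeRange = c(5e4, 1e5), seed = 6)
  f2 <- simulateF1(p1, nLines = 10, indelSizeRange = c(5e4, 1e5), seed = 6)
  expect_identical(f1@inheritance, f2@inheritance)
  expect_identical(f1@indels, f2@indels)

  c1 <- simulateAlleleCounts(p1, f1, meanDepth = 2, seed = 7)
  c2 <- simulateAlleleCounts(p1, f1, meanDepth = 2, seed = 7)
  expect_identical(c1, c2)

  b1 <- simulateBinCoverage(f1, binSize = 5e4, seed = 8)
  b2 <- simulateBinCoverage(f1, binSize = 5e4, seed = 8)
  expect_identical(calls(b1), calls(b2))

  q <- data.frame(trait = "t", chrom = "Chr01", start = 1e4, end = 2e4,
                  channel = "Pd", effect = 1)
  ph1 <- simulatePhenotypes(f1, q, seed = 9)
  ph2 <- simulatePhenotypes(f1, q, seed = 9)
  expect_identical(ph1, ph2)
})

test_that("heterozygous-site counts concentrate at the requested density", {
  p <- simulateParents(nChrom = 1, chromLen = 1e6, hetDensity = 1e-3,
                       seed = 11)
  nHet <- sum(p@sites$pd1 != p@sites$pd2)
  expect_lt(abs(nHet - 1000), 4 * sqrt(1000))
  nHetPn <- sum(p@sites$pn1 != p@sites$pn2)
  expect_lt(abs(nHetPn - 1000), 4 * sqrt(1000))
  ## all joint site classes occur
  het <- function(a, b) a != b
  s <- p@sites
  expect_true(any(het(s$pd1, s$pd2) & !het(s$pn1, s$pn2)))
  expect_true(any(het(s$pd1, s$pd2) & het(s$pn1, s$pn2) &
                    paste(pmin(s$pd1, s$pd2), pmax(s$pd1, s$pd2)) ==
                      paste(pmin(s$pn1, s$pn2), pmax(s$pn1, s$pn2))))
  expect_true(any(het(s$pd1, s$pd2) & het(s$pn1, s$pn2) &
                    paste(pmin(s$pd1, s$pd2), pmax(s$pd1, s$pd2)) !=
                      paste(pmin(s$pn1, s$pn2), pmax(s$pn1, s$pn2))))
})

test_that("karyotype and parameter validation", {
  p <- simulateParents(nChrom = 19, chromLen = 1e5, hetDensity = 1e-4,
                       seed = 3)
  expect_equal(nrow(p@chroms), 19)
  expect_error(simulateParents(nChrom = 0), "nChrom")
  expect_error(simulateParents(hetDensity = 0), "hetDensity")
  expect_error(simulateF1(fxParents, nLines = 0), "nLines")
  expect_error(simulateF1(fxParents, indelSizeRange = c(1e9, 2e9)),
               "indelSizeRange")
})

test_that("meiosis structure: zero recombination and zero indels", {
  pop <- simulateF1(fxParents, nLines = 12, recombPerChrom = 0,
                    indelRate = 0, seed = 13)
  expect_equal(nrow(pop@indels), 0)
  ## each line x parent x chromosome is one whole-chromosome block
  n <- nrow(pop@inheritance)
  expect_equal(n, 12 * 2 * 2)
  expect_true(all(pop@inheritance$start == 1))
})

test_that("deletion/insertion mix matches the configured fraction", {
  p <- simulateParents(nChrom = 2, chromLen = 2e6, hetDensity = 5e-5,
                       seed = 21)
  pop <- simulateF1(p, nLines = 500, recombPerChrom = 0, indelRate = 20,
                    indelSizeRange = c(1e4, 2e4), pDeletion = 0.665,
                    seed = 22)
  expect_gt(nrow(pop@indels), 9000)
  frac <- mean(pop@indels$kind == "deletion")
  expect_lt(abs(frac - 0.665), 0.02)
  ## indels never overlap within a line
  bad <- vapply(split(pop@indels, pop@indels$line), function(d) {
    any(vapply(unique(d$chrom), function(ch) {
      s <- d[d$chrom == ch, ]
      s <- s[order(s$start), ]
      nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])
    }, TRUE))
  }, TRUE)
  expect_false(any(bad))
})

test_that("read conservation: error-free reads only show true alleles", {
  pop <- simulateF1(fxParents, nLines = 6, seed = 31)
  cnt <- simulateAlleleCounts(fxParents, pop, meanDepth = 4,
                              errorRate = 0, seed = 32)
  s <- fxParents@sites
  key <- paste(s$chrom, s$pos)
  idx <- match(paste(cnt$chrom, cnt$pos), key)
  ok <- vapply(seq_len(nrow(cnt)), function(i) {
    li <- cnt$line_id[i]
    al <- duoQTL:::lineAllelesAt(fxParents, pop, li)
    seen <- c("A", "C", "G", "T")[which(unlist(cnt[i, c("A", "C", "G", "T")]) > 0)]
    truth <- c(al$pd[idx[i]], al$pn[idx[i]])
    all(seen %in% truth[!is.na(truth)])
  }, TRUE)
  expect_true(all(ok))
})

test_that("mean depth tracks the Poisson rate, halved inside deletions", {
  pop0 <- simulateF1(fxParents, nLines = 30, indelRate = 0, seed = 41)
  cnt <- simulateAlleleCounts(fxParents, pop0, meanDepth = 0.5,
                              seed = 42, dropZero = FALSE)
  obs <- mean(rowSums(cnt[, c("A", "C", "G", "T")]))
  expect_lt(abs(obs - 0.5) / 0.5, 0.1)

  ## one hand-planted deletion: depth halves inside it
  ind <- data.frame(line = pop0@lines[1], chrom = "Chr01",
                    start = 1L, end = 250000L, kind = "deletion",
                    stringsAsFactors = FALSE)
  popDel <- new("F1Population", lines = pop0@lines, chroms = pop0@chroms,
                inheritance = pop0@inheritance, indels = ind)
  cnt2 <- simulateAlleleCounts(fxParents, popDel, lines = pop0@lines[1],
                               meanDepth = 8, seed = 43, dropZero = FALSE)
  inside <- cnt2$chrom == "Chr01" & cnt2$pos <= 250000
  dIn <- mean(rowSums(cnt2[inside, c("A", "C", "G", "T")]))
  dOut <- mean(rowSums(cnt2[!inside, c("A", "C", "G", "T")]))
  expect_lt(abs(dIn - 4) / 4, 0.15)
  expect_lt(abs(dOut - 8) / 8, 0.15)
})

test_that("bin coverage follows copy number: euploid, deletion, insertion", {
  pop0 <- simulateF1(fxParents, nLines = 20, indelRate = 0, seed = 51)
  ind <- data.frame(line = rep(pop0@lines[1:2], each = 1),
                    chrom = "Chr01",
                    start = c(100001L, 300001L), end = c(200000L, 400000L),
                    kind = c("deletion", "insertion"),
                    stringsAsFactors = FALSE)
  pop <- new("F1Population", lines = pop0@lines, chroms = pop0@chroms,
             inheritance = pop0@inheritance, indels = ind)
  cov <- simulateBinCoverage(pop, binSize = 25000, meanCov = 400, seed = 52)
  cv <- calls(cov); bins <- markerInfo(cov)
  mid <- (bins$start + bins$end) %/% 2
  delBins <- bins$chrom == "Chr01" & mid > 100000 & mid <= 200000
  insBins <- bins$chrom == "Chr01" & mid > 300000 & mid <= 400000
  expect_equal(sum(delBins), 4)       # a deletion occupying 4 bins
  l1 <- pop0@lines[1]; l2 <- pop0@lines[2]
  expect_lt(abs(mean(cv[delBins, l1]) - 200) / 200, 0.15)
  expect_lt(abs(mean(cv[insBins, l2]) - 600) / 600, 0.15)
  euploid <- mean(cv[, -(1:2)])
  expect_lt(abs(euploid - 400) / 400, 0.05)
})

test_that("phenotype forward model: noise-free effects are exact", {
  pop0 <- simulateF1(fxParents, nLines = 25, indelRate = 0, seed = 61)
  ind <- data.frame(line = pop0@lines[1:5], chrom = "Chr02",
                    start = 100001L, end = 300000L, kind = "deletion",
                    stringsAsFactors = FALSE)
  pop <- new("F1Population", lines = pop0@lines, chroms = pop0@chroms,
             inheritance = pop0@inheritance, indels = ind)
  q <- data.frame(trait = "t", chrom = "Chr02", start = 150000,
                  end = 250000, channel = "dosage", effect = 2)
  ph <- simulatePhenotypes(pop, q, beta0 = 10, noiseSd = 0, seed = 62)
  expect_equal(unname(ph$t[1:5]), rep(10, 5))         # deleted: 0 copies
  expect_equal(unname(ph$t[6:25]), rep(12, 20))       # regular: 1 copy
  expect_error(
    simulatePhenotypes(pop, data.frame(trait = "t", chrom = "Chr09",
                                       start = 1, end = 10,
                                       channel = "Pd", effect = 1)),
    "outside")
})

test_that("null traits are pure noise and OLS recovers a planted slope", {
  pop <- simulateF1(fxParents, nLines = 343, seed = 71)
  q <- data.frame(trait = "t", chrom = "Chr01", start = 240000,
                  end = 260000, channel = "Pd", effect = 1)
  ph <- simulatePhenotypes(pop, q, noiseSd = 1, nullTraits = "n0",
                           seed = 72)
  expect_lt(abs(mean(ph$n0)), 0.2)
  expect_lt(abs(sd(ph$n0) - 1), 0.15)
  g <- genotypeCodeAt(pop, "Chr01", 250000, "Pd")
  fit <- fitSingleMarker(ph$t, g)
  se <- fit$residual_sd / (sd(g) * sqrt(fit$n_used - 1))
  expect_lt(abs(fit$beta1 - 1), 3 * se)
})

test_that("dosage truth is recoverable from the indel list", {
  cop <- truePnCopiesAt(fxPop, "Chr01", c(1e5, 3e5))
  ind <- fxPop@indels[fxPop@indels$chrom == "Chr01", ]
  for (li in rownames(cop)) {
    hit <- ind[ind$line == li & ind$start <= 1e5 & ind$end >= 1e5, ]
    want <- if (nrow(hit) == 0) 1L else
      if (hit$kind[1] == "deletion") 0L else 2L
    expect_identical(unname(cop[li, 1]), want)
  }
})
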