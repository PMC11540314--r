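snpRow <- function(pos, a1, a2, o1, o2, chrom = "Chr01") {
  structure(data.frame(chrom = chrom, pos = pos, a1 = a1, a2 = a2,
                       o1 = o1, o2 = o2, stringsAsFactors = FALSE),
            focalParent = "Pd")
}

cntRow <- function(line, pos, A = 0, C = 0, G = 0, T = 0, chrom = "Chr01") {
  data.frame(line_id = line, chrom = chrom, pos = pos, A = A, C = C,
             G = G, T = T, stringsAsFactors = FALSE)
}

test_that("consistency threshold reproduces the 109-of-122 rule", {
  expect_identical(consistencyThreshold(122), 109L)
  expect_identical(consistencyThreshold(120), 108L)
  expect_identical(consistencyThreshold(10, 0.9), 9L)
})

test_that("inherited-allele inference: depth gate and allele subtraction", {
  snps <- snpRow(100, "A", "G", "A", "A")
  ## depth 19 -> below the 20x gate, missing
  m <- inferInheritedAlleles(cntRow("L1", 100, A = 10, G = 9), snps)
  expect_true(is.na(m["L1", "Chr01:100"]))
  ## 12xA + 9xG: G can only come from the focal G haplotype
  m <- inferInheritedAlleles(cntRow("L1", 100, A = 12, G = 9), snps)
  expect_identical(unname(m["L1", "Chr01:100"]), "G")
  ## all-A at depth 21: the inherited focal allele must be A
  m <- inferInheritedAlleles(cntRow("L1", 100, A = 21), snps)
  expect_identical(unname(m["L1", "Chr01:100"]), "A")
  ## both focal alleles present where the other parent is C/C: impossible
  snps2 <- snpRow(100, "A", "G", "C", "C")
  m <- inferInheritedAlleles(cntRow("L1", 100, A = 12, G = 9, C = 11), snps2)
  expect_true(is.na(m["L1", "Chr01:100"]))
  ## het-vs-different-het: reads {G, C} identify focal G
  snps3 <- snpRow(100, "A", "G", "A", "C")
  m <- inferInheritedAlleles(cntRow("L1", 100, G = 12, C = 10), snps3)
  expect_identical(unname(m["L1", "Chr01:100"]), "G")
  ## replicate rows for one line are pooled before calling
  reps <- rbind(cntRow("L1", 100, A = 7, G = 5), cntRow("L1", 100, A = 5, G = 4))
  m <- inferInheritedAlleles(reps, snps)
  expect_identical(unname(m["L1", "Chr01:100"]), "G")
})

test_that("an exact 50/50 orientation split breaks the block", {
  snps <- rbind(snpRow(100, "A", "G", "C", "C"),
                snpRow(200, "A", "T", "C", "C"))
  lines <- sprintf("L%03d", 1:122)
  m <- matrix(NA_character_, 122, 2,
              dimnames = list(lines, c("Chr01:100", "Chr01:200")))
  m[1:61, ] <- rep(c("A", "A"), each = 61)    # 61 cis votes
  m[62:122, 1] <- "A"; m[62:122, 2] <- "T"    # 61 trans votes
  r <- phaseChromosome(m, snps, "Chr01")
  expect_false(r$links$accepted[1])
  expect_equal(r$haplotypes$block, c(1, 2))
})

test_that("noise-free deep data recovers true link orientations and blocks", {
  pop <- simulateF1(fxParents, nLines = 40, recombPerChrom = 1,
                    indelRate = 0, seed = 301)
  cnt <- simulateAlleleCounts(fxParents, pop, meanDepth = 40,
                              errorRate = 0, seed = 302)
  m <- inferInheritedAlleles(cnt, fxInfoPd, depthMin = 20)
  ph <- phaseHaplotypes(m, fxInfoPd, minLines = 10)
  lk <- ph@links[ph@links$accepted, ]
  truth <- trueLinkOrientation(fxParents, fxInfoPd)
  key <- paste(lk$chrom, lk$pos1, lk$pos2)
  tkey <- paste(truth$chrom, truth$pos1, truth$pos2)
  expect_true(all(lk$orientation == truth$orientation[match(key, tkey)]))
  ## phased blocks reproduce the true haplotypes up to a per-block swap
  s <- fxParents@sites
  i <- match(paste(ph@haplotypes$chrom, ph@haplotypes$pos),
             paste(s$chrom, s$pos))
  for (b in split(seq_len(nrow(ph@haplotypes)),
                  paste(ph@haplotypes$chrom, ph@haplotypes$block))) {
    same <- ph@haplotypes$hap1[b] == s$pd1[i[b]]
    expect_true(all(same) || all(!same))
  }
})

test_that("phasing is invariant to relabeling the truth haplotypes", {
  ## swapping a1/a2 in the SNP table must not change which links are
  ## accepted, only the reported orientation of the swapped sites
  pop <- simulateF1(fxParents, nLines = 30, indelRate = 0, seed = 311)
  cnt <- simulateAlleleCounts(fxParents, pop, meanDepth = 40,
                              errorRate = 0, seed = 312)
  snps <- fxInfoPd[fxInfoPd$chrom == "Chr01", ][1:20, ]
  attr(snps, "focalParent") <- "Pd"
  m1 <- inferInheritedAlleles(cnt, snps, 20)
  r1 <- phaseChromosome(m1, snps, "Chr01", minLines = 5)
  snps2 <- snps
  flip <- seq(1, 20, by = 2)
  snps2$a1[flip] <- snps$a2[flip]; snps2$a2[flip] <- snps$a1[flip]
  m2 <- inferInheritedAlleles(cnt, snps2, 20)
  r2 <- phaseChromosome(m2, snps2, "Chr01", minLines = 5)
  expect_equal(r2$links$accepted, r1$links$accepted)
  expect_equal(r2$links$n, r1$links$n)
  expect_equal(r2$links$support, r1$links$support)
})

test_that("raising the consistency threshold never adds accepted links", {
  pop <- simulateF1(fxParents, nLines = 50, indelRate = 1, seed = 321)
  cnt <- simulateAlleleCounts(fxParents, pop, meanDepth = 25,
                              errorRate = 0.01, seed = 322)
  m <- inferInheritedAlleles(cnt, fxInfoPd, 20)
  nAcc <- vapply(c(0.6, 0.75, 0.9, 0.95, 1.0), function(cons) {
    sum(phaseHaplotypes(m, fxInfoPd, consistency = cons,
                        minLines = 5)@links$accepted)
  }, 0)
  expect_true(all(diff(nAcc) <= 0))
})

test_that("a chromosome with a single informative SNP warns and stays unphased", {
  snps <- snpRow(100, "A", "G", "C", "C")
  m <- matrix("A", 5, 1, dimnames = list(paste0("L", 1:5), "Chr01:100"))
  expect_warning(r <- phaseChromosome(m, snps, "Chr01"), "single-site")
  expect_equal(nrow(r$haplotypes), 1)
  expect_equal(nrow(r$links), 0)
})
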