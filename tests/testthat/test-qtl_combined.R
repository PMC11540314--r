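test_that("the state universe closes at exactly 10 labels", {
  u <- enumerateStates()
  expect_length(u, 10)
  expect_false(anyDuplicated(u) > 0)
  expect_true("D1.N1.1" %in% u)
  expect_false("D1.N2.0" %in% u)          # dose 0 forces the Pn NA
  expect_true(all(c("D1.NA.0", "D2.NA.0") %in% u))
})

test_that("state assignment maps triples and missingness", {
  mk <- mkFrame("Chr01", c(1, 10001, 20001), c(10000, 20000, 30000))
  pd <- matrix(c("D1", "D2", NA), 3, 1, dimnames = list(mk$marker_id, "L1"))
  pn <- matrix(c("N1", NA, "N1"), 3, 1, dimnames = dimnames(pd))
  dose <- matrix(c(1L, 0L, 1L), 3, 1, dimnames = dimnames(pd))
  st <- assignStates(CommonMarkers(mk, pd, pn, dose))
  expect_identical(unname(st[, 1]), c("D1.N1.1", "D2.NA.0", NA))
})

test_that("every assigned state on random tables lies in the universe", {
  set.seed(90)
  u <- enumerateStates()
  for (i in 1:5) {
    st <- assignStates(randomCommonMarkers(8, 6))
    v <- st[!is.na(st)]
    expect_true(all(v %in% u))
    expect_lte(length(unique(v)), 10)
  }
})

test_that("pairwise tests: comparison count law and degenerate groups", {
  set.seed(91)
  u <- enumerateStates()
  states <- rep(u, each = 8)
  y <- rnorm(length(states))
  pt <- pairwiseStateTests(y, states, nPerm = 60, minGroup = 5, seed = 1)
  expect_equal(nrow(pt), choose(10, 2))   # all states present -> 45
  expect_equal(nrow(pt), 45)

  states3 <- rep(c("D1.N1.1", "D1.N2.1", "D2.N1.1"), each = 6)
  pt3 <- pairwiseStateTests(rnorm(18), states3, nPerm = 60, minGroup = 5,
                            seed = 1)
  expect_equal(nrow(pt3), choose(3, 2))

  ## identical values in both groups: no permutation exceeds 0 -> p = 1
  ptc <- pairwiseStateTests(rep(2, 12), rep(c("D1.N1.1", "D2.N1.1"), 6),
                            nPerm = 50, minGroup = 5, seed = 1)
  expect_equal(ptc$p_raw, 1)

  ## below min_group: the pair is skipped
  states2 <- c(rep("D1.N1.1", 8), rep("D2.N1.1", 3))
  expect_equal(nrow(pairwiseStateTests(rnorm(11), states2, 50, 5, 1)), 0)
})

test_that("permutation p-values are valid and deterministic under a seed", {
  set.seed(92)
  y <- c(rnorm(20), rnorm(20) + 2)
  states <- rep(c("D1.N1.1", "D1.NA.0"), each = 20)
  p1 <- pairwiseStateTests(y, states, nPerm = 200, seed = 7)
  p2 <- pairwiseStateTests(y, states, nPerm = 200, seed = 7)
  expect_identical(p1, p2)
  expect_lt(p1$p_raw, 0.05)
  expect_gte(p1$p_raw, 1 / 201)           # add-one floor
})

test_that("the Monte-Carlo pair test matches exhaustive enumeration", {
  ## independent oracle: enumerate all C(n, n1) group splits
  exactP <- function(v1, v2) {
    v <- c(v1, v2); n1 <- length(v1)
    obs <- abs(mean(v1) - mean(v2))
    subs <- utils::combn(length(v), n1)
    stats <- apply(subs, 2, function(i) abs(mean(v[i]) - mean(v[-i])))
    mean(stats >= obs - 1e-12)
  }
  set.seed(94)
  for (i in 1:4) {
    v1 <- rnorm(4); v2 <- rnorm(5) + 1
    p_mc <- pairwiseStateTests(c(v1, v2),
                               rep(c("D1.N1.1", "D2.N1.1"), c(4, 5)),
                               nPerm = 4000, minGroup = 3, seed = i)$p_raw
    expect_lt(abs(p_mc - exactP(v1, v2)), 0.025)
  }
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(93)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    a <- bhAdjust(p)
    expect_equal(a, bhBruteForce(p), tolerance = 1e-12)
    expect_true(all(diff(a[order(p)]) >= -1e-15))   # monotone on sorted p
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("pair typing and QTL classification follow the six groups", {
  sp <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(state1 = m[, 1], state2 = m[, 2], stringsAsFactors = FALSE)
  }
  ## equal haplotypes, dose 0 vs 1 -> deletion
  expect_equal(classifyQtl(sp("D1.N1.1", "D1.NA.0")), "deletion")
  ## equal dose, both haplotypes differ, nothing else -> Pd + Pn
  expect_equal(classifyQtl(sp("D1.N1.1", "D2.N2.1")),
               "P. deltoides + P. nigra")
  ## one 0-vs-1 and one 1-vs-2 pair -> deletion+insertion
  expect_equal(classifyQtl(sp("D1.N1.1", "D1.NA.0",
                              "D1.N1.1", "D1.N1.2")), "deletion+insertion")
  expect_equal(classifyQtl(sp("D1.N1.1", "D1.N1.2")), "insertion")
  ## single-haplotype contrasts
  expect_equal(classifyQtl(sp("D1.N1.1", "D2.N1.1")), "P. deltoides")
  expect_equal(classifyQtl(sp("D1.N1.1", "D1.N2.1")), "P. nigra")
  ## parsimony: a Pd contrast plus a both-haplotype contrast is still Pd
  expect_equal(classifyQtl(sp("D1.N1.1", "D2.N1.1",
                              "D1.N1.1", "D2.N2.1")), "P. deltoides")
  ## Pd and Pn single contrasts together -> Pd + Pn
  expect_equal(classifyQtl(sp("D1.N1.1", "D2.N1.1",
                              "D1.N1.1", "D1.N2.1")),
               "P. deltoides + P. nigra")
  ## confounded-only evidence -> ambiguous
  expect_equal(classifyQtl(sp("D1.N1.1", "D2.NA.0")), "ambiguous")
  expect_equal(classifyQtl(sp("D1.NA.0", "D1.N1.2")), "ambiguous")
  ## dosage evidence outranks Pd-allelic evidence
  expect_equal(classifyQtl(sp("D1.N1.1", "D1.NA.0",
                              "D1.N1.1", "D2.N1.1")), "deletion")
  ## ... but direct Pn evidence explains away 0-vs-1 contrasts, since
  ## the dose-0 state is a mixture of both Pn haplotypes
  expect_equal(classifyQtl(sp("D1.N1.1", "D1.NA.0",
                              "D1.N1.1", "D1.N2.1")), "P. nigra")
  expect_length(qtlGroups(), 6)
})

test_that("combined scan recovers planted mechanisms on truth markers", {
  pop <- simulateF1(fxParents, nLines = 343, seed = 801)
  cmn <- truthCommonMarkers(fxParents, pop, binSize = 30)
  mk <- markerInfo(cmn)
  cases <- list(
    list(channel = "deletion", group = "deletion"),
    list(channel = "Pd", group = "P. deltoides"))
  for (cs in cases) {
    eff <- plantedEffect(pop, "Chr01", 25e4, cs$channel, 0.6)
    q <- data.frame(trait = "t", chrom = "Chr01", start = 2e5, end = 3e5,
                    channel = cs$channel, effect = eff)
    ph <- simulatePhenotypes(pop, q, seed = 802)
    res <- combinedScan(cmn, ph, "t", nPerm = 250, seed = 803)
    iv <- qtlIntervals(res$qtls, mk)
    hit <- which(iv$chrom == "Chr01" & iv$start <= 3e5 & iv$end >= 2e5)
    expect_gte(length(hit), 1)
    expect_true(cs$group %in% res$qtls$channel_or_group[hit])
  }
})

test_that("combined scan p-adjustment scopes and output structure", {
  pop <- simulateF1(fxParents, nLines = 120, seed = 811)
  cmn <- truthCommonMarkers(fxParents, pop, binSize = 40)
  ph <- simulatePhenotypes(pop, data.frame(trait = character(),
                                           chrom = character(),
                                           start = numeric(), end = numeric(),
                                           channel = character(),
                                           effect = numeric()),
                           nullTraits = "n0", seed = 812)
  r1 <- combinedScan(cmn, ph, "n0", nPerm = 80, seed = 813)
  expect_true(all(r1$pairs$p_adj >= r1$pairs$p_raw - 1e-12))
  expect_true(all(r1$pairs$p_adj <= 1))
  r2 <- combinedScan(cmn, ph, "n0", nPerm = 80, seed = 813,
                     bhScope = "per-marker-across-pairs")
  expect_identical(r1$pairs$p_raw, r2$pairs$p_raw)
  ## comparison count law: never more than C(10,2) pairs per marker
  cnt <- table(r1$pairs$marker)
  expect_true(all(cnt <= 45))
})
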