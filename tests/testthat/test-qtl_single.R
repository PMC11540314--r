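test_that("channel encoding follows the stated genotype codes", {
  mk <- mkFrame("Chr01", c(1, 10001, 20001), c(10000, 20000, 30000))
  pd <- matrix(c("D2", "D1", "D1"), 3, 1,
               dimnames = list(mk$marker_id, "L1"))
  pn <- matrix(c("N1", NA, "N2"), 3, 1, dimnames = dimnames(pd))
  dose <- matrix(c(1L, 0L, 2L), 3, 1, dimnames = dimnames(pd))
  cm <- CommonMarkers(mk, pd, pn, dose)
  expect_equal(unname(encodeChannel(cm, "Pd")[1, ]), c(1, 0, 0))
  expect_equal(unname(encodeChannel(cm, "Pn")[1, ]), c(0, NA, 1))
  expect_equal(unname(encodeChannel(cm, "dosage")[1, ]), c(1, 0, 2))
  expect_error(encodeChannel(cm, "species"))
})

test_that("single-marker OLS: exact fit, skip reasons", {
  g <- rep(0:1, each = 5)
  f <- fitSingleMarker(2 * g, g, minN = 5)
  expect_equal(f$beta1, 2)
  expect_equal(f$residual_sd, 0)
  expect_equal(f$n_used, 10)

  f2 <- fitSingleMarker(rnorm(10), rep(1, 10), minN = 5)
  expect_equal(f2$reason, "monomorphic")
  f3 <- fitSingleMarker(rnorm(10), 1:10, minN = 20)
  expect_equal(f3$reason, "insufficient data")
})

test_that("regression t equals the pooled two-sample t for binary markers", {
  set.seed(77)
  for (i in 1:25) {
    n1 <- sample(10:40, 1); n2 <- sample(10:40, 1)
    g <- c(rep(0, n1), rep(1, n2))
    y <- rnorm(n1 + n2) + 0.5 * g
    f <- fitSingleMarker(y, g, minN = 5)
    tt <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
    expect_equal(abs(f$t_value), abs(unname(tt$statistic)), tolerance = 1e-10)
    expect_equal(f$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("vectorized scan agrees with lm marker by marker", {
  set.seed(78)
  n <- 60; m <- 8
  G <- matrix(sample(c(0, 1, 2, NA), n * m, TRUE, prob = c(.4, .3, .2, .1)),
              n, m, dimnames = list(NULL, paste0("M", 1:m)))
  y <- rnorm(n) + 0.3 * ifelse(is.na(G[, 3]), 0, G[, 3])
  st <- scanMarkers(y, G, minN = 10, minMinor = 3)
  for (j in which(is.na(st$reason))) {
    fit <- summary(lm(y ~ G[, j]))
    expect_equal(st$t[j], fit$coefficients[2, "t value"], tolerance = 1e-10)
    expect_equal(st$p[j], fit$coefficients[2, "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("null p-values are uniform", {
  set.seed(79)
  p <- replicate(400, {
    g <- sample(0:1, 50, TRUE)
    fitSingleMarker(rnorm(50), g, minN = 10)$p_value
  })
  expect_lt(abs(mean(p) - 0.5), 0.05)
  expect_lt(abs(mean(p < 0.2) - 0.2), 0.07)
  expect_lt(abs(mean(p < 0.8) - 0.8), 0.07)
})

test_that("permutation thresholds are ordered, deterministic and seed-sensitive", {
  G <- encodeChannel(fxTruthCm, "Pd")
  y <- rnorm(nrow(G))
  t1 <- permutationThreshold(y, G, nPerm = 100, seed = 5, minN = 10,
                             minMinor = 3)
  t2 <- permutationThreshold(y, G, nPerm = 100, seed = 5, minN = 10,
                             minMinor = 3)
  t3 <- permutationThreshold(y, G, nPerm = 100, seed = 6, minN = 10,
                             minMinor = 3)
  expect_identical(t1, t2)
  expect_false(identical(t1$maxima, t3$maxima))
  expect_gte(t1$t99, t1$t95)
  ## missing phenotypes are dropped, not permuted into the scan
  y2 <- y; y2[1:10] <- NA
  t4 <- permutationThreshold(y2, G, nPerm = 50, seed = 5, minN = 10,
                             minMinor = 3)
  expect_true(all(is.finite(t4$maxima)))
})

test_that("adjacent significant markers merge into QTLs correctly", {
  mk <- rbind(mkFrame("Chr01", seq(1, by = 1e4, length.out = 4),
                      seq(1e4, by = 1e4, length.out = 4)),
              mkFrame("Chr02", seq(1, by = 1e4, length.out = 4),
                      seq(1e4, by = 1e4, length.out = 4)),
              mkFrame("Chr03", seq(1, by = 1e4, length.out = 2),
                      seq(1e4, by = 1e4, length.out = 2)))
  st <- data.frame(marker = mk$marker_id, n = 100,
                   t = c(1, 1, 1, 1,  3.5, 4.2, 3.6, 1,  3.4, 1))
  q <- callQtls(st, mk, t95 = 3.2, t99 = 4.0)
  expect_equal(nrow(q), 2)
  expect_equal(q$chrom, c("Chr02", "Chr03"))
  expect_equal(q$start_marker[1], mk$marker_id[5])
  expect_equal(q$end_marker[1], mk$marker_id[7])
  expect_equal(q$peak_marker[1], mk$marker_id[6])
  expect_equal(q$significance, c("confirmed", "significant"))
  expect_equal(q$members[[1]], mk$marker_id[5:7])
  ## a significant marker at a chromosome boundary never bridges
  st$t <- c(1, 1, 1, 3.5,  3.5, 1, 1, 1,  1, 1)
  q2 <- callQtls(st, mk, 3.2, 4.0)
  expect_equal(nrow(q2), 2)
})

test_that("variance explained: perfect fit, null predictor, collinearity", {
  set.seed(80)
  g <- sample(0:1, 200, TRUE)
  G <- cbind(m1 = g, m2 = g, m3 = sample(0:1, 200, TRUE))
  y <- g + 0          # noise-free
  expect_equal(suppressWarnings(varianceExplained(y, G, "m1")), 1)
  yN <- rnorm(200)
  expect_lt(abs(varianceExplained(yN, G, "m3")), 0.05)
  yx <- g + rnorm(200)
  expect_equal(varianceExplained(yx, G, c("m1", "m2")),
               varianceExplained(yx, G, "m1"))
})

test_that("qtlScan finds a strong planted QTL and reports its variance", {
  pop <- simulateF1(fxParents, nLines = 200, seed = 701)
  cmn <- truthCommonMarkers(fxParents, pop, binSize = 30)
  mk <- markerInfo(cmn)
  q <- data.frame(trait = "t", chrom = "Chr02", start = 2e5, end = 3e5,
                  channel = "Pd",
                  effect = plantedEffect(pop, "Chr02", 25e4, "Pd", 0.6))
  ph <- simulatePhenotypes(pop, q, seed = 702)
  sc <- qtlScan(cmn, ph, "t", "Pd", nPerm = 150, seed = 703,
                minN = 10, minMinor = 3)
  expect_gte(nrow(sc@qtls), 1)
  iv <- qtlIntervals(sc@qtls, mk)
  expect_true(any(iv$chrom == "Chr02" & iv$start <= 3e5 & iv$end >= 2e5))
  expect_true(all(sc@qtls$variance_explained > 0))
  expect_true(all(abs(sc@qtls$peak_stat) > sc@t95))
})
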