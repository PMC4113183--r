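test_that("regulation metrics reproduce the published worked examples", {
  # rno-miR-30d-5p, HA line: sham 9187, SNL 8140
  expect_equal(round(snlRegSubtraction(8140, 9187), 3), -0.121)
  expect_equal(round(foldChangeSigned(8140, 9187), 3), -1.129)
  # trivial anchors
  expect_equal(snlRegSubtraction(10, 10), 0)
  expect_equal(snlRegSubtraction(30, 10), 1)
  expect_equal(foldChangeSigned(20, 10), 2)
  expect_equal(foldChangeSigned(10, 10), 1)
  expect_true(is.na(snlRegSubtraction(0, 0)))
  expect_true(is.na(foldChangeSigned(0, 5)))
})

test_that("subtraction metric is bounded and antisymmetric; metrics agree in sign", {
  set.seed(14)
  snl <- rexp(300, 1 / 100)
  sham <- rexp(300, 1 / 100)
  s <- snlRegSubtraction(snl, sham)
  expect_true(all(s > -2 & s < 2))
  expect_equal(s, -snlRegSubtraction(sham, snl))
  f <- foldChangeSigned(snl, sham)
  l <- log2FoldRatio(snl, sham)
  expect_true(all(abs(f) >= 1))
  up <- s > 0
  expect_true(all(f[up] > 1 & l[up] > 0))
  expect_true(all(f[!up & s < 0] < 0 & l[!up & s < 0] < 0))
  # one-sided zero: subtraction tolerates it, reaches the +/-2 edge
  expect_equal(snlRegSubtraction(50, 0), 2)
  expect_equal(snlRegSubtraction(0, 50), -2)
})

test_that("BH q-values match hand computations and report the FDR limit", {
  expect_equal(bhFdr(0.123)$q, 0.123)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  expect_equal(bhFdr(c(0.005, 0.9))$q, c(0.01, 0.9))
  lim <- bhFdr(c(0.01, 0.2, 0.03, 0.9), alpha = 0.05)
  expect_equal(lim$limit, 0.01)     # p_(2) = 0.03 > 2*0.05/4; p_(1) passes
  expect_equal(bhFdr(c(0.9, 0.95))$limit, 0)
  expect_error(bhFdr(c(0.2, 1.2)), "0, 1")
})

test_that("BH q-values equal the step-up oracle on random inputs", {
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(bhFdr(p)$q, bhOracle(p))
  }
})

test_that("SNL-reg test is calibrated on ties and ranks spike-ins first", {
  d <- poolDesign()
  m <- matrix(100, 4, 12, dimnames = list(paste0("s", 1:4), d$pool))
  x <- SmallRNAExperiment(m, d, quantMode = "rpm_reads_level")
  sr <- snlRegTest(x, "HA")
  expect_true(all(sr$estimate == 0))
  expect_true(all(sr$p == 1))
  # spiked elements dominate the ranking at low dispersion
  spikes <- data.frame(element = 1:5, line = "HA", fold = 2)
  cfg <- syntheticConfig(nElements = 100, cv = 0.05, lineSd = 0,
                         abundanceSdlog = 1, injuryFraction = 0,
                         spikes = spikes, seed = 12)
  rpm <- abundanceFilter(toRPM(generateCounts(cfg)$experiment))
  res <- snlRegTest(rpm, "HA")
  top10 <- rownames(res)[order(res$p)][1:10]
  expect_true(all(paste0("el", sprintf("%03d", 1:5)) %in% top10))
  # the observed-direction one-tailed p is half the two-sided p
  expect_equal(res$pObserved, res$pTwoSided / 2, tolerance = 1e-9)
})

test_that("pairwise diff-reg reduces to the direct formula at zero variance", {
  means <- rbind(`rno-miR-30d-5p` = c(HA_sham = 9187, HA_SNL = 8140,
                                      LA_sham = 11047, LA_SNL = 11168))
  x <- groupMeanRPM(means)
  dr <- diffRegPairwise(x)
  expect_equal(dr["rno-miR-30d-5p", "meanHA"],
               snlRegSubtraction(8140, 9187))
  expect_equal(dr["rno-miR-30d-5p", "meanLA"],
               snlRegSubtraction(11168, 11047))
  expect_equal(round(dr["rno-miR-30d-5p", "diff"], 3), -0.132)
  expect_equal(dr["rno-miR-30d-5p", "sdHA"], 0)
  # property over random group means
  set.seed(77)
  for (i in 1:20) {
    mm <- rbind(el = setNames(rexp(4, 1 / 500) + 1,
                              c("HA_sham", "HA_SNL", "LA_sham", "LA_SNL")))
    dri <- diffRegPairwise(groupMeanRPM(mm))
    direct <- snlRegSubtraction(mm[, "HA_SNL"], mm[, "HA_sham"]) -
      snlRegSubtraction(mm[, "LA_SNL"], mm[, "LA_sham"])
    expect_equal(unname(dri[1, "diff"]), unname(direct), tolerance = 1e-12)
  }
})

test_that("pairwise estimates enumerate all SNL x sham pairs", {
  # HA SNL pools {10, 20}, sham {10, 10}: estimates {0, 0, 2/3, 2/3}
  d <- poolDesign(replicates = 2)
  m <- matrix(10, 1, 8, dimnames = list("el", d$pool))
  m[, "HA_SNL2"] <- 20
  x <- SmallRNAExperiment(m, d, quantMode = "rpm_reads_level")
  dr <- diffRegPairwise(x)
  expect_equal(dr["el", "nPairsHA"], 4L)
  expect_equal(dr["el", "meanHA"], 1 / 3)
  # the direct group-mean formula legitimately differs under variance
  expect_equal(snlRegSubtraction(15, 10), 0.4)
  # label swap flips the sign of diff
  swapped <- diffRegPairwise(x, lines = c("LA", "HA"))
  expect_equal(swapped["el", "diff"], -dr["el", "diff"])
})

test_that("permutation p-values match exact enumeration", {
  # identical sets: every split is as extreme as observed
  expect_equal(diffRegPermutation(c(1, 2, 3), c(1, 2, 3), exact = TRUE), 1)
  # fully separated 3+3 sets: the two extreme splits out of 20
  expect_equal(diffRegPermutation(c(0, 0, 0), c(1, 1, 1), exact = TRUE),
               2 / 20)
  set.seed(31)
  for (i in 1:10) {
    n <- sample(3:4, 1)
    e1 <- rnorm(n)
    e2 <- rnorm(n)
    expect_equal(diffRegPermutation(e1, e2, exact = TRUE),
                 permOracle(e1, e2))
  }
})

test_that("sampled permutation p converges to the exact value", {
  set.seed(55)
  e1 <- rnorm(4, 0.3)
  e2 <- rnorm(4)
  exact <- diffRegPermutation(e1, e2, exact = TRUE)
  sampled <- diffRegPermutation(e1, e2, nRuns = 1e4, seed = 99)
  mcSd <- sqrt(exact * (1 - exact) / 1e4)
  expect_lt(abs(sampled - exact), 3 * mcSd + 2 / 1e4)
  # determinism under fixed seed
  expect_identical(sampled, diffRegPermutation(e1, e2, nRuns = 1e4, seed = 99))
})

test_that("baseline comparison recovers a known fold difference", {
  d <- poolDesign()
  m <- matrix(100, 2, 12, dimnames = list(c("flat", "up"), d$pool))
  x <- SmallRNAExperiment(m, d, quantMode = "rpm_reads_level")
  bl0 <- baselineCompare(x)
  expect_equal(unname(bl0$ratio), c(1, 1))
  expect_equal(unname(bl0$p), c(1, 1))
  # 9.5-fold HA-over-LA baseline spike at moderate noise
  set.seed(18)
  m2 <- matrix(rlnorm(40 * 12, log(200), 0.15), 40, 12,
               dimnames = list(paste0("s", 1:40), d$pool))
  ha <- grepl("^HA_sham", colnames(m2))
  m2[1, ha] <- m2[1, ha] * 9.5
  bl <- baselineCompare(SmallRNAExperiment(m2, d,
                                           quantMode = "rpm_reads_level"))
  expect_equal(unname(bl$ratio[1]), 9.5, tolerance = 0.35)
  expect_identical(rownames(bl)[which.min(bl$p)], "s1")
})

test_that("diff-reg output supports a finite volcano export", {
  cfg <- syntheticConfig(nElements = 120, seed = 23)
  rpm <- abundanceFilter(toRPM(generateCounts(cfg)$experiment))
  dr <- diffRegPairwise(rpm)
  ok <- !is.na(dr$p)
  expect_true(all(is.finite(dr$diff[ok])))
  expect_true(all(is.finite(-log10(pmax(dr$q[ok], 1e-300)))))
})

test_that("log2 metric floors one-sided zeros instead of dropping them", {
  expect_equal(log2FoldRatio(8, 0), log2(8 / 0.5))
  expect_true(is.na(log2FoldRatio(0, 0)))
  d <- poolDesign()
  m <- matrix(50, 1, 12, dimnames = list("el", d$pool))
  x <- SmallRNAExperiment(m, d, quantMode = "rpm_reads_level")
  dr <- diffRegPairwise(x, metric = "log2")
  expect_equal(dr["el", "diff"], 0)
})
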