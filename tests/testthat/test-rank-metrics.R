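test_that("mean reciprocal rank averages inverse first-active ranks", {
  expect_equal(meanReciprocalRank(c(1, 1, 1)), 1)
  expect_equal(meanReciprocalRank(c(2, 4)), 0.375)
  expect_equal(meanReciprocalRank(c(1, NA)), 0.5)  # 'none' contributes 0
  expect_error(meanReciprocalRank(c(0, 2)), "positive")
  ## Monte-Carlo over uniform first-active ranks vs the exact average
  set.seed(8)
  N <- 100
  draws <- sample.int(N, 1000, replace = TRUE)
  exact <- mean(1 / seq_len(N))
  expect_equal(meanReciprocalRank(draws), exact,
               tolerance = 5 * stats::sd(1 / draws) / sqrt(1000) / exact)
})

test_that("precision at K and average precision match brute-force counting", {
  expect_equal(precisionAtK(c(1, 0, 1, 0), 2), 0.5)
  rel <- relFromRanks(c(2, 5, 9), 12)
  expect_equal(precisionAtK(rel, 12), 3 / 12)
  expect_error(precisionAtK(rel, 0), "k must be")
  expect_error(precisionAtK(rel, 13), "k must be")
  set.seed(3)
  for (i in 1:20) {
    rel <- rbinom(15, 1, 0.4)
    k <- sample(15, 1)
    expect_equal(precisionAtK(rel, k), sum(rel[1:k]) / k)
  }

  expect_equal(averagePrecision(c(1, 1, 0)), 1)
  expect_equal(averagePrecision(c(0, 1)), 0.5)
  expect_equal(averagePrecision(c(1, 0, 1)), (1 + 2 / 3) / 2)
  expect_error(averagePrecision(c(0, 0)), "no actives")
  expect_equal(meanAveragePrecision(list(c(1, 1, 0), c(0, 1))), 0.75)
})

test_that("enrichment factor hits its bounds and has random expectation 1", {
  ranks <- c(1:5, 40, 50, 60, 70, 80)   # 5 of 10 actives in the top 10
  expect_equal(enrichmentFactor(ranks, N = 100, fraction = 0.1), 5)
  expect_equal(enrichmentFactor(1:10, N = 100, fraction = 0.1), 10) # N/n
  expect_error(enrichmentFactor(1:2, N = 100, fraction = 0.005), "k = 0")
  set.seed(14)
  efs <- replicate(2000, enrichmentFactor(randomActiveRanks(100, 10),
                                          N = 100, fraction = 0.1))
  expect_lt(abs(mean(efs) - 1), 3 * stats::sd(efs) / sqrt(2000))
})

test_that("RIE matches direct summation and has unit random expectation", {
  ## independent hand evaluation at N = 10, n = 1, active at rank 1
  num <- exp(-20 * 1 / 10)
  den <- (1 / 10) * (1 - exp(-20)) / (exp(20 / 10) - 1)
  expect_equal(rie(1, N = 10, alpha = 20), num / den)
  ## all actives at the very top equals RIE_max computed by the same sum
  n <- 10; N <- 100; alpha <- 20
  rmax <- mean(exp(-alpha * (1:n) / N)) /
    ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  expect_equal(rie(1:n, N, alpha), rmax)
  set.seed(15)
  ries <- replicate(2000, rie(randomActiveRanks(100, 10), 100, 20))
  expect_lt(abs(mean(ries) - 1), 3 * stats::sd(ries) / sqrt(2000))
  expect_error(rie(integer(0), 10), "at least one active")
  expect_error(rie(1:10, 10), "inactive")
})

test_that("BEDROC is the min-max normalization of RIE onto [0, 1]", {
  expect_equal(suppressWarnings(bedroc(1:10, 100, 20)), 1)
  expect_equal(suppressWarnings(bedroc(91:100, 100, 20)), 0)
  expect_warning(bedroc(1:10, 50, 20), "alpha \\* Ra")
  expect_silent(b <- bedroc(c(3, 70), 500, 20))
  expect_true(b > 0 && b < 1)
  ## mean over random rankings ~ (1 - RIE_min)/(RIE_max - RIE_min), via E(RIE)=1
  n <- 10; N <- 100; alpha <- 20
  den <- (1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  rmax <- mean(exp(-alpha * (1:n) / N)) / den
  rmin <- mean(exp(-alpha * (N - n + 1:n) / N)) / den
  expected <- (1 - rmin) / (rmax - rmin)
  set.seed(16)
  bs <- replicate(2000,
                  suppressWarnings(bedroc(randomActiveRanks(N, n), N, alpha)))
  expect_lt(abs(mean(bs) - expected), 3 * stats::sd(bs) / sqrt(2000))
})

test_that("rank-formula AUROC plus discrete correction equals the pairwise statistic", {
  expect_equal(aurocRankFormula(c(1, 2), 10), 0.9375)
  expect_equal(aurocRankFormula(c(1, 2), 10, correction = "discrete"), 1)
  ## actives at uniform quantiles sit near 0.5
  expect_equal(aurocRankFormula(c(25, 50, 75), 100, "discrete"),
               pairwiseAurocOracle(c(25, 50, 75), 100))
  set.seed(17)
  for (i in 1:200) {
    N <- sample(20:400, 1)
    n <- sample.int(N - 1, 1)
    r <- randomActiveRanks(N, n)
    expect_equal(aurocRankFormula(r, N, correction = "discrete"),
                 pairwiseAurocOracle(r, N), tolerance = 1e-12)
  }
})

test_that("DCG/IDCG/NDCG follow the log2 discount and normalize to [0, 1]", {
  expect_equal(dcg(c(1, 0, 0), 1), 1)
  expect_equal(ndcg(c(1, 0, 0), 1), 1)
  expect_equal(dcg(c(1, 0, 1), 3), 1 + 1 / log2(4))
  expect_equal(idcg(c(1, 0, 1), 3), 1 + 1 / log2(3))
  expect_equal(ndcg(c(1, 0, 1), 3),
               (1 + 1 / log2(4)) / (1 + 1 / log2(3)))
  ## actives filling the top ranks give exactly 1 at any depth
  for (p in c(1, 3, 5, 8))
    expect_equal(ndcg(c(1, 1, 1, 0, 0, 0, 0, 0), p), 1)
  expect_equal(ndcg(c(0, 0, 0), 2), 0)   # no actives -> defined as 0
  expect_error(dcg(c(1, 0), 3), "p must be")
  expect_error(dcg(c(1, -1), 1), "non-negative")
  ## graded relevance: gains are 2^rel - 1
  expect_equal(dcg(c(3, 2, 0), 2), 7 / log2(2) + 3 / log2(3))
  expect_equal(ndcg(c(2, 3, 0), 3),
               (3 + 7 / log2(3)) / (7 + 3 / log2(3)))
})

test_that("metrics ignore permutations of inactives and respect their bounds", {
  set.seed(18)
  for (i in 1:25) {
    N <- sample(20:60, 1)
    n <- sample.int(10, 1)
    r <- randomActiveRanks(N, n)
    rel <- relFromRanks(r, N)
    expect_true(averagePrecision(rel) >= 0 && averagePrecision(rel) <= 1)
    expect_true(suppressWarnings(bedroc(r, N)) >= 0 &&
                  suppressWarnings(bedroc(r, N)) <= 1)
    k <- sample.int(N, 1)
    expect_true(ndcg(rel, k) >= 0 && ndcg(rel, k) <= 1)
    ef <- enrichmentFactor(r, N, fraction = 0.25)
    expect_true(ef >= 0 && ef <= N / n)
    ## all rank-based metrics depend only on the active ranks, so any
    ## relabeling of inactive positions leaves them unchanged
    expect_equal(activeRanks(rel), r)
  }
})
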