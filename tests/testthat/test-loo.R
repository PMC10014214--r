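rankingFromOrder <- function(query, ordered_ids) {
  new("NeighborRanking", query = query, rankedDrugs = ordered_ids,
      distances = seq_along(ordered_ids) / 100)
}

test_that("bestActiveRank finds the first active and signals 'none' as NA", {
  rk <- rankingFromOrder("q", c("a", "b", "c"))
  expect_equal(bestActiveRank(rk, "b"), 2L)
  expect_equal(bestActiveRank(rk, character(0)), NA_integer_)
  expect_equal(bestActiveRank(rk, "not-there"), NA_integer_)
  expect_error(bestActiveRank(rk, c("q", "b")), "query")

  ## exhaustive position-scan oracle on a random 100-drug ranking
  set.seed(21)
  ids <- sprintf("d%03d", 1:100)
  ordered <- sample(ids)
  actives <- sample(ids, 5)
  rk2 <- rankingFromOrder("query", ordered)
  scan <- min(vapply(actives, function(a) which(ordered == a), integer(1)))
  expect_equal(bestActiveRank(rk2, actives), scan)
})

test_that("indicationAccuracy computes hit percentages, incl. the 23/58 worked case", {
  ranks58 <- c(rep(3L, 23), rep(40L, 35))      # 23 of 58 hit within top 10
  acc <- indicationAccuracy(ranks58, cutoff = 10)
  expect_equal(acc, 100 * 23 / 58)
  expect_equal(round(acc, 1), 39.7)            # prints as 39.6-39.7 at 1 dp
  expect_lt(abs(acc - 39.6), 0.1)
  expect_equal(indicationAccuracy(c(1, 2, 5), 5), 100)
  expect_equal(indicationAccuracy(c(11, NA, 20), 10), 0)
  expect_error(indicationAccuracy(c(1, 2), 0), "cutoff")
  expect_error(indicationAccuracy(integer(0), 5), "non-empty")
})

test_that("runLooBenchmark averages indications unweighted and handles perfect similarity", {
  ## geometry: indication A = 4 drugs in 2 tight pairs (accuracy 100%),
  ## indication B = 2 drugs far apart with >5 decoys in between (0%)
  x <- c(a1 = 0, a2 = 0.001, a3 = 50, a4 = 50.001,
         b1 = 1000, b2 = 5000,
         dec1 = 1000.01, dec2 = 1000.02, dec3 = 1000.03, dec4 = 1000.04,
         dec5 = 1000.05, dec6 = 1000.06)
  sig <- SignatureMatrix(cbind(x, 0), drug_ids = names(x),
                         protein_ids = c("p1", "p2"))
  std <- AssociationStandard(
    c("a1", "a2", "a3", "a4", "b1", "b2"),
    c("iA", "iA", "iA", "iA", "iB", "iB"),
    drugs = names(x))
  res <- runLooBenchmark(std, pairwiseDistances(sig),
                         BenchmarkConfig(cutoffs = c(5L)))
  acc <- perIndication(res)
  expect_equal(acc$accuracy[acc$indication_id == "iA"], 100)
  expect_equal(acc$accuracy[acc$indication_id == "iB"], 0)
  expect_equal(aia(res)$aia, 50)    # unweighted mean of 100 and 0

  ## identical signatures within every indication -> AIA 100 at cutoff 1
  sig2 <- SignatureMatrix(
    rbind(d1 = c(0, 0), d2 = c(0, 0), d3 = c(9, 9), d4 = c(9, 9)),
    protein_ids = c("p1", "p2"))
  std2 <- AssociationStandard(c("d1", "d2", "d3", "d4"),
                              c("i1", "i1", "i2", "i2"))
  res2 <- runLooBenchmark(std2, pairwiseDistances(sig2),
                          BenchmarkConfig(cutoffs = c(1L, 2L)))
  expect_equal(aia(res2)$aia, c(100, 100))
})

test_that("AIA is monotone in cutoff, bounded, and errors on missing drugs", {
  dat <- smallSynthetic(seed = 13, signal = 1)
  res <- runLooBenchmark(dat$standard, dat$sim,
                         BenchmarkConfig(cutoffs = c(2L, 5L, 10L, 20L)))
  v <- aia(res)$aia
  expect_false(is.unsorted(v))
  expect_true(all(v >= 0 & v <= 100))
  acc <- perIndication(res)
  for (ind in unique(acc$indication_id))
    expect_false(is.unsorted(acc$accuracy[acc$indication_id == ind]))

  bad <- AssociationStandard(c("ghost", "d1"), c("iX", "iX"))
  expect_error(runLooBenchmark(bad, dat$sim, BenchmarkConfig(cutoffs = 5L)),
               "ghost")
})

test_that("size-1 indications are excluded without disturbing other indications", {
  set.seed(5)
  sim <- randomSim(30)
  ids <- drugIds(sim)
  std_with <- AssociationStandard(
    c(ids[1:6], ids[10]),
    c(rep("iA", 3), rep("iB", 3), "single"),
    drugs = ids)
  std_without <- AssociationStandard(
    ids[1:6], c(rep("iA", 3), rep("iB", 3)), drugs = ids)
  cfg <- BenchmarkConfig(cutoffs = c(3L, 8L))
  r1 <- runLooBenchmark(std_with, sim, cfg)
  r2 <- runLooBenchmark(std_without, sim, cfg)
  expect_false("single" %in% perIndication(r1)$indication_id)
  expect_equal(perIndication(r1), perIndication(r2))
  expect_equal(aia(r1), aia(r2))
})

test_that("shuffled-similarity AIA agrees with the hypergeometric null", {
  set.seed(77)
  ids <- sprintf("d%03d", 1:200)
  std <- AssociationStandard(
    drug_id = as.vector(vapply(1:20, function(i)
      sample(ids, 5), character(5))),
    indication_id = rep(sprintf("i%02d", 1:20), each = 5),
    drugs = ids)
  base <- randomSim(200, ids = ids)
  cfg <- BenchmarkConfig(cutoffs = c(10L, 25L))
  R <- 30
  aias <- matrix(NA_real_, R, 2)
  for (r in seq_len(R)) {
    simR <- shuffleSimilarities(base, seed = 1000 + r)
    aias[r, ] <- aia(runLooBenchmark(std, simR, cfg))$aia
  }
  for (j in 1:2) {
    k <- c(10L, 25L)[j]
    theo <- expectedRandomAia(std, k)
    se <- stats::sd(aias[, j]) / sqrt(R)
    expect_lt(abs(mean(aias[, j]) - theo), 3 * se + 0.5)
  }
})
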