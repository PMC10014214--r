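## exhaustive oracle: P(at least one of n actives in the top k) by
## enumerating every placement of the active set among N positions
enumHitProbability <- function(N, n, k) {
  sets <- utils::combn(N, n)
  mean(apply(sets, 2, function(s) min(s) <= k))
}

test_that("hypergeometric hit probability matches enumeration and phyper", {
  expect_equal(hypergeomHitProbability(10, 3, 10), 1)
  expect_equal(hypergeomHitProbability(4, 1, 2), 0.5)
  expect_equal(hypergeomHitProbability(4, 0, 2), 0)
  expect_error(hypergeomHitProbability(4, 1, 5), "k must be")
  for (N in 4:8) for (n in 1:(N - 1)) for (k in 1:N) {
    expect_equal(hypergeomHitProbability(N, n, k),
                 enumHitProbability(N, n, k), tolerance = 1e-12)
  }
  ## independent cross-check via the hypergeometric distribution function
  expect_equal(hypergeomHitProbability(2161, 5, 10),
               1 - stats::dhyper(0, 5, 2156, 10), tolerance = 1e-12)
})

test_that("hypergeometric closed form matches Monte-Carlo position sampling", {
  set.seed(41)
  N <- 2161; n <- 5; k <- 10
  hits <- replicate(1e5, min(sample.int(N, n)) <= k)
  p <- hypergeomHitProbability(N, n, k)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(mean(hits) - p), 3 * se)
})

test_that("expected random AIA averages per-indication hit probabilities", {
  ## one indication of 2 drugs among 5: candidate list 4, 1 active, top 2
  std <- AssociationStandard(c("d1", "d2"), c("i1", "i1"),
                             drugs = sprintf("d%d", 1:5))
  expect_equal(expectedRandomAia(std, 2), 50)
  ## k = nDrugs - 1 makes a hit certain for every size-2 indication
  std2 <- AssociationStandard(c("a", "b", "c", "d"),
                              c("i1", "i1", "i2", "i2"))
  expect_equal(expectedRandomAia(std2, 3), 100)
  ## size-1 indications are excluded, matching the benchmark
  std3 <- AssociationStandard(c("a", "b", "c"), c("i1", "i1", "solo"))
  expect_equal(expectedRandomAia(std3, 1),
               100 * hypergeomHitProbability(2, 1, 1))
  expect_error(expectedRandomAia(std3, 1, minIndicationSize = 4),
               "no indication")
})

test_that("shuffling preserves the distance distribution but not structure", {
  set.seed(42)
  base <- randomSim(40)
  sh <- shuffleSimilarities(base, seed = 9)
  expect_s4_class(sh, "SimilarityMatrix")
  up <- upper.tri(distances(base))
  expect_equal(sort(distances(sh)[up]), sort(distances(base)[up]))
  expect_false(identical(distances(sh), distances(base)))
  ## deterministic given the seed
  expect_identical(distances(shuffleSimilarities(base, seed = 9)),
                   distances(sh))
})

test_that("null controls are reproducible and center where theory says", {
  set.seed(43)
  ids <- sprintf("d%03d", 1:60)
  std <- AssociationStandard(
    drug_id = as.vector(vapply(1:10, function(i) sample(ids, 4),
                               character(4))),
    indication_id = rep(sprintf("i%02d", 1:10), each = 4),
    drugs = ids)
  cfg <- BenchmarkConfig(cutoffs = c(5L, 10L))
  spec <- NullSpec("uniform_rankings", replicates = 25L, seed = 7L)
  r1 <- runNullControl(std, cfg, spec,
                       metrics = c("indication_accuracy", "AUROC", "NDCG"))
  r2 <- runNullControl(std, cfg, spec,
                       metrics = c("indication_accuracy", "AUROC", "NDCG"))
  expect_identical(aggregated(r1), aggregated(r2))   # same seed, same bits

  agg <- aggregated(r1)
  auroc <- agg$mean[agg$metric == "AUROC" & agg$level == "pair"]
  expect_lt(abs(auroc - 0.5), 0.02)
  aiaRows <- agg[agg$metric == "AIA", ]
  for (r in seq_len(nrow(aiaRows))) {
    theo <- expectedRandomAia(std, aiaRows$cutoff[r])
    expect_lt(abs(aiaRows$mean[r] - theo), 5)
  }
})

test_that("null NDCG and BEDROC fall below planted-signal values", {
  dat <- smallSynthetic(seed = 19, signal = 3)
  cfg <- BenchmarkConfig(cutoffs = c(5L, 10L))
  planted <- suppressWarnings(
    runMetricSuite(dat$standard, dat$sim, cfg, metrics = c("NDCG", "BEDROC")))
  nullRep <- suppressWarnings(
    runNullControl(dat$standard, cfg,
                   NullSpec("shuffle_similarities", replicates = 10L,
                            seed = 5L),
                   sim = dat$sim, metrics = c("NDCG", "BEDROC")))
  pa <- aggregated(planted); na <- aggregated(nullRep)
  for (lvl in c("indication", "pair")) {
    for (metric in c("NDCG", "BEDROC")) {
      p <- pa$mean[pa$metric == metric & pa$level == lvl]
      q <- na$mean[na$metric == metric & na$level == lvl]
      expect_true(all(p > q))
    }
  }
})
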