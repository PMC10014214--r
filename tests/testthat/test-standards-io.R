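test_that("association standards parse, deduplicate and report counts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "d1\ti1", "d2\ti1", "d1\ti2"), f)
  std <- readAssociationStandard(f)
  expect_s4_class(std, "AssociationStandard")
  expect_equal(nDrugs(std), 2L)
  expect_equal(nIndications(std), 2L)
  expect_equal(nAssociations(std), 3L)
  expect_equal(sort(indicationDrugs(std, "i1")), c("d1", "d2"))

  writeLines(c("d1\ti1", "d1\ti1"), f)
  expect_message(std2 <- readAssociationStandard(f), "1 duplicate")
  expect_equal(nAssociations(std2), 1L)

  writeLines(c("d1\ti1", "lonely-field"), f)
  expect_error(readAssociationStandard(f), "line\\(s\\).*2")
  writeLines(character(0), f)
  expect_error(readAssociationStandard(f), "empty")
})

test_that("cardinality bookkeeping: association count equals summed indication sizes", {
  dat <- smallSynthetic(seed = 11)
  std <- dat$standard
  expect_equal(sum(indicationSizes(std)), nAssociations(std))
  ## duplicates in input never inflate counts
  a <- associations(std)
  expect_message(
    dup <- AssociationStandard(c(a$drug_id, a$drug_id[1]),
                               c(a$indication_id, a$indication_id[1])),
    "1 duplicate")
  expect_equal(nAssociations(dup), nAssociations(std))
})

test_that("a full-scale synthetic standard round-trips through write/read", {
  spec <- SyntheticSpec(seed = 5)   # 2162 drugs, 2178 indications, 18709 pairs
  std <- generateStandard(spec)
  expect_equal(nAssociations(std), 18709L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAssociationStandard(std, f)
  back <- readAssociationStandard(f)
  expect_equal(associations(back)[order(associations(back)$drug_id,
                                        associations(back)$indication_id), ],
               associations(std)[order(associations(std)$drug_id,
                                       associations(std)$indication_id), ],
               ignore_attr = TRUE)
  expect_equal(sort(indicationIds(back)), sort(indicationIds(std)))
})

test_that("signature matrices read, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tp1\tp2\tp3",
               "d1\t0.5\t1\t-2",
               "d2\t0\t3.25\t4"), f)
  sig <- readSignatureMatrix(f)
  expect_equal(drugIds(sig), c("d1", "d2"))
  expect_equal(proteinIds(sig), c("p1", "p2", "p3"))
  expect_equal(scores(sig)["d2", "p2"], 3.25)

  writeLines(c("drug_id\tp1\tp2", "d1\t0.5", "d2\t1\t2"), f)
  expect_error(readSignatureMatrix(f), "ragged.*d1")
  writeLines(c("drug_id\tp1\tp2", "d1\t0.5\toops"), f)
  expect_error(readSignatureMatrix(f), "non-numeric.*d1")

  set.seed(42)
  m <- matrix(rnorm(100 * 50), 100, 50,
              dimnames = list(sprintf("d%03d", 1:100),
                              sprintf("p%02d", 1:50)))
  sig2 <- SignatureMatrix(m)
  writeSignatureMatrix(sig2, f)
  back <- readSignatureMatrix(f)
  expect_equal(scores(back), scores(sig2), tolerance = 1e-12)
})

test_that("metric reports round-trip through JSON and export to TSV", {
  empty <- MetricReport()
  f <- withr::local_tempfile(fileext = ".json")
  writeMetricReport(empty, f, "json")
  back <- readMetricReport(f)
  expect_equal(nrow(perIndication(back)), 0L)

  one <- MetricReport(
    perIndication = data.frame(indication_id = "D000001",
                               metric = "indication_accuracy",
                               cutoff = 10L, value = 39.65517,
                               stringsAsFactors = FALSE),
    aggregate = data.frame(metric = "indication_accuracy", cutoff = 10L,
                           level = "indication", mean = 39.65517,
                           median = 39.65517, q25 = 39.65517,
                           q75 = 39.65517, stringsAsFactors = FALSE))
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  writeMetricReport(one, ftsv, "tsv")
  lines <- readLines(ftsv)
  expect_length(grep("^per_indication\t", lines), 1L)

  dat <- smallSynthetic(seed = 7)
  rep1 <- suppressWarnings(
    runMetricSuite(dat$standard, dat$sim, BenchmarkConfig(cutoffs = c(5, 10))))
  writeMetricReport(rep1, f, "json")
  back <- readMetricReport(f)
  expect_equal(perIndication(back), perIndication(rep1), tolerance = 1e-12)
  expect_equal(aggregated(back), aggregated(rep1), tolerance = 1e-12)
})
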