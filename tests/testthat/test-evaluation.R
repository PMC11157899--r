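test_that("classWeights is the prevalence complement", {
  expect_equal(classWeights(c(1L, 2L), 2L), c(0.5, 0.5))
  expect_equal(classWeights(c(1L, 1L, 1L, 2L), 2L), c(0.25, 0.75))
  expect_equal(classWeights(c(2L, 2L), 2L), c(1, 0))
  expect_error(classWeights(integer(0), 2L), "empty")
})

test_that("weightedAccuracy matches hand computations and identities", {
  # all correct with >= 2 gold classes: exactly 1
  expect_equal(weightedAccuracy(c(1, 2, 1), c(1, 2, 1), 2), 1)
  # gold AAAB, pred AABB: weights (0.25, 0.75) -> 1.25 / 1.5
  expect_equal(weightedAccuracy(c(1, 1, 1, 2), c(1, 1, 2, 2), 2),
               1.25 / 1.5, tolerance = 1e-12)
  # equal prevalence: equals unweighted accuracy for any predictions
  set.seed(7)
  gold <- rep(1:2, 20)
  pred <- sample(1:2, 40, replace = TRUE)
  expect_equal(weightedAccuracy(gold, pred, 2),
               unweightedAccuracy(gold, pred), tolerance = 1e-12)
  # single-class gold degenerates to unweighted accuracy, flagged
  wa <- weightedAccuracy(c(1, 1), c(1, 2), 2)
  expect_equal(as.numeric(wa), 0.5)
  expect_match(attr(wa, "degenerate"), "single-class")
  # majority-default predictions score lower weighted than unweighted
  gold <- c(rep(1L, 18), 2L, 3L)
  pred <- rep(1L, 20)
  expect_lt(weightedAccuracy(gold, pred, 3),
            unweightedAccuracy(gold, pred))
})

test_that("unweightedAccuracy is the exact-match fraction", {
  expect_equal(unweightedAccuracy(c(1, 2, 1, 2), c(1, 2, 1, 1)), 0.75)
  expect_equal(unweightedAccuracy(c(1, 1), c(2, 2)), 0)
})

test_that("microF1 pools counts over non-default classes", {
  # gold [neg, def, unc, def], pred [neg, unc, def, def] with default = 1
  gold <- c(2L, 1L, 3L, 1L); pred <- c(2L, 3L, 1L, 1L)
  expect_equal(microF1(gold, pred, 3L, defaultClass = 1L), 0.5)
  # perfect with >= 1 non-default gold
  expect_equal(microF1(c(1, 2), c(1, 2), 2L, 1L), 1)
  # all-default gold and pred: flagged undefined, not zero
  out <- microF1(c(1, 1), c(1, 1), 2L, 1L)
  expect_true(is.na(out))
  expect_match(attr(out, "note"), "no non-default")
  # excluded class drops out of the pooled counts
  expect_equal(microF1(gold, pred, 3L, 1L, exclude = 3L), 1)
})

test_that("macroF1 averages per-class F1 with equal weight", {
  expect_equal(macroF1(c(1, 2, 1, 2), c(1, 2, 1, 2), 2L, 1L), 1)
  # gold [0,0,1,1], pred [0,0,0,0]: F1 = (2/3 + 0)/2
  expect_equal(macroF1(c(1, 1, 2, 2), c(1, 1, 1, 1), 2L, 1L),
               mean(c(2 / 3, 0)), tolerance = 1e-12)
  # include/exclude default changes the class set by exactly one
  gold <- c(1L, 2L, 3L, 1L); pred <- c(1L, 2L, 3L, 3L)
  withDef <- macroF1(gold, pred, 3L, 1L, includeDefault = TRUE)
  noDef <- macroF1(gold, pred, 3L, 1L, includeDefault = FALSE)
  expect_false(isTRUE(all.equal(withDef, noDef)))
  # classes absent from gold and pred are skipped with a note
  out <- macroF1(c(1, 1), c(1, 1), 3L, 1L)
  expect_match(attr(out, "note"), "skipped")
})

test_that("chiSquareCompare is the closed-form Pearson 2x2 statistic", {
  r <- chiSquareCompare(50, 50, 50, 50)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  r <- chiSquareCompare(90, 10, 80, 20)
  expect_equal(r$statistic,
               200 * (90 * 20 - 10 * 80)^2 / (170 * 30 * 100 * 100),
               tolerance = 1e-9)
  # symmetric in the two systems
  expect_equal(chiSquareCompare(80, 20, 90, 10)$statistic, r$statistic)
  # zero column total is an error
  expect_error(chiSquareCompare(0, 10, 0, 20), "zero row or column")
  # counts reconstructed from accuracy and N
  expect_identical(unname(countsFromAccuracy(0.9, 100)), c(90, 10))
})

test_that("metrics equal their brute-force counterparts on random sets", {
  set.seed(123)
  for (rep in 1:200) {
    C <- sample(2:5, 1)
    n <- sample(2:50, 1)
    gold <- sample.int(C, n, replace = TRUE)
    pred <- sample.int(C, n, replace = TRUE)
    dflt <- sample.int(C, 1)
    expect_equal(unweightedAccuracy(gold, pred),
                 naiveUnweightedAcc(gold, pred), tolerance = 1e-9)
    expect_equal(as.numeric(weightedAccuracy(gold, pred, C)),
                 naiveWeightedAcc(gold, pred, C), tolerance = 1e-9)
    expect_equal(as.numeric(microF1(gold, pred, C, dflt)),
                 naiveMicroF1(gold, pred, C, dflt), tolerance = 1e-9)
    expect_equal(as.numeric(macroF1(gold, pred, C, dflt)),
                 naiveMacroF1(gold, pred, C, dflt), tolerance = 1e-9)
  }
})

test_that("evaluatePredictions aligns, reports and skips undefined cells", {
  sch <- tinySchema()
  gold <- cbind(c(1L, 1L, 2L, 1L), c(1L, 1L, 1L, 1L))
  ex <- madeExamples(sch, gold)

  # perfect predictions: every defined metric is 1
  rep1 <- evaluatePredictions(ex, matrix(gold, ncol = 2,
                                         dimnames = list(NULL,
                                                         modifiers(ex))))
  pm <- metricsPerModifier(rep1)
  expect_equal(pm$unweighted_accuracy, c(1, 1))
  expect_equal(pm$micro_f1[1], 1)
  # severity is all-default: its micro F1 is NA and skipped in the average
  expect_true(is.na(pm$micro_f1[2]))
  expect_equal(metricsAverages(rep1)[["micro_f1"]], 1)
  expect_match(paste(rep1@notes, collapse = " "), "severity")

  # predict-default baseline: unweighted accuracy = default prevalence
  base <- matrix(1L, 4, 2, dimnames = list(NULL, modifiers(ex)))
  rep2 <- evaluatePredictions(ex, base)
  expect_equal(metricsPerModifier(rep2)$unweighted_accuracy,
               c(0.75, 1))
  expect_equal(metricsPerModifier(rep2)$micro_f1[1], 0)

  # misaligned predictions are an error
  expect_error(evaluatePredictions(ex, base[1:3, ]), "alignment")
})

test_that("metric reports serialize to JSON and TSV", {
  sch <- tinySchema()
  gold <- cbind(c(1L, 2L), c(1L, 3L))
  ex <- madeExamples(sch, gold)
  rep <- evaluatePredictions(ex, matrix(gold, ncol = 2,
                                        dimnames = list(NULL,
                                                        modifiers(ex))))
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  writeMetricsJson(rep, jp)
  writeMetricsTsv(rep, tp)
  j <- jsonlite::fromJSON(jp)
  expect_equal(j$averages$unweighted_accuracy, 1)
  tsv <- utils::read.delim(tp)
  expect_identical(tsv$modifier, modifiers(ex))
})
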