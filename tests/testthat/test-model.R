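sch <- tinySchema()

zeroHeads <- function(model) {
  for (mi in names(model@heads)) {
    model@heads[[mi]]$W[] <- 0
    model@heads[[mi]]$b[] <- 0
  }
  model
}

test_that("modelForward applies softmax(W h + b) per head", {
  # zero weights and bias: uniform over each head's classes
  h <- matrix(c(1, 0), 1)
  m <- zeroHeads(constModel(h, sch))
  ex <- madeExamples(sch, matrix(c(1L, 1L), 1))
  probs <- modelForward(m, ex)
  expect_equal(unname(probs$negation[1, ]), c(0.5, 0.5))
  expect_equal(unname(probs$severity[1, ]), rep(1 / 3, 3))

  # closed-form softmax: W=[[1,0],[0,0]], b=0, h=(1,0) -> softmax(1, 0)
  m2 <- m
  m2@heads$negation$W <- rbind(c(1, 0), c(0, 0))
  p <- modelForward(m2, ex)$negation[1, ]
  expect_equal(unname(p), c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)

  # normalization holds for random heads and inputs
  set.seed(1)
  hr <- matrix(rnorm(20), 10, 2)
  mr <- constModel(hr, sch, seed = 5)
  exr <- madeExamples(sch, cbind(rep(1L, 10), rep(1L, 10)))
  pr <- modelForward(mr, exr)
  for (p in pr) {
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  }
})

test_that("headLoss matches the closed forms", {
  # one-hot correct prediction: zero loss
  expect_equal(headLoss(matrix(c(1, 0), 1), 1L), 0)
  # uniform over C classes: log(C)
  expect_equal(headLoss(matrix(rep(1 / 3, 3), 1), 2L), log(3),
               tolerance = 1e-12)
  # focal, gamma 2, p = 0.9
  expect_equal(headLoss(matrix(c(0.9, 0.1), 1), 1L,
                        lossConfig("focal", 2)),
               -(0.1)^2 * log(0.9), tolerance = 1e-12)
  # zero probability is clamped with a warning, never infinite
  expect_warning(l <- headLoss(matrix(c(0, 1), 1), 1L), "clamped")
  expect_true(is.finite(l))
})

test_that("focal loss with gamma 0 equals cross-entropy", {
  set.seed(42)
  for (rep in 1:20) {
    C <- sample(2:5, 1); k <- sample(1:30, 1)
    p <- matrix(rexp(k * C), k)
    p <- p / rowSums(p)
    gold <- sample.int(C, k, replace = TRUE)
    expect_equal(headLoss(p, gold, lossConfig("focal", 0)),
                 headLoss(p, gold, lossConfig("cross_entropy")),
                 tolerance = 1e-9)
  }
})

test_that("multitaskLoss is the arithmetic mean of per-head losses", {
  # n = 1: equals headLoss exactly
  one <- modifierSchema("one", list(negation = c("no", "yes")))
  h <- matrix(c(0.3, -0.2), 1)
  m1 <- constModel(h, one, seed = 3)
  ex1 <- madeExamples(one, matrix(2L, 1))
  probs <- modelForward(m1, ex1)
  expect_equal(multitaskLoss(m1, ex1),
               headLoss(probs$negation, 2L))

  # uniform heads: mean of log class counts, here (log 2 + log 3)/2
  mz <- zeroHeads(constModel(h, sch))
  exz <- madeExamples(sch, matrix(c(1L, 2L), 1))
  expect_equal(multitaskLoss(mz, exz), mean(c(log(2), log(3))),
               tolerance = 1e-12)

  # 7 uniform heads: mean of log of each head's class count
  share <- makeSchema("share_like")
  ms <- zeroHeads(constModel(matrix(rnorm(8), 2, 4), share, seed = 2))
  exs <- madeExamples(share, matrix(1L, 2, 7))
  counts <- lengths(ms@schema@labels)
  expect_equal(multitaskLoss(ms, exs), mean(log(counts)),
               tolerance = 1e-12)

  expect_error(multitaskLoss(mz, madeExamples(sch, matrix(1L, 0, 2))),
               "empty")
})

test_that("predictModifiers takes the argmax with lowest-index ties", {
  h <- matrix(0, 3, 2)
  m <- zeroHeads(constModel(h, sch))
  # all-zero heads: exact ties everywhere -> class 1
  ex <- madeExamples(sch, matrix(1L, 3, 2))
  pred <- predictModifiers(m, ex)
  expect_true(all(pred == 1L))
  # a shifted bias moves the argmax
  m@heads$severity$b <- c(0, 1, 0)
  expect_true(all(predictModifiers(m, ex)[, "severity"] == 2L))
  # batch decode equals per-example decode
  set.seed(3)
  mr <- constModel(matrix(rnorm(12), 6, 2), sch, seed = 9)
  exr <- madeExamples(sch, matrix(1L, 6, 2))
  batch <- predictModifiers(mr, exr)
  for (i in 1:6) {
    single <- predictModifiers(
      constModel(mr@encoder@h[i, , drop = FALSE], sch, heads = mr@heads),
      subsetExamples(exr, i))
    expect_identical(unname(batch[i, ]), unname(single[1, ]))
  }
})

test_that("single-task models are independent one-head specials", {
  share <- makeSchema("share_like")
  models <- makeSingleTaskModels(
    share, function(mi) tinyEncoder(vocab = c("a", "b"), seed = 11))
  expect_length(models, 7L)
  expect_identical(names(models), modifiers(share))
  for (mi in names(models)) {
    expect_length(modelHeads(models[[mi]]), 1L)
    expect_identical(modifiers(models[[mi]]), mi)
    expect_identical(labelSet(schemaOf(models[[mi]]), mi),
                     labelSet(share, mi))
  }
  # fresh encoder instances: mutating one leaves the others unchanged
  e1 <- modelEncoder(models[[1]])
  p <- encoderParams(e1); p$E[] <- 99
  models[[1]]@encoder <- encoderWithParams(e1, p)
  expect_false(identical(encoderParams(modelEncoder(models[[1]])),
                         encoderParams(modelEncoder(models[[2]]))))
  # concatenated single-task label spaces cover the multi-task schema
  expect_setequal(unlist(lapply(models, function(m) modifiers(m))),
                  modifiers(share))
})

test_that("checkpoints round-trip through the JSON manifest", {
  corp <- generateCorpus(generatorConfig(nMentions = 30, seed = 31))
  ex <- buildDataset(corp)
  enc <- tinyEncoder(texts = exampleMeta(ex)$left, seed = 3)
  model <- multiHeadModel(enc, schemaOf(corp), seed = 3)
  dir <- withr::local_tempdir()
  saveCheckpoint(model, dir)
  back <- loadCheckpoint(dir)
  expect_identical(modifiers(back), modifiers(model))
  expect_equal(modelHeads(back), modelHeads(model), tolerance = 0)
  expect_identical(predictModifiers(back, ex),
                   predictModifiers(model, ex))
})
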