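# small shared fixtures: a share-like and an oud-like synthetic corpus
makeFit <- function(nMentions = 300, seed = 5, kind = "share_like",
                    cfg = tinyTrainConfig(seed = 5, maxEpochs = 3,
                                          patience = 3)) {
  corp <- generateCorpus(generatorConfig(kind, nMentions = nMentions,
                                         seed = seed))
  sp <- splitCorpus(corp, c(0.8, 0.1, 0.1), seed = seed)
  tr <- buildDataset(sp$train); dv <- buildDataset(sp$dev)
  enc <- tinyEncoder(texts = c(exampleMeta(tr)$left,
                               exampleMeta(tr)$entity), seed = seed)
  model <- multiHeadModel(enc, schemaOf(corp), seed = seed)
  list(model = model, tr = tr, dv = dv, cfg = cfg, corp = corp, sp = sp)
}

test_that("early stopping keeps the best epoch under the patience rule", {
  d <- modmtl:::earlyStopDecision(c(0.6, 0.7, 0.7, 0.7), patience = 1)
  expect_identical(d$selected, 2L)
  expect_identical(d$ran, 3L)
  d <- modmtl:::earlyStopDecision(c(0.5, 0.6, 0.7, 0.8), patience = 2)
  expect_identical(d$selected, 4L)
  expect_identical(d$ran, 4L)
  d <- modmtl:::earlyStopDecision(c(0.9, 0.8, 0.8, 0.95), patience = 2)
  expect_identical(d$selected, 1L)
  expect_identical(d$ran, 3L)
})

test_that("training is deterministic given the seed", {
  f <- makeFit()
  fit1 <- trainModel(f$model, f$tr, f$dv, f$cfg)
  fit2 <- trainModel(f$model, f$tr, f$dv, f$cfg)
  expect_equal(modelHeads(fit1$model), modelHeads(fit2$model),
               tolerance = 0)
  expect_equal(encoderParams(modelEncoder(fit1$model)),
               encoderParams(modelEncoder(fit2$model)), tolerance = 0)
  expect_identical(fit1$report@trainLoss, fit2$report@trainLoss)
})

test_that("the multitask loss decreases on a solvable synthetic task", {
  f <- makeFit(cfg = tinyTrainConfig(seed = 5, maxEpochs = 5,
                                     patience = 5))
  fit <- trainModel(f$model, f$tr, f$dv, f$cfg)
  loss <- fit$report@trainLoss
  expect_lt(loss[length(loss)], loss[1])
  expect_lte(fit$report@selectedEpoch, length(loss))
})

test_that("trainFinal retrains on the train+dev union for fixed epochs", {
  f <- makeFit()
  fit <- trainFinal(f$model, f$tr, f$dv, f$cfg, epochs = 2)
  expect_identical(fit$report@mode, "final")
  expect_length(fit$report@trainLoss, 2L)
  expect_identical(nrow(fit$report@devMetric), 0L)
  expect_identical(nExamples(bindExamples(f$tr, f$dv)),
                   nExamples(f$tr) + nExamples(f$dv))
})

test_that("transferInit copies the encoder and name-matched heads verbatim", {
  share <- makeSchema("share_like"); oud <- makeSchema("oud_like")
  enc <- tinyEncoder(vocab = c("denies", "possible", "fever"), seed = 2)
  src <- multiHeadModel(enc, share, seed = 2)

  # identity transfer: every head identical
  same <- transferInit(src, share, seed = 99)
  expect_equal(modelHeads(same), modelHeads(src), tolerance = 0)
  expect_identical(encoderParams(modelEncoder(same)),
                   encoderParams(modelEncoder(src)))

  # share(7) -> oud(5): exactly {negation, subject, uncertainty} copied
  tgt <- transferInit(src, oud, seed = 99)
  expect_length(modelHeads(tgt), 5L)
  shared <- c("negation", "subject", "uncertainty")
  for (mi in shared)
    expect_identical(modelHeads(tgt)[[mi]], modelHeads(src)[[mi]])
  for (mi in setdiff(modifiers(oud), shared))
    expect_false(isTRUE(all.equal(modelHeads(tgt)[[mi]]$W[1, 1],
                                  0)))  # freshly initialized, nonzero
  # reverse direction has 7 heads
  srcOud <- multiHeadModel(enc, oud, seed = 3)
  back <- transferInit(srcOud, share, seed = 99)
  expect_length(modelHeads(back), 7L)

  # disjoint schemas: nothing copied, encoder still shared
  other <- modifierSchema("x", list(foo = c("a", "b")))
  d <- transferInit(src, other, seed = 1)
  expect_length(modelHeads(d), 1L)
  expect_identical(encoderParams(modelEncoder(d)),
                   encoderParams(modelEncoder(src)))

  # a name match with a different label list is an explicit error
  clash <- modifierSchema("clash",
                          list(negation = c("absent", "present")))
  expect_error(transferInit(src, clash, seed = 1), "negation")
})

test_that("transferInit from a checkpoint directory equals in-memory", {
  share <- makeSchema("share_like"); oud <- makeSchema("oud_like")
  enc <- tinyEncoder(vocab = c("denies", "no"), seed = 8)
  src <- multiHeadModel(enc, share, seed = 8)
  dir <- withr::local_tempdir()
  saveCheckpoint(src, dir)
  a <- transferInit(src, oud, seed = 4)
  b <- transferInit(dir, oud, seed = 4)
  expect_equal(modelHeads(a), modelHeads(b), tolerance = 0)
})

test_that("mergeCorpora builds the union schema and keeps labels", {
  a <- generateCorpus(generatorConfig("share_like", nMentions = 30,
                                      seed = 41))
  b <- generateCorpus(generatorConfig("oud_like", nMentions = 30,
                                      seed = 43))
  merged <- mergeCorpora(a, b)
  expect_length(modifiers(merged), 9L)
  expect_identical(nMentions(merged), nMentions(a) + nMentions(b))

  # self-merge: schema unchanged, examples concatenated
  aa <- mergeCorpora(a, a)
  expect_identical(modifiers(aa), modifiers(a))
  expect_identical(nMentions(aa), 2L * nMentions(a))

  # original non-default labels survive; novel modifiers sit at default
  ex <- buildDataset(merged)
  exA <- buildDataset(a)
  lab <- exampleLabels(ex); labA <- exampleLabels(exA)
  aRows <- exampleMeta(ex)$entityId %in% exampleMeta(exA)$entityId
  sub <- lab[aRows, modifiers(a)][order(exampleMeta(ex)$entityId[aRows]), ]
  expect_identical(unname(sub),
                   unname(labA[order(exampleMeta(exA)$entityId), ]))
  novel <- setdiff(modifiers(merged), modifiers(a))
  for (mi in novel) {
    di <- schemaOf(merged)@defaults[[mi]]
    expect_true(all(lab[aRows, mi] == di))
  }

  # conflicting label lists are a schema error
  conflict <- annotatedCorpus(
    modifierSchema("c", list(negation = c("absent", "present"))),
    list(), list())
  expect_error(mergeCorpora(a, conflict), "negation")
})
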