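schema2 <- tinySchema()

test_that("parseBrat handles plain, attributed and discontiguous mentions", {
  # no annotations
  p <- parseBrat("No fever today.", "", schema2, "d0")
  expect_s4_class(p$document, "Document")
  expect_length(p$mentions, 0L)

  # attributed mention
  p <- parseBrat("No fever today.",
                 "T1\tDisorder 3 8\tfever\nA1\tNegation T1 yes",
                 schema2, "d1")
  m <- p$mentions[[1]]
  expect_equal(unname(mentionSpans(m)), matrix(c(3L, 8L), 1))
  expect_identical(mentionSurface(m), "fever")
  expect_identical(mentionLabels(m), c(negation = "yes"))

  # discontiguous fragments join with a single space
  txt <- "pain in my ache today"
  p <- parseBrat(txt, "T1\tDisorder 0 4;11 15\tpain ache", schema2, "d2")
  m <- p$mentions[[1]]
  expect_equal(unname(mentionSpans(m)),
               matrix(c(0L, 11L, 4L, 15L), 2))
  expect_identical(mentionSurface(m), "pain ache")

  # valueless binary attribute takes the non-default label
  p <- parseBrat("No fever today.",
                 "T1\tDisorder 3 8\tfever\nA1\tNegation T1",
                 schema2, "d3")
  expect_identical(mentionLabels(p$mentions[[1]]), c(negation = "yes"))
})

test_that("parseBrat rejects malformed input and flags unknown attributes", {
  expect_error(parseBrat("short", "T1\tDisorder 3 99\tx", schema2, "d"),
               "outside")
  expect_error(parseBrat("No fever today.",
                         "T1\tDisorder 3 8\tchill", schema2, "d"),
               "does not match")
  expect_error(parseBrat("No fever today.",
                         "T1\tDisorder 3 8\tfever\nA1\tNegation T9 yes",
                         schema2, "d"),
               "unknown entity")
  expect_error(parseBrat("No fever today.", "T1\tDisorder\tfever",
                         schema2, "d"),
               "malformed")
  # valueless attribute on a 3-class modifier is ambiguous
  expect_error(parseBrat("No fever today.",
                         "T1\tDisorder 3 8\tfever\nA1\tSeverity T1",
                         schema2, "d"),
               "valueless")
  # unknown attribute names are skipped with a warning, not an error
  expect_warning(
    p <- parseBrat("No fever today.",
                   "T1\tDisorder 3 8\tfever\nA1\tAnatomy T1 leg",
                   schema2, "d"),
    "not in schema")
  expect_length(mentionLabels(p$mentions[[1]]), 0L)
})

test_that("writeBrat omits defaults and round-trips parseBrat", {
  doc <- document("d1", "No fever today.")
  m <- entityMention("e1", "d1", c(3, 8), "fever",
                     labels = c(negation = "yes"))
  b <- writeBrat(doc, list(m), schema2)
  expect_identical(b$txt, "No fever today.")
  p <- parseBrat(b$txt, b$ann, schema2, "d1")
  expect_equal(mentionSpans(p$mentions[[1]]), mentionSpans(m))
  expect_identical(mentionLabels(p$mentions[[1]]), mentionLabels(m))

  # all-default labels produce only the T line
  mDef <- entityMention("e1", "d1", c(3, 8), "fever",
                        labels = c(negation = "no"))
  b <- writeBrat(doc, list(mDef), schema2)
  expect_false(grepl("^A", b$ann))
  expect_match(b$ann, "^T1\t")

  # no mentions -> empty ann
  expect_identical(writeBrat(doc, list(), schema2)$ann, "")
})

test_that("JSONL round-trips examples and enforces the schema", {
  sch <- tinySchema()
  labels <- matrix(c(1L, 2L, 1L, 1L, 2L, 3L), ncol = 2)
  ex <- madeExamples(sch, labels)
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeExamplesJsonl(ex, path)
  back <- readExamplesJsonl(path, sch)
  expect_identical(exampleMeta(back), exampleMeta(ex))
  expect_identical(exampleLabels(back), exampleLabels(ex))

  # empty file -> empty set
  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), empty)
  expect_identical(nExamples(readExamplesJsonl(empty, sch)), 0L)

  # a record missing a schema modifier is a schema error
  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0('{"doc_id":"d","entity_id":"e","left_sequence":"x",',
                    '"entity_sequence":"y","labels":{"negation":"no"}}'),
             bad)
  expect_error(readExamplesJsonl(bad, sch), "missing schema modifier")

  # malformed JSON names the line
  writeLines(c('{"doc_id": "d"', "{oops"), bad)
  expect_error(readExamplesJsonl(bad, sch), "line 1")
})

test_that("splitCorpus partitions mentions deterministically", {
  corp <- generateCorpus(generatorConfig(nMentions = 10, seed = 3))
  # generator may round the count up slightly through multiplicities;
  # force exactly 10 for the arithmetic check
  corp10 <- annotatedCorpus(schemaOf(corp), corpusDocuments(corp),
                            corpusMentions(corp)[1:10])
  sp <- splitCorpus(corp10, c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(vapply(sp, nMentions, integer(1)),
                   c(train = 8L, dev = 1L, test = 1L))

  # same seed -> identical partition; union is a disjoint cover
  sp2 <- splitCorpus(corp10, c(0.8, 0.1, 0.1), seed = 7)
  ids <- function(x) vapply(corpusMentions(x), entityId, character(1))
  expect_identical(lapply(sp, ids), lapply(sp2, ids))
  all1 <- unlist(lapply(sp, ids))
  expect_setequal(all1, ids(corp10))
  expect_identical(anyDuplicated(all1), 0L)

  # different seeds give different partitions on 100 mentions
  corp100 <- generateCorpus(generatorConfig(nMentions = 100, seed = 5))
  a <- splitCorpus(corp100, c(0.8, 0.1, 0.1), seed = 1)
  b <- splitCorpus(corp100, c(0.8, 0.1, 0.1), seed = 2)
  expect_false(identical(ids(a$train), ids(b$train)))

  expect_error(splitCorpus(corp100, c(0.5, 0.2, 0.2), seed = 1),
               "sum to 1")
  emptyCorp <- annotatedCorpus(schemaOf(corp100), list(), list())
  expect_warning(se <- splitCorpus(emptyCorp, c(0.8, 0.1, 0.1), 1),
                 "empty")
  expect_identical(nMentions(se$train), 0L)
})

test_that("document-level splitting keeps a document's mentions together", {
  corp <- generateCorpus(generatorConfig(nMentions = 100, seed = 11))
  sp <- splitCorpus(corp, c(0.8, 0.1, 0.1), seed = 4, byDocument = TRUE)
  docsIn <- lapply(sp, function(x)
    unique(vapply(corpusMentions(x), docId, character(1))))
  expect_identical(length(Reduce(intersect, docsIn[c("train", "dev")])), 0L)
  expect_identical(length(Reduce(intersect, docsIn[c("dev", "test")])), 0L)
})

test_that("BRAT directory round-trip preserves a generated corpus", {
  corp <- generateCorpus(generatorConfig(nMentions = 40, seed = 21))
  dir <- withr::local_tempdir()
  writeBratDir(corp, dir)
  back <- readBratDir(dir, schemaOf(corp))
  expect_identical(nMentions(back), nMentions(corp))
  key <- function(x) {
    m <- corpusMentions(x)
    o <- order(vapply(m, docId, character(1)),
               vapply(m, function(mm) mentionSpans(mm)[1, 1], numeric(1)))
    lapply(m[o], function(mm)
      list(docId(mm), unname(mentionSpans(mm)), mentionSurface(mm),
           mentionLabels(mm)[sort(names(mentionLabels(mm)))]))
  }
  expect_identical(key(back), key(corp))
})
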