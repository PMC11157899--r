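# Feature extraction: (document, mention) -> two-sequence input pairs.
#
# The model input follows a question-answering-style pair: the first
# sequence is the mention in its character context window (200 characters
# before the first span, 50 after the last, clipped at document
# boundaries), the second sequence is the entity string itself. No sentence
# segmentation is attempted anywhere: sentence boundaries are unreliable in
# clinical notes, and the character window sidesteps them.

#' Construct a window configuration
#' @param charsBefore characters of context before the mention (default 200).
#' @param charsAfter characters of context after the mention (default 50).
#' @param hint logical; FALSE omits the entity string from the second
#'   sequence (the "no hint" ablation).
#' @return a [WindowConfig-class].
#' @export
windowConfig <- function(charsBefore = 200L, charsAfter = 50L, hint = TRUE) {
  new("WindowConfig", charsBefore = as.integer(charsBefore),
      charsAfter = as.integer(charsAfter), hint = hint)
}

# Gold labels of one mention as a full 1-based index vector over the schema
# (defaults materialized for unannotated modifiers).
labelIndices <- function(schema, labels) {
  idx <- schema@defaults
  for (nm in names(labels)) {
    if (!nm %in% schema@modifiers)
      stop(sprintf("unknown modifier '%s'", nm))
    k <- match(labels[[nm]], schema@labels[[nm]])
    if (is.na(k))
      stop(sprintf("'%s' is not a label of modifier '%s'", labels[[nm]], nm))
    idx[[nm]] <- k
  }
  idx
}

#' Extract the two-sequence input pair for one mention
#'
#' The left sequence is the contiguous document substring from
#' `first_span_start - charsBefore` to `last_span_end + charsAfter`
#' (clipped at the document boundaries); for a discontiguous mention the
#' window is anchored on the first span's start and the last span's end.
#' The entity sequence is the mention surface — only the strings that
#' represent the entity, fragments joined by one space — or "" in no-hint
#' mode.
#'
#' @param doc a [Document-class].
#' @param mention an [EntityMention-class] in `doc`.
#' @param schema the governing [ModifierSchema-class].
#' @param config a [WindowConfig-class].
#' @return list(docId, entityId, left, entity, labels) where labels is a
#'   named integer vector of 1-based label indices (defaults filled).
#' @export
extractInputPair <- function(doc, mention, schema,
                             config = windowConfig()) {
  sp <- mention@spans
  if (max(sp[, 2]) > nchar(doc@text))
    stop(sprintf("mention '%s' has a span outside document '%s'",
                 mention@entityId, doc@docId))
  if (!identical(mention@surface, substrSpans(doc@text, sp)))
    stop(sprintf("mention '%s' surface does not match the document",
                 mention@entityId))
  a <- max(0L, sp[1, 1] - config@charsBefore)          # 0-based inclusive
  b <- min(nchar(doc@text), sp[nrow(sp), 2] + config@charsAfter)
  list(docId = doc@docId, entityId = mention@entityId,
       left = substring(doc@text, a + 1L, b),
       entity = if (config@hint) mention@surface else "",
       labels = labelIndices(schema, mention@labels))
}

#' Featurize a whole corpus
#'
#' Produces exactly one example per entity mention — duplicate surface
#' strings inside one window stay distinct examples, keyed by their span
#' sets — in the deterministic order (docId, first span start, entityId).
#'
#' @param corpus an [AnnotatedCorpus-class].
#' @param config a [WindowConfig-class].
#' @return an [ExampleSet-class].
#' @export
buildDataset <- function(corpus, config = windowConfig()) {
  sch <- corpus@schema
  men <- corpus@mentions
  if (length(men)) {
    key <- order(vapply(men, docId, character(1)),
                 vapply(men, function(m) m@spans[1, 1], numeric(1)),
                 vapply(men, entityId, character(1)))
    men <- men[key]
  }
  rows <- lapply(men, function(m)
    extractInputPair(corpus@documents[[m@docId]], m, sch, config))
  meta <- data.frame(
    docId = vapply(rows, `[[`, character(1), "docId"),
    entityId = vapply(rows, `[[`, character(1), "entityId"),
    left = vapply(rows, `[[`, character(1), "left"),
    entity = vapply(rows, `[[`, character(1), "entity"),
    stringsAsFactors = FALSE)
  if (!length(rows))
    meta <- data.frame(docId = character(0), entityId = character(0),
                       left = character(0), entity = character(0),
                       stringsAsFactors = FALSE)
  labs <- matrix(0L, nrow = length(rows), ncol = length(sch@modifiers),
                 dimnames = list(NULL, sch@modifiers))
  for (i in seq_along(rows)) labs[i, ] <- rows[[i]]$labels
  new("ExampleSet", schema = sch, meta = meta, labels = labs)
}

#' @describeIn nExamples ExampleSet method
#' @export
setMethod("nExamples", "ExampleSet", function(x) nrow(x@meta))

#' @describeIn modifiers ExampleSet method
#' @export
setMethod("modifiers", "ExampleSet", function(x) x@schema@modifiers)

#' @describeIn schemaOf ExampleSet method
#' @export
setMethod("schemaOf", "ExampleSet", function(x) x@schema)

#' Example metadata / gold labels of an ExampleSet
#' @param x an [ExampleSet-class].
#' @return `exampleMeta`: data.frame (docId, entityId, left, entity).
#' @export
exampleMeta <- function(x) x@meta

#' @rdname exampleMeta
#' @return `exampleLabels`: integer matrix of 1-based gold label indices.
#' @export
exampleLabels <- function(x) x@labels

#' Subset an ExampleSet by row
#' @param x an [ExampleSet-class].
#' @param idx integer or logical row index.
#' @return an [ExampleSet-class].
#' @export
subsetExamples <- function(x, idx) {
  new("ExampleSet", schema = x@schema, meta = x@meta[idx, , drop = FALSE],
      labels = x@labels[idx, , drop = FALSE])
}

#' Concatenate ExampleSets sharing a schema
#' @param ... [ExampleSet-class] objects with identical schemas.
#' @return an [ExampleSet-class].
#' @export
bindExamples <- function(...) {
  xs <- list(...)
  sch <- xs[[1]]@schema
  for (x in xs[-1])
    if (!identical(x@schema@modifiers, sch@modifiers) ||
        !identical(x@schema@labels, sch@labels))
      stop("ExampleSets have different schemas")
  new("ExampleSet", schema = sch,
      meta = do.call(rbind, lapply(xs, function(x) x@meta)),
      labels = do.call(rbind, lapply(xs, function(x) x@labels)))
}

setMethod("show", "ExampleSet", function(object) {
  cat(sprintf("ExampleSet: %d examples, schema '%s' (%d modifiers)\n",
              nrow(object@meta), object@schema@name,
              length(object@schema@modifiers)))
  invisible(NULL)
})

#' Fit a sequence pair into a token budget
#'
#' When the tokenized pair (plus 3 special markers: sequence start and two
#' separators) exceeds `maxTokens`, characters are dropped from the LEFT
#' edge of the left sequence — farthest from the mention — until the budget
#' fits; the entity sequence is never touched before the left sequence is
#' exhausted. The mention and its trailing context carry the modifier cues,
#' and the context window is itself asymmetric toward preceding text, so the
#' oldest context is the cheapest to lose.
#'
#' @param left,entity character(1) the sequence pair.
#' @param maxTokens integer(1) >= 8; token budget including 3 markers.
#' @return list(left, entity) fitting the budget.
#' @export
encodePairLengthBudget <- function(left, entity, maxTokens = 144L) {
  stopifnot(maxTokens >= 8L)
  budget <- maxTokens - 3L
  entTok <- tokenizeText(entity)[[1]]
  starts <- tokenStarts(left)
  nLeft <- length(starts)
  if (length(entTok) >= budget) {
    warning("entity sequence alone exceeds the token budget; truncated")
    keep <- tokenizeText(entity)[[1]][seq_len(budget)]
    return(list(left = "", entity = paste(keep, collapse = " ")))
  }
  keepLeft <- budget - length(entTok)
  if (nLeft <= keepLeft) return(list(left = left, entity = entity))
  cut <- starts[nLeft - keepLeft + 1L]
  list(left = substring(left, cut), entity = entity)
}
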