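#' Construct a Document
#' @param docId character(1) identifier.
#' @param text character(1) full document text.
#' @return a [Document-class].
#' @export
document <- function(docId, text) new("Document", docId = docId, text = text)

#' Document accessors
#' @param x a [Document-class] or [EntityMention-class].
#' @return `docId`: character(1).
#' @export
docId <- function(x) x@docId

#' @rdname docId
#' @return `docText`: character(1) the document text.
#' @export
docText <- function(x) x@text

setMethod("show", "Document", function(object) {
  cat(sprintf("Document '%s' (%d chars)\n", object@docId,
              nchar(object@text)))
  invisible(NULL)
})

#' Construct an EntityMention
#'
#' @param entityId character(1) identifier.
#' @param docId character(1) owning document id.
#' @param spans two-column matrix (or length-2 vector) of 0-based half-open
#'   character offsets; rows are sorted by start if needed.
#' @param surface character(1); if NULL it must be set later against the
#'   document (see [parseBrat()]).
#' @param labels named character of explicitly annotated modifier values
#'   (absent modifiers carry the schema default).
#' @return an [EntityMention-class].
#' @examples
#' entityMention("e1", "d1", c(3, 8), surface = "fever",
#'               labels = c(negation = "yes"))
#' @export
entityMention <- function(entityId, docId, spans, surface,
                          labels = character()) {
  if (is.null(dim(spans))) spans <- matrix(spans, ncol = 2, byrow = TRUE)
  spans <- matrix(as.integer(spans), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  new("EntityMention", entityId = entityId, docId = docId, spans = spans,
      surface = surface, labels = labels)
}

#' EntityMention accessors
#' @param x an [EntityMention-class].
#' @return `entityId`: character(1).
#' @export
entityId <- function(x) x@entityId

#' @rdname entityId
#' @return `mentionSpans`: integer matrix of 0-based half-open spans.
#' @export
mentionSpans <- function(x) x@spans

#' @rdname entityId
#' @return `mentionSurface`: character(1) the entity string(s).
#' @export
mentionSurface <- function(x) x@surface

#' @rdname entityId
#' @return `mentionLabels`: named character of explicit labels.
#' @export
mentionLabels <- function(x) x@labels

setMethod("show", "EntityMention", function(object) {
  sp <- apply(object@spans, 1L, function(r) sprintf("%d-%d", r[1], r[2]))
  lab <- if (length(object@labels))
    paste(names(object@labels), object@labels, sep = "=", collapse = ", ")
  else "(all default)"
  cat(sprintf("EntityMention '%s' in '%s' [%s] \"%s\" %s\n",
              object@entityId, object@docId, paste(sp, collapse = ";"),
              object@surface, lab))
  invisible(NULL)
})

#' Construct an AnnotatedCorpus
#' @param schema a [ModifierSchema-class].
#' @param documents list of [Document-class].
#' @param mentions list of [EntityMention-class].
#' @return an [AnnotatedCorpus-class]; all cross-references are validated.
#' @export
annotatedCorpus <- function(schema, documents = list(), mentions = list()) {
  names(documents) <- vapply(documents, docId, character(1))
  new("AnnotatedCorpus", schema = schema, documents = documents,
      mentions = mentions)
}

#' @describeIn modifiers corpus method
#' @export
setMethod("modifiers", "AnnotatedCorpus", function(x) x@schema@modifiers)

#' @describeIn schemaOf corpus method
#' @export
setMethod("schemaOf", "AnnotatedCorpus", function(x) x@schema)

#' @describeIn nMentions corpus method
#' @export
setMethod("nMentions", "AnnotatedCorpus", function(x) length(x@mentions))

#' @describeIn nDocuments corpus method
#' @export
setMethod("nDocuments", "AnnotatedCorpus", function(x) length(x@documents))

#' Documents / mentions of a corpus
#' @param x an [AnnotatedCorpus-class].
#' @return `corpusDocuments`: named list of [Document-class].
#' @export
corpusDocuments <- function(x) x@documents

#' @rdname corpusDocuments
#' @return `corpusMentions`: list of [EntityMention-class].
#' @export
corpusMentions <- function(x) x@mentions

setMethod("show", "AnnotatedCorpus", function(object) {
  cat(sprintf("AnnotatedCorpus: %d documents, %d mentions, schema '%s' (%d modifiers)\n",
              length(object@documents), length(object@mentions),
              object@schema@name, length(object@schema@modifiers)))
  invisible(NULL)
})

#' Split a corpus into train / dev / test
#'
#' By default the partition is over entity mentions, not documents: the same
#' document text may back mentions in different splits. This matches
#' entity-level evaluation protocols for modifier classification; set
#' `byDocument = TRUE` to keep each document's mentions together.
#'
#' @param corpus an [AnnotatedCorpus-class].
#' @param fractions numeric(3) (train, dev, test); must be positive and sum
#'   to 1 (tolerance 1e-9). Split sizes are the rounded fractions of the
#'   mention (or document) count.
#' @param seed integer; the same seed always yields the same partition.
#' @param byDocument logical(1), partition whole documents instead.
#' @return named list of three [AnnotatedCorpus-class]: train, dev, test.
#' @examples
#' sch <- modifierSchema("s", list(negation = c("no", "yes")))
#' doc <- document("d1", "fever and cough and rash today")
#' men <- list(entityMention("e1", "d1", c(0, 5), "fever"),
#'             entityMention("e2", "d1", c(10, 15), "cough"))
#' sp <- splitCorpus(annotatedCorpus(sch, list(doc), men), c(.5, .25, .25), 1)
#' nMentions(sp$train)
#' @export
splitCorpus <- function(corpus, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                        byDocument = FALSE) {
  stopifnot(length(fractions) == 3L)
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be positive and sum to 1")
  subCorpus <- function(mentions) {
    keep <- unique(vapply(mentions, docId, character(1)))
    annotatedCorpus(corpus@schema, corpus@documents[keep], mentions)
  }
  if (nMentions(corpus) == 0L) {
    warning("splitting an empty corpus")
    e <- annotatedCorpus(corpus@schema, list(), list())
    return(list(train = e, dev = e, test = e))
  }
  if (byDocument) {
    n <- length(corpus@documents)
    perm <- withSeed(seed, sample.int(n))
    n1 <- round(fractions[1] * n); n2 <- round(fractions[2] * n)
    grp <- list(perm[seq_len(n1)],
                perm[seq_len(n2) + n1],
                perm[setdiff(seq_len(n), seq_len(n1 + n2))])
    ids <- names(corpus@documents)
    mdoc <- vapply(corpus@mentions, docId, character(1))
    parts <- lapply(grp, function(g)
      corpus@mentions[mdoc %in% ids[g]])
  } else {
    n <- nMentions(corpus)
    perm <- withSeed(seed, sample.int(n))
    n1 <- round(fractions[1] * n); n2 <- round(fractions[2] * n)
    parts <- list(corpus@mentions[perm[seq_len(n1)]],
                  corpus@mentions[perm[n1 + seq_len(n2)]],
                  corpus@mentions[perm[setdiff(seq_len(n),
                                               seq_len(n1 + n2))]])
  }
  stats::setNames(lapply(parts, subCorpus), c("train", "dev", "test"))
}

#' Merge two corpora into a combined-schema corpus
#'
#' The schemas are merged on modifier names via [mergeSchemas()]; examples
#' from one corpus implicitly carry the default label for the other corpus's
#' novel modifiers (defaults are materialized at featurization). Document
#' ids colliding across corpora are disambiguated with a suffix.
#'
#' @param a,b [AnnotatedCorpus-class] objects.
#' @return an [AnnotatedCorpus-class] over the union schema.
#' @export
mergeCorpora <- function(a, b) {
  sch <- mergeSchemas(a@schema, b@schema)
  bdocs <- b@documents
  bmen <- b@mentions
  clash <- intersect(names(a@documents), names(bdocs))
  if (length(clash)) {
    remap <- stats::setNames(paste0(names(bdocs), ".b"), names(bdocs))
    bdocs <- lapply(bdocs, function(d) document(remap[[d@docId]], d@text))
    bmen <- lapply(bmen, function(m) {
      m@docId <- remap[[m@docId]]; m
    })
  }
  eClash <- intersect(vapply(a@mentions, entityId, character(1)),
                      vapply(bmen, entityId, character(1)))
  if (length(eClash))
    bmen <- lapply(bmen, function(m) {
      m@entityId <- paste0(m@entityId, ".b"); m
    })
  annotatedCorpus(sch, c(unname(a@documents), unname(bdocs)),
                  c(a@mentions, bmen))
}

#' Per-modifier annotation counts
#'
#' Mirrors the usual corpus-statistics table: total mentions and, per
#' modifier, the number of mentions carrying a non-default label (default
#' values are unannotated, hence not counted).
#'
#' @param corpus an [AnnotatedCorpus-class].
#' @return data.frame with columns modifier, non_default; plus attributes
#'   `mentions` and `documents`.
#' @export
corpusStatistics <- function(corpus) {
  sch <- corpus@schema
  counts <- stats::setNames(integer(length(sch@modifiers)), sch@modifiers)
  for (m in corpus@mentions) {
    for (nm in names(m@labels)) {
      if (m@labels[[nm]] != defaultLabel(sch, nm))
        counts[[nm]] <- counts[[nm]] + 1L
    }
  }
  out <- data.frame(modifier = sch@modifiers, non_default = unname(counts),
                    stringsAsFactors = FALSE)
  attr(out, "mentions") <- nMentions(corpus)
  attr(out, "documents") <- nDocuments(corpus)
  out
}
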