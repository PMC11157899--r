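#' @import methods
NULL

#' ModifierSchema: an ordered set of modifier types
#'
#' A schema names the modifiers a corpus annotates (negation, severity,
#' course, ...), the label vocabulary of each, and which label is the
#' default ("unmarked"/null) class that an unannotated mention carries.
#' The order of the modifiers is significant: it fixes the order of the
#' classification heads in a [MultiHeadModel-class].
#'
#' @slot name character(1) schema identifier.
#' @slot modifiers character vector of modifier names, in head order.
#' @slot labels named list; for each modifier, its character label vocabulary
#'   (>= 2 distinct labels).
#' @slot defaults named integer; for each modifier, the 1-based index of the
#'   default label within its vocabulary.
#' @seealso [modifierSchema()], [makeSchema()], [mergeSchemas()]
#' @export
setClass("ModifierSchema",
  representation(name = "character", modifiers = "character",
                 labels = "list", defaults = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
    m <- object@modifiers
    if (anyDuplicated(m)) msg <- c(msg, "modifier names must be unique")
    if (!identical(names(object@labels), m))
      msg <- c(msg, "labels must be named exactly by the modifiers, in order")
    if (!identical(names(object@defaults), m))
      msg <- c(msg, "defaults must be named exactly by the modifiers, in order")
    for (mi in m) {
      lv <- object@labels[[mi]]
      if (!is.character(lv) || length(lv) < 2L || anyDuplicated(lv))
        msg <- c(msg, sprintf("modifier '%s' needs >= 2 distinct labels", mi))
      di <- object@defaults[[mi]]
      if (is.na(di) || di < 1L || di > length(lv))
        msg <- c(msg, sprintf("modifier '%s' has an invalid default index", mi))
    }
    if (length(msg)) msg else TRUE
  })

#' Document: one clinical-style text
#'
#' @slot docId character(1) unique document identifier.
#' @slot text character(1) full document text; all entity spans are
#'   0-based half-open character offsets into this string.
#' @export
setClass("Document",
  representation(docId = "character", text = "character"),
  validity = function(object) {
    if (length(object@docId) != 1L || !nzchar(object@docId))
      return("docId must be a non-empty string")
    if (length(object@text) != 1L || is.na(object@text))
      return("text must be a single (possibly empty) string")
    TRUE
  })

#' EntityMention: an entity span set with its modifier labels
#'
#' A mention is one (possibly discontiguous) entity occurrence. Spans use
#' the BRAT convention: 0-based, half-open character offsets. The surface
#' string is the document substrings of the spans joined with a single
#' space. `labels` holds only explicitly annotated modifier values; a
#' modifier absent from `labels` carries the schema default.
#'
#' @slot entityId character(1) identifier, unique within a corpus.
#' @slot docId character(1) id of the owning document.
#' @slot spans integer matrix with columns `start`, `end`; rows sorted by
#'   start and pairwise non-overlapping; each row has start < end.
#' @slot surface character(1) the entity string(s), fragments joined by " ".
#' @slot labels named character; modifier name -> label string.
#' @export
setClass("EntityMention",
  representation(entityId = "character", docId = "character",
                 spans = "matrix", surface = "character",
                 labels = "character"),
  validity = function(object) {
    s <- object@spans
    if (!is.numeric(s) || ncol(s) != 2L || nrow(s) < 1L)
      return("spans must be a numeric matrix with >= 1 row and 2 columns")
    if (any(s[, 1] < 0) || any(s[, 2] <= s[, 1]))
      return("each span must satisfy 0 <= start < end")
    if (is.unsorted(s[, 1], strictly = TRUE) && nrow(s) > 1L)
      return("spans must be sorted by start")
    if (nrow(s) > 1L && any(s[-1L, 1] < s[-nrow(s), 2]))
      return("spans must be pairwise non-overlapping")
    if (length(object@surface) != 1L)
      return("surface must be a single string")
    if (length(object@labels) && is.null(names(object@labels)))
      return("labels must be a named character vector")
    TRUE
  })

#' AnnotatedCorpus: documents, mentions and their governing schema
#'
#' @slot schema a [ModifierSchema-class].
#' @slot documents named list of [Document-class] (names = doc ids).
#' @slot mentions list of [EntityMention-class].
#' @export
setClass("AnnotatedCorpus",
  representation(schema = "ModifierSchema", documents = "list",
                 mentions = "list"),
  validity = function(object) {
    docs <- object@documents
    ids <- vapply(docs, function(d) d@docId, character(1))
    if (length(docs) && !identical(names(docs), unname(ids)))
      return("documents must be named by their docId")
    if (anyDuplicated(ids)) return("doc ids must be unique")
    sch <- object@schema
    for (mn in object@mentions) {
      d <- docs[[mn@docId]]
      if (is.null(d))
        return(sprintf("mention '%s' references unknown document '%s'",
                       mn@entityId, mn@docId))
      if (max(mn@spans[, 2]) > nchar(d@text))
        return(sprintf("mention '%s' has a span outside its document",
                       mn@entityId))
      if (!identical(mn@surface, substrSpans(d@text, mn@spans)))
        return(sprintf("mention '%s' surface does not match document text",
                       mn@entityId))
      for (nm in names(mn@labels)) {
        if (!nm %in% sch@modifiers)
          return(sprintf("mention '%s' labels unknown modifier '%s'",
                         mn@entityId, nm))
        if (!mn@labels[[nm]] %in% sch@labels[[nm]])
          return(sprintf("mention '%s': '%s' is not a label of modifier '%s'",
                         mn@entityId, mn@labels[[nm]], nm))
      }
    }
    TRUE
  })

#' WindowConfig: the character context window around a mention
#'
#' @slot charsBefore integer(1) characters of context kept before the first
#'   span (default 200).
#' @slot charsAfter integer(1) characters kept after the last span
#'   (default 50).
#' @slot hint logical(1); if FALSE the entity sequence is left empty
#'   (the "no hint" ablation).
#' @export
setClass("WindowConfig",
  representation(charsBefore = "integer", charsAfter = "integer",
                 hint = "logical"),
  validity = function(object) {
    if (object@charsBefore < 0L || object@charsAfter < 0L)
      return("window sizes must be >= 0")
    TRUE
  })

#' ExampleSet: featurized (left sequence, entity sequence) pairs
#'
#' The canonical in-memory dataset: one row per entity mention, in the
#' deterministic order (docId, first span start, entityId). Gold labels are
#' stored as a dense integer matrix of 1-based label indices with one column
#' per schema modifier (defaults materialized).
#'
#' @slot schema the governing [ModifierSchema-class].
#' @slot meta data.frame with columns docId, entityId, left, entity.
#' @slot labels integer matrix, nrow(meta) x length(modifiers(schema)).
#' @export
setClass("ExampleSet",
  representation(schema = "ModifierSchema", meta = "data.frame",
                 labels = "matrix"),
  validity = function(object) {
    need <- c("docId", "entityId", "left", "entity")
    if (!all(need %in% names(object@meta)))
      return("meta must have columns docId, entityId, left, entity")
    sch <- object@schema
    if (!identical(colnames(object@labels), sch@modifiers))
      return("label matrix columns must match schema modifiers")
    if (nrow(object@labels) != nrow(object@meta))
      return("labels and meta must have the same number of rows")
    if (nrow(object@labels)) {
      for (j in seq_along(sch@modifiers)) {
        C <- length(sch@labels[[j]])
        v <- object@labels[, j]
        if (any(is.na(v)) || any(v < 1L) || any(v > C))
          return(sprintf("invalid label index for modifier '%s'",
                         sch@modifiers[j]))
      }
    }
    TRUE
  })

#' PairEncoder: contract for pluggable sequence-pair encoders
#'
#' Any encoder that maps a (left sequence, entity sequence) pair to a pooled
#' vector of fixed dimension H can drive a [MultiHeadModel-class]. Concrete
#' encoders implement [encoderHiddenSize()], [encodeBatch()] and — if they
#' are to be trained by [trainModel()] — the gradient generics
#' [encoderPrepare()], [encoderForward()], [encoderBackward()],
#' [encoderParams()] and [encoderWithParams()]. The package ships
#' [tinyEncoder()], a compact trainable encoder; bindings to large
#' pretrained transformers served by an external runtime can be added by
#' implementing the same generics.
#' @export
setClass("PairEncoder", representation("VIRTUAL"))

#' TinyEncoder: a compact trainable sequence-pair encoder
#'
#' Trainable token embeddings, mean-pooled separately over the left
#' (context) and entity segments, concatenated and projected through a tanh
#' layer to a pooled vector of dimension `hidden`. Tokenization is a simple
#' case-sensitive alphanumeric split with an unknown-token bucket.
#'
#' @slot vocab character vector of known tokens (position = id - 1; id 1 is
#'   the unknown token).
#' @slot embedDim integer(1) embedding dimension.
#' @slot hidden integer(1) pooled output dimension H.
#' @slot params named list of numeric arrays: `E` ((V+1) x embedDim token
#'   embeddings), `Wp` (hidden x 2*embedDim projection), `bp` (hidden).
#' @export
setClass("TinyEncoder", contains = "PairEncoder",
  representation(vocab = "character", embedDim = "integer",
                 hidden = "integer", params = "list"),
  validity = function(object) {
    p <- object@params
    if (!all(c("E", "Wp", "bp") %in% names(p)))
      return("params must contain E, Wp, bp")
    if (!identical(dim(p$E), c(length(object@vocab) + 1L, object@embedDim)))
      return("E must be (|vocab|+1) x embedDim")
    if (!identical(dim(p$Wp), c(object@hidden, 2L * object@embedDim)))
      return("Wp must be hidden x 2*embedDim")
    if (length(p$bp) != object@hidden) return("bp must have length hidden")
    TRUE
  })

#' MultiHeadModel: per-modifier classification heads over a shared encoder
#'
#' One linear-softmax head per schema modifier, all fed the same pooled
#' encoder vector. Head i for a modifier with C_i labels holds a weight
#' matrix W (C_i x H) and bias b (C_i); the head's class distribution is
#' softmax(W h + b). Single-task models are the one-head special case.
#'
#' @slot encoder a [PairEncoder-class].
#' @slot schema the [ModifierSchema-class] (fixes head order and names).
#' @slot heads named list (one per modifier, schema order) of
#'   `list(W = matrix, b = numeric)`.
#' @slot maxTokens integer(1) token budget for the encoded pair.
#' @export
setClass("MultiHeadModel",
  representation(encoder = "PairEncoder", schema = "ModifierSchema",
                 heads = "list", maxTokens = "integer"),
  validity = function(object) {
    sch <- object@schema
    if (!identical(names(object@heads), sch@modifiers))
      return("heads must be named by the schema modifiers, in order")
    H <- encoderHiddenSize(object@encoder)
    for (mi in sch@modifiers) {
      h <- object@heads[[mi]]
      C <- length(sch@labels[[mi]])
      if (!identical(dim(h$W), c(C, H)))
        return(sprintf("head '%s' weight must be %d x %d", mi, C, H))
      if (length(h$b) != C)
        return(sprintf("head '%s' bias must have length %d", mi, C))
    }
    if (object@maxTokens < 8L) return("maxTokens must be >= 8")
    TRUE
  })

#' TrainReport: per-epoch training diagnostics
#'
#' @slot trainLoss numeric, mean multitask loss per epoch.
#' @slot devMetric matrix (epochs x modifiers) of per-modifier dev
#'   unweighted accuracy (0 rows when no dev set was given).
#' @slot devMacro numeric, dev accuracy macro-averaged over heads per epoch.
#' @slot selectedEpoch integer(1), the epoch whose weights were kept.
#' @slot mode character(1), "early_stop", "fixed" or "final".
#' @slot epochSeconds numeric, wall-clock seconds per epoch.
#' @export
setClass("TrainReport",
  representation(trainLoss = "numeric", devMetric = "matrix",
                 devMacro = "numeric", selectedEpoch = "integer",
                 mode = "character", epochSeconds = "numeric"),
  validity = function(object) {
    if (length(object@selectedEpoch) == 1L && !is.na(object@selectedEpoch) &&
        object@selectedEpoch > length(object@trainLoss))
      return("selectedEpoch cannot exceed the number of epochs run")
    TRUE
  })

#' MetricsReport: per-modifier and averaged evaluation metrics
#'
#' Undefined cells (e.g. micro F1 when neither gold nor predictions contain
#' a non-default class) are NA and recorded in `notes`; they are skipped,
#' never zeroed, when averaging.
#'
#' @slot perModifier data.frame with one row per modifier and columns
#'   weighted_accuracy, unweighted_accuracy, micro_f1, macro_f1.
#' @slot averages named numeric, simple means over the defined cells.
#' @slot notes character, flags for degenerate/undefined cells.
#' @export
setClass("MetricsReport",
  representation(perModifier = "data.frame", averages = "numeric",
                 notes = "character"))
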