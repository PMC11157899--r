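# Generics for the encoder contract and small accessors.

#' Pooled output dimension of an encoder
#' @param encoder a [PairEncoder-class].
#' @return integer(1) the dimension H of the pooled vector.
#' @export
setGeneric("encoderHiddenSize", function(encoder)
  standardGeneric("encoderHiddenSize"))

#' Encode a batch of sequence pairs to pooled vectors
#' @param encoder a [PairEncoder-class].
#' @param left character vector of left (context) sequences.
#' @param entity character vector of entity sequences ("" in no-hint mode).
#' @param maxTokens token budget for the pair including special markers.
#' @return numeric matrix, length(left) x H.
#' @export
setGeneric("encodeBatch", function(encoder, left, entity, maxTokens)
  standardGeneric("encodeBatch"))

#' Pre-tokenize a dataset for repeated encoder passes
#' @inheritParams encodeBatch
#' @return an opaque prepared-batch object consumed by [encoderForward()].
#' @export
setGeneric("encoderPrepare", function(encoder, left, entity, maxTokens)
  standardGeneric("encoderPrepare"))

#' Forward pass with cache for backpropagation
#' @param encoder a trainable [PairEncoder-class].
#' @param prepared object from [encoderPrepare()].
#' @param idx integer indices of the examples forming the batch.
#' @return list(h = pooled matrix k x H, cache = backward-pass cache).
#' @export
setGeneric("encoderForward", function(encoder, prepared, idx)
  standardGeneric("encoderForward"))

#' Backward pass: gradients of the encoder parameters
#' @param encoder a trainable [PairEncoder-class].
#' @param cache the cache from [encoderForward()].
#' @param dh gradient of the loss w.r.t. the pooled matrix (k x H).
#' @return named list of gradients matching [encoderParams()].
#' @export
setGeneric("encoderBackward", function(encoder, cache, dh)
  standardGeneric("encoderBackward"))

#' Trainable parameters of an encoder
#' @param encoder a [PairEncoder-class].
#' @return named list of numeric arrays.
#' @export
setGeneric("encoderParams", function(encoder)
  standardGeneric("encoderParams"))

#' Replace the trainable parameters of an encoder
#' @param encoder a [PairEncoder-class].
#' @param params named list as returned by [encoderParams()].
#' @return the encoder with parameters replaced.
#' @export
setGeneric("encoderWithParams", function(encoder, params)
  standardGeneric("encoderWithParams"))

#' Modifier names of a schema (or of an object carrying one)
#' @param x a [ModifierSchema-class], [AnnotatedCorpus-class],
#'   [ExampleSet-class] or [MultiHeadModel-class].
#' @return character vector of modifier names, in head order.
#' @export
setGeneric("modifiers", function(x) standardGeneric("modifiers"))

#' Label vocabulary of one modifier
#' @param x an object carrying a schema.
#' @param modifier character(1) modifier name.
#' @return character vector of labels.
#' @export
setGeneric("labelSet", function(x, modifier) standardGeneric("labelSet"))

#' Default label of one modifier
#' @inheritParams labelSet
#' @return character(1) the default ("unmarked") label.
#' @export
setGeneric("defaultLabel", function(x, modifier)
  standardGeneric("defaultLabel"))

#' The governing schema of an object
#' @param x an object carrying a [ModifierSchema-class].
#' @return the schema.
#' @export
setGeneric("schemaOf", function(x) standardGeneric("schemaOf"))

#' Number of entity mentions
#' @param x an [AnnotatedCorpus-class].
#' @return integer(1).
#' @export
setGeneric("nMentions", function(x) standardGeneric("nMentions"))

#' Number of documents
#' @param x an [AnnotatedCorpus-class].
#' @return integer(1).
#' @export
setGeneric("nDocuments", function(x) standardGeneric("nDocuments"))

#' Number of featurized examples
#' @param x an [ExampleSet-class].
#' @return integer(1).
#' @export
setGeneric("nExamples", function(x) standardGeneric("nExamples"))
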