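# Multi-head modifier classifier: per-modifier linear-softmax heads over a
# shared pooled encoder vector h. Head i computes softmax(W_i h + b_i); the
# training objective is the arithmetic mean over heads of the per-head
# batch-mean loss (cross-entropy by default, focal optionally).

PROB_FLOOR <- 1e-12

softmaxRows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

initHead <- function(C, H) {
  list(W = matrix(stats::rnorm(C * H, sd = 0.02), C, H), b = numeric(C))
}

#' Construct a multi-head modifier classifier
#'
#' @param encoder a [PairEncoder-class].
#' @param schema a [ModifierSchema-class]; one head is created per modifier,
#'   in schema order.
#' @param maxTokens token budget for the encoded pair (default 144).
#' @param seed integer seed for head initialization.
#' @return a [MultiHeadModel-class].
#' @export
multiHeadModel <- function(encoder, schema, maxTokens = 144L, seed = 1L) {
  H <- encoderHiddenSize(encoder)
  heads <- withSeed(seed, lapply(schema@modifiers, function(mi)
    initHead(length(schema@labels[[mi]]), H)))
  names(heads) <- schema@modifiers
  new("MultiHeadModel", encoder = encoder, schema = schema, heads = heads,
      maxTokens = as.integer(maxTokens))
}

#' @describeIn modifiers MultiHeadModel method
#' @export
setMethod("modifiers", "MultiHeadModel", function(x) x@schema@modifiers)

#' @describeIn schemaOf MultiHeadModel method
#' @export
setMethod("schemaOf", "MultiHeadModel", function(x) x@schema)

#' Model components
#' @param x a [MultiHeadModel-class].
#' @return `modelEncoder`: the encoder.
#' @export
modelEncoder <- function(x) x@encoder

#' @rdname modelEncoder
#' @return `modelHeads`: named list of `list(W, b)` heads.
#' @export
modelHeads <- function(x) x@heads

setMethod("show", "MultiHeadModel", function(object) {
  cat(sprintf("MultiHeadModel: %d heads over a %d-dim pooled encoder (schema '%s')\n",
              length(object@heads), encoderHiddenSize(object@encoder),
              object@schema@name))
  for (mi in object@schema@modifiers)
    cat(sprintf("  head %-16s %d classes\n", mi,
                length(object@schema@labels[[mi]])))
  invisible(NULL)
})

#' Forward pass: per-modifier class distributions
#'
#' Encodes the examples once and applies every head to the shared pooled
#' vector. Each returned row is a softmax distribution (non-negative,
#' summing to 1).
#'
#' @param model a [MultiHeadModel-class].
#' @param examples an [ExampleSet-class] conforming to the model schema.
#' @param h optional pre-computed pooled matrix (rows = examples); when
#'   given, the encoder is not run.
#' @return named list (one element per modifier) of k x C probability
#'   matrices with the label strings as column names.
#' @export
modelForward <- function(model, examples = NULL, h = NULL) {
  if (is.null(h)) {
    if (!identical(examples@schema@modifiers, model@schema@modifiers))
      stop("examples do not conform to the model schema")
    h <- encodeBatch(model@encoder, examples@meta$left,
                     examples@meta$entity, model@maxTokens)
  }
  sch <- model@schema
  out <- lapply(sch@modifiers, function(mi) {
    hd <- model@heads[[mi]]
    p <- softmaxRows(sweep(h %*% t(hd$W), 2L, hd$b, `+`))
    colnames(p) <- sch@labels[[mi]]
    p
  })
  names(out) <- sch@modifiers
  out
}

#' Loss configuration
#' @param kind "cross_entropy" or "focal".
#' @param focalGamma focusing parameter gamma >= 0 for the focal loss
#'   (default 2, the canonical value; gamma = 0 recovers cross-entropy).
#' @return list with class "LossConfig".
#' @export
lossConfig <- function(kind = c("cross_entropy", "focal"),
                       focalGamma = 2) {
  kind <- match.arg(kind)
  stopifnot(focalGamma >= 0)
  structure(list(kind = kind, focalGamma = focalGamma),
            class = "LossConfig")
}

#' Per-head loss on a batch
#'
#' Cross-entropy: mean over the batch of -log p(gold). Focal: mean of
#' -(1 - p_gold)^gamma * log p_gold. Probabilities are floored at 1e-12
#' (with a warning) so degenerate encoders cannot produce infinities.
#'
#' @param prob k x C probability matrix (or a single probability vector).
#' @param gold integer vector of 1-based gold label indices.
#' @param config a [lossConfig()].
#' @return scalar loss.
#' @examples
#' headLoss(matrix(rep(1 / 3, 3), 1), 1L)  # uniform over 3: log(3)
#' @export
headLoss <- function(prob, gold, config = lossConfig()) {
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1L)
  stopifnot(nrow(prob) == length(gold))
  p <- prob[cbind(seq_len(nrow(prob)), gold)]
  if (any(p < PROB_FLOOR)) {
    warning("gold-class probability clamped at 1e-12")
    p <- pmax(p, PROB_FLOOR)
  }
  if (config$kind == "focal")
    mean(-(1 - p)^config$focalGamma * log(p))
  else
    mean(-log(p))
}

#' Multi-task loss: the mean of the per-head losses
#'
#' L = (1/n) * sum_i L_i over the n heads; every example contributes a gold
#' label to every head (defaults are materialized at featurization).
#'
#' @param model a [MultiHeadModel-class].
#' @param examples a non-empty [ExampleSet-class].
#' @param config a [lossConfig()].
#' @param probs optional precomputed [modelForward()] output.
#' @return scalar loss.
#' @export
multitaskLoss <- function(model, examples, config = lossConfig(),
                          probs = NULL) {
  if (nExamples(examples) == 0L) stop("empty batch")
  if (is.null(probs)) probs <- modelForward(model, examples)
  losses <- vapply(seq_along(probs), function(j)
    headLoss(probs[[j]], examples@labels[, j], config), numeric(1))
  mean(losses)
}

#' Decode predictions: per-head argmax
#'
#' Ties are broken toward the lowest class index, so decoding is
#' deterministic.
#'
#' @param model a [MultiHeadModel-class].
#' @param examples an [ExampleSet-class].
#' @param probs optional precomputed [modelForward()] output.
#' @return integer matrix (examples x modifiers) of 1-based predicted label
#'   indices.
#' @export
predictModifiers <- function(model, examples, probs = NULL) {
  if (is.null(probs)) probs <- modelForward(model, examples)
  out <- vapply(probs, function(p) max.col(p, ties.method = "first"),
                integer(nrow(probs[[1]])))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(probs)))
  out
}

#' Map predicted indices to label strings
#' @param schema a [ModifierSchema-class].
#' @param pred integer matrix from [predictModifiers()].
#' @return character data.frame, one column per modifier.
#' @export
decodePredictions <- function(schema, pred) {
  out <- as.data.frame(lapply(seq_along(schema@modifiers), function(j)
    schema@labels[[j]][pred[, j]]), stringsAsFactors = FALSE)
  names(out) <- schema@modifiers
  out
}

#' Write predictions as TSV
#' @param examples the [ExampleSet-class] that was decoded.
#' @param pred integer matrix from [predictModifiers()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePredictionsTsv <- function(examples, pred, path) {
  df <- cbind(data.frame(doc_id = examples@meta$docId,
                         entity_id = examples@meta$entityId,
                         stringsAsFactors = FALSE),
              decodePredictions(examples@schema, pred))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' One independent single-task model per modifier
#'
#' The single-task ablation: each modifier gets its own one-head model with
#' a fresh encoder instance, so no parameters are shared across modifiers.
#'
#' @param schema a [ModifierSchema-class].
#' @param encoderFactory function(modifierName) returning a fresh
#'   [PairEncoder-class].
#' @param maxTokens token budget (default 144).
#' @param seed integer; head seeds are derived per modifier.
#' @return named list of one-head [MultiHeadModel-class] objects.
#' @export
makeSingleTaskModels <- function(schema, encoderFactory, maxTokens = 144L,
                                 seed = 1L) {
  out <- lapply(seq_along(schema@modifiers), function(j) {
    mi <- schema@modifiers[j]
    sub <- modifierSchema(paste0(schema@name, ":", mi),
                          schema@labels[mi],
                          defaults = as.list(schema@defaults[mi]))
    multiHeadModel(encoderFactory(mi), sub, maxTokens = maxTokens,
                   seed = childSeed(seed, j))
  })
  names(out) <- schema@modifiers
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding the encoder in R's native serialized
#' form (`encoder.rds`) and a JSON manifest with the schema, the token
#' budget and every head's weights, keyed by modifier NAME so that transfer
#' can match heads by name rather than position.
#'
#' @param model a [MultiHeadModel-class].
#' @param dir checkpoint directory (created if needed).
#' @return `saveCheckpoint`: `dir`, invisibly.
#' @export
saveCheckpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sch <- model@schema
  manifest <- list(
    schema = list(
      name = sch@name,
      modifiers = lapply(sch@modifiers, function(mi) list(
        name = mi, labels = as.list(sch@labels[[mi]]),
        default_index = sch@defaults[[mi]]))),
    max_tokens = model@maxTokens,
    heads = lapply(sch@modifiers, function(mi) {
      hd <- model@heads[[mi]]
      list(name = mi, shape = dim(hd$W),
           W = as.numeric(t(hd$W)),  # row-major
           b = as.numeric(hd$b))
    }))
  # digits = I(17): significant-digit mode with enough digits for doubles
  # to round-trip bit-exactly through the manifest
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  saveRDS(model@encoder, file.path(dir, "encoder.rds"))
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @return `loadCheckpoint`: the reconstructed [MultiHeadModel-class].
#' @export
loadCheckpoint <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = FALSE)
  encoder <- readRDS(file.path(dir, "encoder.rds"))
  mods <- manifest$schema$modifiers
  labs <- stats::setNames(
    lapply(mods, function(m) as.character(unlist(m$labels))),
    vapply(mods, function(m) m$name, character(1)))
  defs <- stats::setNames(lapply(mods, function(m) m$default_index),
                          names(labs))
  sch <- modifierSchema(manifest$schema$name, labs, defaults = defs)
  heads <- lapply(manifest$heads, function(h) {
    shape <- as.integer(unlist(h$shape))
    list(W = matrix(as.numeric(unlist(h$W)), shape[1], shape[2],
                    byrow = TRUE),
         b = as.numeric(unlist(h$b)))
  })
  names(heads) <- vapply(manifest$heads, function(h) h$name, character(1))
  new("MultiHeadModel", encoder = encoder, schema = sch,
      heads = heads[sch@modifiers],
      maxTokens = as.integer(manifest$max_tokens))
}
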