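# Independent brute-force re-implementations of the evaluation metrics and
# small fixture builders. These are naive loops kept deliberately separate
# from the package's vectorized code paths.

naiveUnweightedAcc <- function(gold, pred) {
  hits <- 0L
  for (i in seq_along(gold)) if (pred[i] == gold[i]) hits <- hits + 1L
  hits / length(gold)
}

naiveWeightedAcc <- function(gold, pred, nClasses) {
  w <- numeric(nClasses)
  for (c in seq_len(nClasses)) {
    cnt <- 0L
    for (g in gold) if (g == c) cnt <- cnt + 1L
    w[c] <- 1 - cnt / length(gold)
  }
  num <- 0; den <- 0
  for (i in seq_along(gold)) {
    den <- den + w[gold[i]]
    if (pred[i] == gold[i]) num <- num + w[gold[i]]
  }
  if (den == 0) naiveUnweightedAcc(gold, pred) else num / den
}

naiveMicroF1 <- function(gold, pred, nClasses, defaultClass,
                         exclude = integer(0)) {
  tp <- fp <- fn <- 0L
  for (c in seq_len(nClasses)) {
    if (c == defaultClass || c %in% exclude) next
    for (i in seq_along(gold)) {
      if (pred[i] == c && gold[i] == c) tp <- tp + 1L
      if (pred[i] == c && gold[i] != c) fp <- fp + 1L
      if (gold[i] == c && pred[i] != c) fn <- fn + 1L
    }
  }
  if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
}

naiveMacroF1 <- function(gold, pred, nClasses, defaultClass,
                         includeDefault = TRUE) {
  f1s <- c()
  for (c in seq_len(nClasses)) {
    if (!includeDefault && c == defaultClass) next
    tp <- fp <- fn <- 0L
    for (i in seq_along(gold)) {
      if (pred[i] == c && gold[i] == c) tp <- tp + 1L
      if (pred[i] == c && gold[i] != c) fp <- fp + 1L
      if (gold[i] == c && pred[i] != c) fn <- fn + 1L
    }
    if (2 * tp + fp + fn == 0) next
    f1s <- c(f1s, 2 * tp / (2 * tp + fp + fn))
  }
  if (length(f1s)) mean(f1s) else NA_real_
}

naiveChiSquare <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# two-modifier schema used across unit tests
tinySchema <- function() {
  modifierSchema("tiny",
                 list(negation = c("no", "yes"),
                      severity = c("unmarked", "slight", "severe")))
}

# a constant encoder: returns preset pooled rows regardless of the input,
# to probe the head mathematics in isolation
setClass("ConstEncoder", contains = "PairEncoder",
         representation(h = "matrix"))
setMethod("encoderHiddenSize", "ConstEncoder", function(encoder)
  ncol(encoder@h))
setMethod("encodeBatch", "ConstEncoder",
  function(encoder, left, entity, maxTokens)
    encoder@h[rep_len(seq_len(nrow(encoder@h)), length(left)), ,
              drop = FALSE])

constModel <- function(h, schema, heads = NULL, seed = 1L) {
  m <- multiHeadModel(new("ConstEncoder", h = h), schema, seed = seed)
  if (!is.null(heads)) m@heads[names(heads)] <- heads
  m
}

# example set with given label matrix and trivial text
madeExamples <- function(schema, labels) {
  n <- nrow(labels)
  meta <- data.frame(docId = sprintf("d%d", seq_len(n)),
                     entityId = sprintf("e%d", seq_len(n)),
                     left = rep("ctx", n), entity = rep("ent", n),
                     stringsAsFactors = FALSE)
  new("ExampleSet", schema = schema, meta = meta,
      labels = matrix(as.integer(labels), nrow = n, ncol = ncol(labels),
                      dimnames = list(NULL, schema@modifiers)))
}
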