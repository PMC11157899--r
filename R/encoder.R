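# The compact trainable sequence-pair encoder.
#
# Trainable token embeddings are mean-pooled separately over the left
# (context) segment and the entity segment; the two segment means are
# concatenated and projected through a tanh layer to the pooled vector fed
# to every classification head. Modifier cues in clinical text are short
# lexical triggers, so a position-insensitive pooled representation is a
# deliberately small but trainable stand-in that honors the PairEncoder
# contract; heavier encoders (pretrained transformers served by an external
# runtime) can be plugged in by implementing the same generics.

#' Construct a TinyEncoder
#'
#' @param texts character vector used to build the token vocabulary
#'   (typically the training left and entity sequences), or NULL if `vocab`
#'   is given.
#' @param vocab character vector of tokens (overrides `texts`).
#' @param embedDim embedding dimension (default 32).
#' @param hidden pooled output dimension H (default 64).
#' @param maxVocab cap on vocabulary size; most frequent tokens kept.
#' @param seed integer seed for the parameter initialization.
#' @return a [TinyEncoder-class].
#' @examples
#' enc <- tinyEncoder(c("patient denies fever", "fever improving"), seed = 1)
#' dim(encodeBatch(enc, "patient denies fever", "fever", 144L))
#' @export
tinyEncoder <- function(texts = NULL, vocab = NULL, embedDim = 32L,
                        hidden = 64L, maxVocab = 20000L, seed = 1L) {
  if (is.null(vocab)) {
    if (is.null(texts)) stop("provide `texts` or `vocab`")
    toks <- unlist(tokenizeText(texts), use.names = FALSE)
    tab <- sort(table(toks), decreasing = TRUE)
    vocab <- names(tab)[seq_len(min(length(tab), maxVocab))]
  }
  embedDim <- as.integer(embedDim); hidden <- as.integer(hidden)
  V <- length(vocab)
  params <- withSeed(seed, list(
    E = matrix(stats::rnorm((V + 1L) * embedDim, sd = 0.5),
               V + 1L, embedDim),
    Wp = matrix(stats::rnorm(hidden * 2L * embedDim,
                             sd = 1 / sqrt(2 * embedDim)),
                hidden, 2L * embedDim),
    bp = numeric(hidden)))
  new("TinyEncoder", vocab = vocab, embedDim = embedDim, hidden = hidden,
      params = params)
}

#' @describeIn encoderHiddenSize TinyEncoder method
#' @export
setMethod("encoderHiddenSize", "TinyEncoder", function(encoder)
  encoder@hidden)

# token ids: 1 = unknown, i+1 = vocab[i]
tokenIds <- function(encoder, texts) {
  lapply(tokenizeText(texts), function(t) {
    id <- match(t, encoder@vocab)
    id[is.na(id)] <- 0L
    id + 1L
  })
}

#' @describeIn encoderPrepare TinyEncoder method: tokenizes both segments
#'   and applies the token budget (left edge of the left segment truncated
#'   first; the entity segment only when the left segment is exhausted).
#' @export
setMethod("encoderPrepare", "TinyEncoder",
  function(encoder, left, entity, maxTokens) {
    stopifnot(length(left) == length(entity), maxTokens >= 8L)
    leftIds <- tokenIds(encoder, left)
    entIds <- tokenIds(encoder, entity)
    budget <- as.integer(maxTokens) - 3L
    for (i in seq_along(leftIds)) {
      ne <- length(entIds[[i]])
      if (ne >= budget) {
        entIds[[i]] <- entIds[[i]][seq_len(budget)]
        leftIds[[i]] <- integer(0)
      } else {
        keep <- budget - ne
        nl <- length(leftIds[[i]])
        if (nl > keep)
          leftIds[[i]] <- leftIds[[i]][(nl - keep + 1L):nl]
      }
    }
    list(leftIds = leftIds, entIds = entIds, n = length(leftIds))
  })

# mean embedding per example over a ragged id list
segMeans <- function(E, ids) {
  k <- length(ids); D <- ncol(E)
  Z <- matrix(0, k, D)
  lens <- lengths(ids)
  nz <- which(lens > 0L)
  if (length(nz)) {
    flat <- unlist(ids[nz], use.names = FALSE)
    rows <- rep.int(nz, lens[nz])
    S <- rowsum(E[flat, , drop = FALSE] / lens[rows], group = rows)
    Z[as.integer(rownames(S)), ] <- S
  }
  Z
}

# scatter segment-mean gradients back onto the embedding table
segBackward <- function(dZ, ids, nRows) {
  dE <- matrix(0, nRows, ncol(dZ))
  lens <- lengths(ids)
  nz <- which(lens > 0L)
  if (length(nz)) {
    flat <- unlist(ids[nz], use.names = FALSE)
    rows <- rep.int(nz, lens[nz])
    S <- rowsum(dZ[rows, , drop = FALSE] / lens[rows], group = flat)
    dE[as.integer(rownames(S)), ] <- S
  }
  dE
}

#' @describeIn encoderForward TinyEncoder method
#' @export
setMethod("encoderForward", "TinyEncoder",
  function(encoder, prepared, idx) {
    p <- encoder@params
    lids <- prepared$leftIds[idx]
    eids <- prepared$entIds[idx]
    Zl <- segMeans(p$E, lids)
    Ze <- segMeans(p$E, eids)
    z <- cbind(Zl, Ze)
    h <- tanh(sweep(z %*% t(p$Wp), 2L, p$bp, `+`))
    list(h = h, cache = list(z = z, h = h, lids = lids, eids = eids))
  })

#' @describeIn encoderBackward TinyEncoder method
#' @export
setMethod("encoderBackward", "TinyEncoder",
  function(encoder, cache, dh) {
    p <- encoder@params
    D <- encoder@embedDim
    da <- dh * (1 - cache$h^2)
    dWp <- t(da) %*% cache$z
    dbp <- colSums(da)
    dz <- da %*% p$Wp
    dE <- segBackward(dz[, seq_len(D), drop = FALSE], cache$lids,
                      nrow(p$E)) +
          segBackward(dz[, D + seq_len(D), drop = FALSE], cache$eids,
                      nrow(p$E))
    list(E = dE, Wp = dWp, bp = dbp)
  })

#' @describeIn encoderParams TinyEncoder method
#' @export
setMethod("encoderParams", "TinyEncoder", function(encoder)
  encoder@params)

#' @describeIn encoderWithParams TinyEncoder method
#' @export
setMethod("encoderWithParams", "TinyEncoder", function(encoder, params) {
  encoder@params <- params
  encoder
})

#' @describeIn encodeBatch TinyEncoder method
#' @export
setMethod("encodeBatch", "TinyEncoder",
  function(encoder, left, entity, maxTokens) {
    prepared <- encoderPrepare(encoder, left, entity, maxTokens)
    encoderForward(encoder, prepared, seq_len(prepared$n))$h
  })

setMethod("show", "TinyEncoder", function(object) {
  cat(sprintf("TinyEncoder: |vocab| = %d, embedDim = %d, hidden = %d\n",
              length(object@vocab), object@embedDim, object@hidden))
  invisible(NULL)
})
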