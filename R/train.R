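# Supervised fine-tuning with decoupled weight decay (AdamW), early
# stopping on dev accuracy, and the transfer-learning procedures
# (name-matched head copy; combined-corpus training is served by
# mergeCorpora + ordinary training).

#' Training configuration
#'
#' Defaults mirror the fine-tuning recipe for a large pretrained encoder:
#' learning rate 2e-5, weight decay 1e-2, batch size 64, at most 10 epochs
#' with early stopping, token budget 144. The early-stop rule — monitor dev
#' unweighted accuracy macro-averaged over heads, strict improvement,
#' patience in epochs, keep the best checkpoint — is this package's
#' assumption; see the methods vignette.
#'
#' @param learningRate AdamW step size.
#' @param weightDecay decoupled weight decay, applied to weight matrices
#'   (not biases).
#' @param batchSize minibatch size.
#' @param maxEpochs maximum epochs.
#' @param maxTokens token budget for the encoded pair.
#' @param patience epochs without dev improvement before stopping.
#' @param seed master seed; data order, dropout and initialization derive
#'   from it, so (seed, data, config) fully determines the trained model.
#' @param loss a [lossConfig()].
#' @param dropout dropout rate on the pooled vector before the heads.
#' @param warmupFraction fraction of total steps with linear learning-rate
#'   warmup (0 disables; constant rate afterwards).
#' @param verbose print per-epoch loss and dev metrics.
#' @return list with class "TrainConfig".
#' @export
trainConfig <- function(learningRate = 2e-5, weightDecay = 1e-2,
                        batchSize = 64L, maxEpochs = 10L,
                        maxTokens = 144L, patience = 3L, seed = 1L,
                        loss = lossConfig(), dropout = 0.1,
                        warmupFraction = 0, verbose = FALSE) {
  stopifnot(learningRate > 0, weightDecay >= 0, batchSize >= 1,
            maxEpochs >= 1, maxTokens >= 8, patience >= 1,
            patience <= maxEpochs, dropout >= 0, dropout < 1)
  structure(list(learningRate = learningRate, weightDecay = weightDecay,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 maxTokens = as.integer(maxTokens),
                 patience = as.integer(patience), seed = as.integer(seed),
                 loss = loss, dropout = dropout,
                 warmupFraction = warmupFraction, verbose = verbose),
            class = "TrainConfig")
}

#' Training configuration tuned for the compact encoder
#'
#' The [tinyEncoder()] is trained from scratch, so it uses a from-scratch
#' Adam step size (3e-2, chosen for stable convergence of the compact
#' bag-of-embeddings architecture at desk scale) instead of the 2e-5
#' fine-tuning rate appropriate for a pretrained transformer. All other
#' knobs match [trainConfig()].
#'
#' @param ... overrides passed to [trainConfig()].
#' @return list with class "TrainConfig".
#' @export
tinyTrainConfig <- function(...) {
  args <- list(...)
  defaults <- list(learningRate = 3e-2)
  do.call(trainConfig, utils::modifyList(defaults, args))
}

# Early-stop bookkeeping on a dev-metric sequence: returns the epoch whose
# weights are kept and how many epochs run before stopping.
earlyStopDecision <- function(devMetric, patience) {
  best <- -Inf; bestEpoch <- 0L; since <- 0L; ran <- 0L
  for (e in seq_along(devMetric)) {
    ran <- e
    if (devMetric[e] > best) {
      best <- devMetric[e]; bestEpoch <- e; since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) break
    }
  }
  list(selected = bestEpoch, ran = ran)
}

# ---- AdamW over a flat named parameter list --------------------------------

adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamwStep <- function(params, grads, state, lr, weightDecay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      decayMask) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    wd <- if (decayMask[[nm]]) weightDecay else 0
    params[[nm]] <- params[[nm]] - lr * upd - lr * wd * params[[nm]]
  }
  list(params = params, state = state)
}

# flatten model parameters to a named list and back
flattenParams <- function(model) {
  out <- encoderParams(model@encoder)
  names(out) <- paste0("enc.", names(out))
  for (mi in names(model@heads)) {
    out[[paste0("head.", mi, ".W")]] <- model@heads[[mi]]$W
    out[[paste0("head.", mi, ".b")]] <- model@heads[[mi]]$b
  }
  out
}

unflattenParams <- function(model, flat) {
  encNames <- names(encoderParams(model@encoder))
  enc <- stats::setNames(flat[paste0("enc.", encNames)], encNames)
  model@encoder <- encoderWithParams(model@encoder, enc)
  for (mi in names(model@heads)) {
    model@heads[[mi]]$W <- flat[[paste0("head.", mi, ".W")]]
    model@heads[[mi]]$b <- flat[[paste0("head.", mi, ".b")]]
  }
  model
}

# gradient of the multitask loss w.r.t. a head's logits; `prob` k x C,
# `gold` indices; returns the k x C logit gradient already scaled by
# 1/(batch k) and 1/(number of heads n)
logitGrad <- function(prob, gold, loss, nHeads) {
  k <- nrow(prob)
  g <- prob[cbind(seq_len(k), gold)]
  gc <- pmax(g, PROB_FLOOR)
  dfdp <- if (loss$kind == "focal") {
    gam <- loss$focalGamma
    gam * (1 - g)^(pmax(gam - 1, 0)) * log(gc) - (1 - g)^gam / gc
  } else -1 / gc
  dl <- -prob * (dfdp * g)
  dl[cbind(seq_len(k), gold)] <- dl[cbind(seq_len(k), gold)] + dfdp * g
  dl / (k * nHeads)
}

# per-modifier unweighted accuracy of a model on an example set
devAccuracy <- function(model, examples) {
  pred <- predictModifiers(model, examples)
  vapply(seq_len(ncol(pred)), function(j)
    mean(pred[, j] == examples@labels[, j]), numeric(1))
}

#' Fine-tune a multi-head model
#'
#' AdamW optimization of encoder and heads against [multitaskLoss()]. After
#' every epoch the dev unweighted accuracy, macro-averaged over heads, is
#' computed; training stops at `maxEpochs` or when the dev metric fails to
#' improve for `patience` consecutive epochs, and the best-dev weights are
#' returned. With an empty/NULL dev set there is no early stop and the
#' final weights are kept. Fully deterministic given `config$seed`.
#'
#' @param model a [MultiHeadModel-class] whose encoder implements the
#'   trainable-encoder generics.
#' @param trainSet non-empty [ExampleSet-class] conforming to the model.
#' @param devSet optional [ExampleSet-class] for early stopping.
#' @param config a [trainConfig()] / [tinyTrainConfig()].
#' @param mode report label: "early_stop"/"fixed" (chosen automatically) or
#'   "final" from [trainFinal()].
#' @return list(model = trained [MultiHeadModel-class],
#'   report = [TrainReport-class]).
#' @export
trainModel <- function(model, trainSet, devSet = NULL,
                       config = trainConfig(), mode = NULL) {
  if (!identical(trainSet@schema@modifiers, model@schema@modifiers))
    stop("training examples do not conform to the model schema")
  if (nExamples(trainSet) == 0L) stop("empty training set")
  hasDev <- !is.null(devSet) && nExamples(devSet) > 0L
  if (hasDev && !identical(devSet@schema@modifiers, model@schema@modifiers))
    stop("dev examples do not conform to the model schema")
  model@maxTokens <- config$maxTokens
  sch <- model@schema
  n <- nExamples(trainSet)
  nHeads <- length(sch@modifiers)

  prepared <- encoderPrepare(model@encoder, trainSet@meta$left,
                             trainSet@meta$entity, config$maxTokens)
  flat <- flattenParams(model)
  decayMask <- vapply(flat, function(p) !is.null(dim(p)), logical(1))
  state <- adamwInit(flat)
  totalSteps <- config$maxEpochs * ceiling(n / config$batchSize)
  warmSteps <- floor(config$warmupFraction * totalSteps)

  trainLoss <- numeric(0)
  devMetric <- matrix(numeric(0), nrow = 0, ncol = nHeads,
                      dimnames = list(NULL, sch@modifiers))
  devMacro <- numeric(0)
  epochSecs <- numeric(0)
  best <- -Inf; bestFlat <- flat; bestEpoch <- 0L; since <- 0L
  step <- 0L

  for (epoch in seq_len(config$maxEpochs)) {
    t0 <- proc.time()[["elapsed"]]
    epochLoss <- withSeed(childSeed(config$seed, epoch), {
      perm <- sample.int(n)
      batchLosses <- numeric(0)
      for (b in seq_len(ceiling(n / config$batchSize))) {
        idx <- perm[((b - 1L) * config$batchSize + 1L):
                      min(b * config$batchSize, n)]
        k <- length(idx)
        fw <- encoderForward(
          encoderWithParams(model@encoder,
            stats::setNames(flat[paste0("enc.",
              names(encoderParams(model@encoder)))],
              names(encoderParams(model@encoder)))),
          prepared, idx)
        h <- fw$h
        mask <- NULL
        if (config$dropout > 0) {
          mask <- matrix(stats::runif(length(h)) >= config$dropout,
                         nrow(h), ncol(h)) / (1 - config$dropout)
          h <- h * mask
        }
        grads <- lapply(flat, function(p) p * 0)
        dh <- h * 0
        loss <- 0
        for (j in seq_len(nHeads)) {
          mi <- sch@modifiers[j]
          W <- flat[[paste0("head.", mi, ".W")]]
          bb <- flat[[paste0("head.", mi, ".b")]]
          prob <- softmaxRows(sweep(h %*% t(W), 2L, bb, `+`))
          gold <- trainSet@labels[idx, j]
          loss <- loss + headLoss(prob, gold, config$loss) / nHeads
          dl <- logitGrad(prob, gold, config$loss, nHeads)
          grads[[paste0("head.", mi, ".W")]] <- t(dl) %*% h
          grads[[paste0("head.", mi, ".b")]] <- colSums(dl)
          dh <- dh + dl %*% W
        }
        if (!is.null(mask)) dh <- dh * mask
        encGrads <- encoderBackward(model@encoder, fw$cache, dh)
        for (nm in names(encGrads))
          grads[[paste0("enc.", nm)]] <- encGrads[[nm]]
        step <- step + 1L
        lr <- if (step <= warmSteps)
          config$learningRate * step / warmSteps else config$learningRate
        upd <- adamwStep(flat, grads, state, lr, config$weightDecay,
                         decayMask = decayMask)
        flat <- upd$params
        state <- upd$state
        batchLosses <- c(batchLosses, loss)
      }
      mean(batchLosses)
    })
    trainLoss <- c(trainLoss, epochLoss)
    epochSecs <- c(epochSecs, proc.time()[["elapsed"]] - t0)

    if (hasDev) {
      cur <- unflattenParams(model, flat)
      acc <- devAccuracy(cur, devSet)
      devMetric <- rbind(devMetric, acc)
      macro <- mean(acc)
      devMacro <- c(devMacro, macro)
      if (config$verbose)
        message(sprintf("epoch %d: loss %.4f, dev macro acc %.4f",
                        epoch, epochLoss, macro))
      if (macro > best) {
        best <- macro; bestFlat <- flat; bestEpoch <- epoch; since <- 0L
      } else {
        since <- since + 1L
        if (since >= config$patience) break
      }
    } else {
      if (config$verbose)
        message(sprintf("epoch %d: loss %.4f", epoch, epochLoss))
      bestFlat <- flat; bestEpoch <- epoch
    }
  }

  rownames(devMetric) <- NULL
  report <- new("TrainReport", trainLoss = trainLoss,
                devMetric = devMetric, devMacro = devMacro,
                selectedEpoch = bestEpoch,
                mode = if (!is.null(mode)) mode
                       else if (hasDev) "early_stop" else "fixed",
                epochSeconds = epochSecs)
  list(model = unflattenParams(model, bestFlat), report = report)
}

#' Retrain on train + dev for a fixed epoch count
#'
#' The final-model protocol: after an early-stopped run has selected an
#' epoch count, the training and development sets are combined and the
#' model is retrained for exactly that many epochs.
#'
#' @param model an untrained [MultiHeadModel-class] (fresh initialization).
#' @param trainSet,devSet [ExampleSet-class] objects; their union is the
#'   training data.
#' @param config a [trainConfig()].
#' @param epochs the epoch count selected by the prior early-stopped run.
#' @return list(model, report) with report mode "final".
#' @export
trainFinal <- function(model, trainSet, devSet, config, epochs) {
  union <- if (!is.null(devSet) && nExamples(devSet) > 0L)
    bindExamples(trainSet, devSet) else trainSet
  config$maxEpochs <- as.integer(epochs)
  config$patience <- min(config$patience, config$maxEpochs)
  trainModel(model, union, devSet = NULL, config = config, mode = "final")
}

#' Initialize a target-schema model from a source checkpoint
#'
#' The transfer-learning initialization: the encoder is copied verbatim
#' from the source; each target modifier whose NAME matches a source head
#' with an exactly matching label list (and default) gets that head's
#' weights verbatim; every other target head is freshly initialized from
#' the seeded initializer. Source-only heads are dropped, so the result has
#' exactly one head per target modifier. A name match with a different
#' label list is an error naming the modifier — silent partial copies would
#' scramble class indices.
#'
#' @param source a trained [MultiHeadModel-class] or a checkpoint directory
#'   from [saveCheckpoint()].
#' @param targetSchema the target [ModifierSchema-class].
#' @param seed integer seed for the fresh-head initializer.
#' @return a [MultiHeadModel-class] over `targetSchema`.
#' @export
transferInit <- function(source, targetSchema, seed = 1L) {
  if (is.character(source)) source <- loadCheckpoint(source)
  src <- source@schema
  model <- multiHeadModel(source@encoder, targetSchema,
                          maxTokens = source@maxTokens, seed = seed)
  for (mi in targetSchema@modifiers) {
    if (!mi %in% src@modifiers) next
    same <- identical(src@labels[[mi]], targetSchema@labels[[mi]]) &&
      src@defaults[[mi]] == targetSchema@defaults[[mi]]
    if (!same)
      stop(sprintf(
        "modifier '%s' exists in both schemas with different label lists",
        mi))
    model@heads[[mi]] <- source@heads[[mi]]
  }
  model
}

#' First epoch at which dev accuracy reaches a threshold
#'
#' Convenience for convergence comparisons (e.g. transfer-initialized vs
#' scratch training): the first epoch whose dev accuracy, averaged over the
#' given modifiers, is at least `threshold`; `Inf` if never reached.
#'
#' @param report a [TrainReport-class] from a run with a dev set.
#' @param mods modifier names to average over (default: all).
#' @param threshold accuracy threshold.
#' @return numeric(1) epoch index or Inf.
#' @export
epochsToThreshold <- function(report, mods = NULL, threshold = 0.9) {
  m <- report@devMetric
  if (!nrow(m)) return(Inf)
  if (!is.null(mods)) m <- m[, mods, drop = FALSE]
  hit <- which(rowMeans(m) >= threshold)
  if (length(hit)) hit[1] else Inf
}

setMethod("show", "TrainReport", function(object) {
  cat(sprintf("TrainReport (%s): %d epoch(s), selected epoch %d\n",
              object@mode, length(object@trainLoss),
              object@selectedEpoch))
  if (length(object@devMacro))
    cat(sprintf("  dev macro accuracy: %s\n",
                paste(sprintf("%.3f", object@devMacro), collapse = " ")))
  invisible(NULL)
})
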