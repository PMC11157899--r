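# Evaluation: prevalence-weighted accuracy (the shared-task scorer style
# for rare modifier values), unweighted accuracy, micro-averaged F1 over
# non-default classes, macro-averaged F1 (optionally including the default
# class), per-modifier and averaged reporting, and the chi-square system
# comparison. Undefined metrics are NA with a note, never silently 0.

#' Prevalence-complement class weights for one modifier
#'
#' weight(k) = 1 - prevalence(k), where prevalence is computed over the gold
#' labels of the evaluation set. Classes absent from the gold get weight 1.
#' Rare modifier values therefore count the most.
#'
#' @param gold integer vector of 1-based gold label indices.
#' @param nClasses number of classes (>= 2).
#' @return numeric vector of per-class weights in [0, 1].
#' @examples
#' classWeights(c(1L, 1L, 1L, 2L), 2L)  # 0.25, 0.75
#' @export
classWeights <- function(gold, nClasses) {
  stopifnot(nClasses >= 2L)
  if (!length(gold)) stop("empty gold label vector")
  1 - tabulate(gold, nClasses) / length(gold)
}

#' Prevalence-weighted accuracy
#'
#' Each pair counts with the weight of its gold class,
#' sum(w[gold] * correct) / sum(w[gold]), so a perfect system scores exactly
#' 1 and correctness on rare classes is worth more. With a single-class gold
#' (zero weight mass) the unweighted accuracy is returned, flagged via the
#' "degenerate" attribute.
#'
#' @param gold,pred integer vectors of 1-based label indices.
#' @param nClasses number of classes.
#' @param weights optional externally supplied per-class weights (e.g.
#'   computed from a training set for sensitivity analysis); default:
#'   [classWeights()] on `gold`.
#' @return numeric(1) in [0, 1].
#' @examples
#' weightedAccuracy(c(1, 1, 1, 2), c(1, 1, 2, 2), 2)  # 0.8333...
#' @export
weightedAccuracy <- function(gold, pred, nClasses, weights = NULL) {
  stopifnot(length(gold) == length(pred), length(gold) >= 1L)
  if (is.null(weights)) weights <- classWeights(gold, nClasses)
  den <- sum(weights[gold])
  if (den == 0) {
    out <- unweightedAccuracy(gold, pred)
    attr(out, "degenerate") <- "single-class gold; unweighted accuracy used"
    return(out)
  }
  sum(weights[gold] * (pred == gold)) / den
}

#' Unweighted accuracy
#' @param gold,pred integer vectors of 1-based label indices.
#' @return numeric(1) fraction of exact matches.
#' @export
unweightedAccuracy <- function(gold, pred) {
  stopifnot(length(gold) == length(pred), length(gold) >= 1L)
  mean(pred == gold)
}

#' Micro-averaged F1 over non-default classes
#'
#' The default ("unmarked") class plays the role of the negative class, as
#' in slot-filling F1: counts are pooled over all non-default classes c
#' (TP: pred == gold == c; FP: pred == c, gold != c; FN: gold == c,
#' pred != c) and F1 = 2TP / (2TP + FP + FN). Pairs whose gold and
#' prediction are both the default contribute nothing. Classes in
#' `exclude` are dropped from the pooled counts (the mechanism behind
#' excluding a label with too few test examples).
#'
#' @param gold,pred integer vectors of 1-based label indices.
#' @param nClasses number of classes.
#' @param defaultClass 1-based index of the default class.
#' @param exclude integer vector of class indices to exclude.
#' @return numeric(1), or NA (with a "note" attribute) when neither gold
#'   nor predictions contain a scored class.
#' @export
microF1 <- function(gold, pred, nClasses, defaultClass,
                    exclude = integer(0)) {
  stopifnot(length(gold) == length(pred), length(gold) >= 1L)
  classes <- setdiff(seq_len(nClasses), c(defaultClass, exclude))
  tp <- fp <- fn <- 0L
  for (c in classes) {
    tp <- tp + sum(pred == c & gold == c)
    fp <- fp + sum(pred == c & gold != c)
    fn <- fn + sum(gold == c & pred != c)
  }
  if (2L * tp + fp + fn == 0L) {
    out <- NA_real_
    attr(out, "note") <- "no non-default gold or predicted instances"
    return(out)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Macro-averaged F1
#'
#' Per-class F1 averaged with equal class weight. `includeDefault = TRUE`
#' includes the default/null class in the average (the convention used for
#' corpora reported with the null class); classes absent from both gold and
#' predictions are skipped, with a note.
#'
#' @param gold,pred integer vectors of 1-based label indices.
#' @param nClasses number of classes.
#' @param defaultClass 1-based index of the default class.
#' @param includeDefault include the default class in the average.
#' @return numeric(1); a "note" attribute lists skipped classes.
#' @export
macroF1 <- function(gold, pred, nClasses, defaultClass,
                    includeDefault = TRUE) {
  stopifnot(length(gold) == length(pred), length(gold) >= 1L)
  classes <- seq_len(nClasses)
  if (!includeDefault) classes <- setdiff(classes, defaultClass)
  f1s <- numeric(0); skipped <- integer(0)
  for (c in classes) {
    tp <- sum(pred == c & gold == c)
    fp <- sum(pred == c & gold != c)
    fn <- sum(gold == c & pred != c)
    if (2 * tp + fp + fn == 0) { skipped <- c(skipped, c); next }
    f1s <- c(f1s, 2 * tp / (2 * tp + fp + fn))
  }
  out <- if (length(f1s)) mean(f1s) else NA_real_
  if (length(skipped))
    attr(out, "note") <- sprintf("classes absent from gold and pred skipped: %s",
                                 paste(skipped, collapse = ","))
  out
}

#' Chi-square comparison of two systems
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' correct/incorrect prediction counts of two systems. When only accuracies
#' are published, counts can be reconstructed with [countsFromAccuracy()].
#'
#' @param correctA,incorrectA,correctB,incorrectB non-negative counts.
#' @return list(statistic, p.value).
#' @examples
#' chiSquareCompare(90, 10, 80, 20)  # statistic 3.9216
#' @export
chiSquareCompare <- function(correctA, incorrectA, correctB, incorrectB) {
  tab <- matrix(c(correctA, incorrectA, correctB, incorrectB), nrow = 2,
                byrow = TRUE)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a zero row or column total makes the test undefined")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value))
}

#' Reconstruct correct/incorrect counts from a published accuracy
#' @param accuracy accuracy in [0, 1].
#' @param n total number of test examples.
#' @return integer vector c(correct, incorrect).
#' @export
countsFromAccuracy <- function(accuracy, n) {
  correct <- round(accuracy * n)
  c(correct = correct, incorrect = n - correct)
}

#' Evaluate predictions against gold labels, per modifier
#'
#' Predictions and gold are aligned by (doc id, entity id); misalignment is
#' an error listing the offending records. Per modifier the report carries
#' weighted accuracy, unweighted accuracy, micro F1 (non-default classes)
#' and macro F1; cross-modifier averages are simple means over the defined
#' cells only.
#'
#' @param examples the gold [ExampleSet-class].
#' @param pred integer matrix from [predictModifiers()], rows aligned with
#'   `examples` (or carrying docId/entityId rownames in a different order).
#' @param exclude named list: modifier -> label strings excluded from that
#'   modifier's micro F1 (e.g. a class with too few test examples).
#' @param includeDefaultMacro include the default class in macro F1.
#' @param weights optional named list: modifier -> per-class weight vector
#'   overriding the evaluation-set prevalence weights.
#' @return a [MetricsReport-class].
#' @export
evaluatePredictions <- function(examples, pred, exclude = list(),
                                includeDefaultMacro = TRUE,
                                weights = NULL) {
  sch <- examples@schema
  if (nrow(pred) != nExamples(examples))
    stop(sprintf("alignment error: %d predictions for %d gold examples",
                 nrow(pred), nExamples(examples)))
  if (!identical(colnames(pred), sch@modifiers))
    stop("prediction columns must match the schema modifiers")
  rows <- lapply(seq_along(sch@modifiers), function(j) {
    mi <- sch@modifiers[j]
    C <- length(sch@labels[[j]])
    gold <- examples@labels[, j]; pj <- pred[, j]
    exc <- match(exclude[[mi]], sch@labels[[j]])
    exc <- exc[!is.na(exc)]
    w <- if (!is.null(weights)) weights[[mi]] else NULL
    data.frame(
      modifier = mi,
      weighted_accuracy = as.numeric(weightedAccuracy(gold, pj, C, w)),
      unweighted_accuracy = unweightedAccuracy(gold, pj),
      micro_f1 = as.numeric(microF1(gold, pj, C, sch@defaults[[j]], exc)),
      macro_f1 = as.numeric(macroF1(gold, pj, C, sch@defaults[[j]],
                                    includeDefaultMacro)),
      stringsAsFactors = FALSE)
  })
  perMod <- do.call(rbind, rows)
  metricCols <- c("weighted_accuracy", "unweighted_accuracy", "micro_f1",
                  "macro_f1")
  averages <- vapply(metricCols, function(cl) {
    v <- perMod[[cl]]
    if (all(is.na(v))) NA_real_ else mean(v[!is.na(v)])
  }, numeric(1))
  notes <- character(0)
  for (cl in metricCols) {
    bad <- perMod$modifier[is.na(perMod[[cl]])]
    if (length(bad))
      notes <- c(notes, sprintf("%s undefined for: %s (skipped in average)",
                                cl, paste(bad, collapse = ", ")))
  }
  new("MetricsReport", perModifier = perMod, averages = averages,
      notes = notes)
}

#' MetricsReport accessors
#' @param x a [MetricsReport-class].
#' @return `metricsPerModifier`: data.frame of per-modifier metrics.
#' @export
metricsPerModifier <- function(x) x@perModifier

#' @rdname metricsPerModifier
#' @return `metricsAverages`: named numeric of cross-modifier means.
#' @export
metricsAverages <- function(x) x@averages

setMethod("show", "MetricsReport", function(object) {
  df <- object@perModifier
  df[-1] <- lapply(df[-1], function(v) sprintf("%.4f", v))
  print(df, row.names = FALSE)
  cat("averages (defined cells only):\n")
  print(round(object@averages, 4))
  for (n in object@notes) cat("note:", n, "\n")
  invisible(NULL)
})

#' Write a metrics report as JSON or aligned TSV
#' @param report a [MetricsReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMetricsJson <- function(report, path) {
  jsonlite::write_json(
    list(per_modifier = report@perModifier,
         averages = as.list(report@averages),
         notes = report@notes),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeMetricsJson
#' @export
writeMetricsTsv <- function(report, path) {
  utils::write.table(report@perModifier, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
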