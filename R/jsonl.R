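# Canonical JSON-lines example format: one object per line with keys
# doc_id, entity_id, left_sequence, entity_sequence, labels (an object
# mapping every schema modifier name to its gold label string). UTF-8.

#' Write featurized examples as JSON lines
#'
#' @param examples an [ExampleSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExamplesJsonl <- function(examples, path) {
  sch <- examples@schema
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- examples@meta
  labs <- examples@labels
  for (i in seq_len(nrow(meta))) {
    lab <- lapply(seq_along(sch@modifiers), function(j)
      sch@labels[[j]][labs[i, j]])
    names(lab) <- sch@modifiers
    rec <- list(doc_id = meta$docId[i], entity_id = meta$entityId[i],
                left_sequence = meta$left[i],
                entity_sequence = meta$entity[i], labels = lab)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read JSON-lines examples
#'
#' Round-trips [writeExamplesJsonl()] losslessly. Every record must carry a
#' label for every schema modifier; a missing key or an unknown label is a
#' schema error naming the line.
#'
#' @param path input file path.
#' @param schema the governing [ModifierSchema-class].
#' @return an [ExampleSet-class].
#' @export
readExamplesJsonl <- function(path, schema) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  meta <- data.frame(docId = character(n), entityId = character(n),
                     left = character(n), entity = character(n),
                     stringsAsFactors = FALSE)
  labs <- matrix(0L, nrow = n, ncol = length(schema@modifiers),
                 dimnames = list(NULL, schema@modifiers))
  for (i in seq_len(n)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop(sprintf("line %d: malformed JSON (%s)",
                                   i, conditionMessage(e))))
    need <- c("doc_id", "entity_id", "left_sequence", "entity_sequence",
              "labels")
    if (!all(need %in% names(rec)))
      stop(sprintf("line %d: missing field(s) %s", i,
                   paste(setdiff(need, names(rec)), collapse = ", ")))
    meta$docId[i] <- rec$doc_id
    meta$entityId[i] <- rec$entity_id
    meta$left[i] <- rec$left_sequence
    meta$entity[i] <- rec$entity_sequence
    for (j in seq_along(schema@modifiers)) {
      mi <- schema@modifiers[j]
      if (!mi %in% names(rec$labels))
        stop(sprintf("line %d: record is missing schema modifier '%s'",
                     i, mi))
      k <- match(rec$labels[[mi]], schema@labels[[mi]])
      if (is.na(k))
        stop(sprintf("line %d: '%s' is not a label of modifier '%s'",
                     i, rec$labels[[mi]], mi))
      labs[i, j] <- k
    }
  }
  new("ExampleSet", schema = schema, meta = meta, labels = labs)
}
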