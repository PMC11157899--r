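# BRAT standoff I/O. Only text-bound (T) and attribute (A) lines are
# interpreted; event, relation and normalization lines are out of scope.

#' Parse a BRAT standoff document
#'
#' Text-bound lines have the form
#' `T<id>\t<Type> <start> <end>[;<start> <end>...]\t<text>` with 0-based
#' half-open character offsets; semicolon-separated fragments become a
#' discontiguous mention whose surface is the fragments joined by a single
#' space. Attribute lines `A<id>\t<AttrName> T<id> [<Value>]` attach modifier
#' labels; a valueless (binary) attribute sets the non-default label of a
#' two-class modifier. Attribute names not in `schema` are skipped with a
#' warning so mixed-schema corpora can be partially loaded. The recorded
#' entity text of every T line is validated against the document substring.
#'
#' @param txtContent character(1) full document text.
#' @param annContent character(1) standoff annotation content ("" for none).
#' @param schema the governing [ModifierSchema-class].
#' @param docId character(1) id for the resulting document.
#' @return list with elements `document` ([Document-class]) and `mentions`
#'   (list of [EntityMention-class]).
#' @examples
#' sch <- modifierSchema("s", list(negation = c("no", "yes")))
#' p <- parseBrat("No fever today.", "T1\tDisorder 3 8\tfever\nA1\tNegation T1 yes",
#'                sch, "d1")
#' mentionLabels(p$mentions[[1]])
#' @export
parseBrat <- function(txtContent, annContent, schema, docId) {
  doc <- document(docId, txtContent)
  lines <- strsplit(annContent, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  mentions <- list()
  tIndex <- character(0)   # T id -> position in `mentions`
  # schema lookup is case-insensitive on attribute names, a common BRAT
  # configuration discrepancy
  modLookup <- stats::setNames(schema@modifiers, tolower(schema@modifiers))

  tLines <- grep("^T", lines)
  for (i in tLines) {
    ln <- lines[i]
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop(sprintf("line %d: malformed text-bound line", i))
    tid <- sub("^T", "", parts[1])
    offs <- strsplit(sub("^\\S+ ", "", parts[2]), ";", fixed = TRUE)[[1]]
    spans <- lapply(offs, function(o) {
      nums <- suppressWarnings(as.integer(strsplit(trimws(o), " ")[[1]]))
      if (length(nums) != 2L || anyNA(nums))
        stop(sprintf("line %d: malformed offsets '%s'", i, o))
      nums
    })
    spans <- do.call(rbind, spans)
    if (any(spans[, 2] > nchar(txtContent)) || any(spans[, 1] < 0))
      stop(sprintf("line %d: span outside document (length %d)",
                   i, nchar(txtContent)))
    surface <- substrSpans(txtContent, spans)
    recorded <- parts[3]
    if (!identical(recorded, surface))
      stop(sprintf(
        "line %d: recorded text '%s' does not match document text '%s'",
        i, recorded, surface))
    m <- entityMention(paste0("T", tid), docId, spans, surface)
    mentions[[length(mentions) + 1L]] <- m
    tIndex[paste0("T", tid)] <- length(mentions)
  }

  for (i in grep("^A", lines)) {
    ln <- lines[i]
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("line %d: malformed attribute line", i))
    fields <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    if (length(fields) < 2L || length(fields) > 3L)
      stop(sprintf("line %d: malformed attribute line", i))
    attrName <- fields[1]; target <- fields[2]
    pos <- tIndex[target]
    if (is.na(pos))
      stop(sprintf("line %d: attribute references unknown entity '%s'",
                   i, target))
    mod <- modLookup[tolower(attrName)]
    if (is.na(mod)) {
      warning(sprintf(
        "line %d: attribute '%s' not in schema '%s'; skipped",
        i, attrName, schema@name))
      next
    }
    labs <- schema@labels[[mod]]
    if (length(fields) == 3L) {
      value <- fields[3]
      if (!value %in% labs)
        stop(sprintf("line %d: '%s' is not a label of modifier '%s'",
                     i, value, mod))
    } else {
      # valueless binary attribute: the non-default label of a 2-class
      # modifier
      if (length(labs) != 2L)
        stop(sprintf(
          "line %d: valueless attribute '%s' on a %d-class modifier",
          i, attrName, length(labs)))
      value <- labs[-schema@defaults[[mod]]]
    }
    m <- mentions[[as.integer(pos)]]
    m@labels[mod] <- value
    mentions[[as.integer(pos)]] <- m
  }

  bad <- grep("^[^TA#]", lines)
  if (length(bad))
    warning(sprintf("%d non-T/A annotation line(s) ignored", length(bad)))

  list(document = doc, mentions = mentions)
}

#' Serialize a document and its mentions to BRAT standoff
#'
#' Inverse of [parseBrat()] up to identifier renaming: T ids are renumbered
#' T1..Tn in mention order. Only non-default labels become A lines (default
#' modifier values are unannotated by convention).
#'
#' @param doc a [Document-class].
#' @param mentions list of [EntityMention-class] over `doc`.
#' @param schema the governing [ModifierSchema-class].
#' @param entityType character(1) BRAT type for the T lines.
#' @return list(txt = document text, ann = standoff content).
#' @export
writeBrat <- function(doc, mentions, schema, entityType = "Disorder") {
  out <- character(0)
  aid <- 0L
  for (k in seq_along(mentions)) {
    m <- mentions[[k]]
    if (!identical(m@surface, substrSpans(doc@text, m@spans)))
      stop(sprintf("mention '%s' is inconsistent with the document",
                   m@entityId))
    offs <- paste(apply(m@spans, 1L, function(r) paste(r[1], r[2])),
                  collapse = ";")
    out <- c(out, sprintf("T%d\t%s %s\t%s", k, entityType, offs, m@surface))
    for (nm in names(m@labels)) {
      if (identical(m@labels[[nm]], defaultLabel(schema, nm))) next
      aid <- aid + 1L
      out <- c(out, sprintf("A%d\t%s T%d %s", aid, nm, k, m@labels[[nm]]))
    }
  }
  list(txt = doc@text,
       ann = if (length(out)) paste0(paste(out, collapse = "\n"), "\n")
             else "")
}

#' Read / write a directory of paired .txt/.ann files
#'
#' @param dir directory containing `<doc>.txt` / `<doc>.ann` pairs (reading)
#'   or to be populated with them (writing).
#' @param schema the governing [ModifierSchema-class].
#' @return `readBratDir`: an [AnnotatedCorpus-class].
#' @export
readBratDir <- function(dir, schema) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- list(); mentions <- list()
  for (tp in txts) {
    id <- sub("\\.txt$", "", basename(tp))
    ap <- file.path(dir, paste0(id, ".ann"))
    ann <- if (file.exists(ap))
      paste(readLines(ap, warn = FALSE), collapse = "\n") else ""
    txt <- paste(readLines(tp, warn = FALSE), collapse = "\n")
    p <- parseBrat(txt, ann, schema, id)
    # make entity ids corpus-unique
    p$mentions <- lapply(p$mentions, function(m) {
      m@entityId <- paste0(id, ":", m@entityId); m
    })
    docs[[length(docs) + 1L]] <- p$document
    mentions <- c(mentions, p$mentions)
  }
  annotatedCorpus(schema, docs, mentions)
}

#' @rdname readBratDir
#' @param corpus an [AnnotatedCorpus-class] to serialize.
#' @return `writeBratDir`: `dir`, invisibly.
#' @export
writeBratDir <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mdoc <- vapply(corpus@mentions, docId, character(1))
  for (d in corpus@documents) {
    men <- corpus@mentions[mdoc == d@docId]
    b <- writeBrat(d, men, corpus@schema)
    writeLines(b$txt, file.path(dir, paste0(d@docId, ".txt")), sep = "")
    writeLines(b$ann, file.path(dir, paste0(d@docId, ".ann")), sep = "")
  }
  invisible(dir)
}
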