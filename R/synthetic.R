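# Seeded generator of clinical-style corpora with cue-determined modifier
# labels. The generator emulates the statistical structure of real modifier
# corpora — a dominant default class (~92%), short lexical triggers that
# determine the non-default labels, discontiguous mentions, duplicate
# mentions inside one context window, and distractor phrases (lab-panel
# "Negative"/"Positive" tokens, family-history headers) that must NOT flip
# labels — while staying trivially license-free. Every non-default label is
# recoverable from its window by exact cue lookup ([ruleOracle()]), so the
# learning task is solvable by construction and end-to-end model accuracy
# is a meaningful measurement.

# -- schemas ------------------------------------------------------------------

.shareModifiers <- function() list(
  negation = c("no", "yes"),
  severity = c("unmarked", "slight", "moderate", "severe"),
  course = c("unmarked", "improved", "worsened", "increased", "decreased"),
  subject = c("patient", "family_member", "other"),
  uncertainty = c("no", "yes"),
  conditional = c("false", "true"),
  generic = c("false", "true"))

.oudModifiers <- function() list(
  negation = c("no", "yes"),
  subject = c("patient", "family_member", "other"),
  DocTime = c("unmarked", "before", "overlaps", "after"),
  illicitDrugUse = c("false", "true"),
  uncertainty = c("no", "yes"))

#' Built-in modifier schemas
#'
#' `"share_like"` has the 7 disorder modifiers (negation, severity, course,
#' subject, uncertainty, conditional, generic); `"oud_like"` has 5
#' (negation, subject, DocTime with before/overlaps/after plus an unmarked
#' default, illicitDrugUse, uncertainty). The two schemas share exactly
#' {negation, subject, uncertainty} with identical label lists, so models
#' transferred between them have genuinely shared heads; their union has 9
#' distinct modifiers.
#'
#' @param kind "share_like" or "oud_like".
#' @return a [ModifierSchema-class].
#' @examples
#' length(modifiers(makeSchema("share_like")))  # 7
#' @export
makeSchema <- function(kind = c("share_like", "oud_like")) {
  kind <- match.arg(kind)
  modifierSchema(kind, switch(kind, share_like = .shareModifiers(),
                              oud_like = .oudModifiers()))
}

# -- cue bank -----------------------------------------------------------------

#' The cue bank: trigger phrases that determine non-default labels
#'
#' For every (modifier, non-default label) there are >= 2 cue phrases; the
#' cue -> label mapping is deterministic and shared between the two schema
#' kinds, so transfer between them has shared lexical structure. Cue tokens
#' are disjoint from the generator's filler sentences, distractor phrases
#' and entity terms (enforced by tests), which is what makes exact cue
#' lookup a perfect oracle on generated data.
#'
#' @return named list: modifier -> (non-default label -> character cues).
#' @export
cueBank <- function() list(
  negation = list(yes = c("denies", "without", "no", "none")),
  severity = list(slight = c("slight", "mild"),
                  moderate = c("moderate", "middling"),
                  severe = c("severe", "extreme")),
  course = list(improved = c("improving", "improved"),
                worsened = c("worsening", "worsened"),
                increased = c("increasing", "escalating"),
                decreased = c("decreasing", "diminishing")),
  subject = list(family_member = c("mother reports", "father reports"),
                 other = c("neighbor reports", "caretaker reports")),
  uncertainty = list(yes = c("possible", "possibly", "questionable",
                             "suspected")),
  conditional = list(true = c("if needed", "contingent upon")),
  generic = list(true = c("typically", "generically")),
  DocTime = list(before = c("previously", "years ago"),
                 overlaps = c("currently", "presently"),
                 after = c("anticipated", "expected soon")),
  illicitDrugUse = list(true = c("illicitly", "street acquired")))

# distractor phrases: near-miss tokens that must not flip any label
.distractors <- function() c(
  "Lab Results : U Methadone Negative U Opiates Positive U Oxycodone Negative .",
  "Family History : relatives were interviewed and records were attached .",
  "Screening scale score 0 of 10 was recorded by the technician .")

.fillers <- function() c(
  "Vital signs were reviewed and remain stable this morning per the flowsheet record .",
  "The care team discussed medication timing and documented adherence in the chart .",
  "Laboratory panels from admission were unremarkable and repeat draws are scheduled .",
  "Nursing staff completed the intake checklist and updated the bedside record .",
  "Follow up visits were arranged with the outpatient coordinator for next week .",
  "The patient rested comfortably during the afternoon and ate a full meal .",
  "Imaging from the prior visit was compared and archived in the radiology system .")

.entityTerms <- function() c(
  "fever", "cough", "nausea", "vomiting", "headache", "dizziness", "rash",
  "fatigue", "insomnia", "anxiety", "tremor", "sweating", "palpitations",
  "constipation", "diarrhea", "pruritus", "cramping", "numbness",
  "tingling", "weakness", "agitation", "paranoia", "hallucinations",
  "confusion", "drowsiness", "seizures", "wheezing", "hives", "bruising",
  "swelling")

.discSites <- function() c("ankle", "wrist", "knee", "elbow", "shoulder")

#' Generator configuration
#'
#' Default rates mirror the statistics of real modifier corpora: the
#' default class covers ~92% of instances per modifier; ~4% of examples
#' have a duplicate of the entity mention inside their context window and
#' ~2% have it three times; ~5% of mentions are discontiguous.
#'
#' @param schemaKind "share_like" or "oud_like".
#' @param nMentions total number of entity mentions to generate.
#' @param defaultRate probability a modifier takes its default label.
#' @param duplicateRate target fraction of examples whose window holds the
#'   mention twice.
#' @param triplicateRate target fraction with three or more occurrences.
#' @param discontiguousRate fraction of discontiguous mentions.
#' @param seed master seed; one generator stream drives all randomness.
#' @param vocabularySize number of distinct entity terms used (<= 30).
#' @param perModifierRates optional named numeric overriding `defaultRate`
#'   for individual modifiers.
#' @return list with class "GeneratorConfig".
#' @export
generatorConfig <- function(schemaKind = c("share_like", "oud_like"),
                            nMentions = 1000L, defaultRate = 0.92,
                            duplicateRate = 0.04, triplicateRate = 0.02,
                            discontiguousRate = 0.05, seed = 1L,
                            vocabularySize = 30L,
                            perModifierRates = NULL) {
  schemaKind <- match.arg(schemaKind)
  rates <- c(defaultRate, duplicateRate, triplicateRate, discontiguousRate)
  if (any(rates < 0) || any(rates > 1))
    stop("rates must be in [0, 1]")
  if (duplicateRate + triplicateRate >= 1)
    stop("duplicateRate + triplicateRate must be < 1")
  if (defaultRate <= 0 || defaultRate >= 1)
    stop("defaultRate must be in (0, 1)")
  structure(list(schemaKind = schemaKind,
                 nMentions = as.integer(nMentions),
                 defaultRate = defaultRate, duplicateRate = duplicateRate,
                 triplicateRate = triplicateRate,
                 discontiguousRate = discontiguousRate,
                 seed = as.integer(seed),
                 vocabularySize = as.integer(min(vocabularySize, 30L)),
                 perModifierRates = perModifierRates),
            class = "GeneratorConfig")
}

# draw the labels of one mention: default with prob rate, else uniform
# non-default; returns named character of NON-default labels only
.drawLabels <- function(schema, config) {
  out <- character(0)
  for (mi in schema@modifiers) {
    rate <- config$defaultRate
    if (!is.null(config$perModifierRates) &&
        mi %in% names(config$perModifierRates))
      rate <- config$perModifierRates[[mi]]
    if (stats::runif(1) < rate) next
    nd <- setdiff(schema@labels[[mi]], defaultLabel(schema, mi))
    out[mi] <- nd[sample.int(length(nd), 1L)]
  }
  out
}

# cue phrases realizing a label draw; course cues go after the entity,
# everything else before (the context window is asymmetric toward
# preceding text, so cues predominantly precede the mention)
.cuesFor <- function(labels) {
  bank <- cueBank()
  pre <- character(0); post <- character(0)
  for (mi in names(labels)) {
    cues <- bank[[mi]][[labels[[mi]]]]
    cue <- cues[sample.int(length(cues), 1L)]
    if (mi == "course") post <- c(post, cue) else pre <- c(pre, cue)
  }
  list(pre = pre, post = post)
}

#' Generate a synthetic annotated corpus
#'
#' Documents are templated clinical-style notes: filler sentences
#' interleaved with mention sentences in which cue phrases inside the
#' mention's 200/50-character window realize each non-default label.
#' Mention sentences are separated by enough neutral filler that one
#' mention's cues never enter another mention's window (duplicate and
#' triplicate mentions, which deliberately share a window — and hence their
#' gold labels — are the exception). Distractor phrases are injected
#' adjacent to some mentions. Identical seeds give identical corpora.
#'
#' @param config a [generatorConfig()].
#' @return an [AnnotatedCorpus-class] (all corpus invariants validated).
#' @examples
#' corp <- generateCorpus(generatorConfig(nMentions = 20, seed = 13))
#' nMentions(corp)
#' @export
generateCorpus <- function(config) {
  schema <- makeSchema(config$schemaKind)
  withSeed(config$seed, {
    fillers <- .fillers()
    distractors <- .distractors()
    entities <- .entityTerms()[seq_len(config$vocabularySize)]
    sites <- .discSites()

    docs <- list(); mentions <- list()
    made <- 0L; eCounter <- 0L; dCounter <- 0L

    while (made < config$nMentions) {
      dCounter <- dCounter + 1L
      docIdStr <- sprintf("doc%04d", dCounter)
      nGroups <- sample.int(3L, 1L)
      text <- fillers[sample.int(length(fillers), 1L)]

      for (g in seq_len(nGroups)) {
        if (made >= config$nMentions) break
        # isolation: pad with filler until >= 210 neutral chars precede
        # the next mention sentence
        pad <- 0L
        while (pad < 210L) {
          f <- fillers[sample.int(length(fillers), 1L)]
          text <- paste0(text, " ", f)
          pad <- pad + nchar(f) + 1L
        }
        if (stats::runif(1) < 0.15)
          text <- paste0(text, " ",
                         distractors[sample.int(length(distractors), 1L)])

        # multiplicity and shape of this mention event
        r <- stats::runif(1)
        mult <- 1L; disc <- FALSE
        if (r < config$discontiguousRate) {
          disc <- TRUE
        } else if (r < config$discontiguousRate + config$duplicateRate / 2) {
          mult <- 2L
        } else if (r < config$discontiguousRate + config$duplicateRate / 2 +
                   config$triplicateRate / 3) {
          mult <- 3L
        }
        mult <- min(mult, config$nMentions - made)

        labels <- .drawLabels(schema, config)
        cues <- .cuesFor(labels)
        ent <- entities[sample.int(length(entities), 1L)]

        lead <- paste(c("Assessment records that", cues$pre), collapse = " ")
        text <- paste0(text, " ", lead, " ")
        spansList <- list()
        # post cues (course) go right after the FIRST occurrence so they
        # stay within 50 characters of its last span for every multiplicity
        post <- if (length(cues$post))
          paste0(" ", paste(cues$post, collapse = " ")) else ""
        if (disc) {
          s1 <- nchar(text)
          text <- paste0(text, ent)
          e1 <- nchar(text)
          site <- sites[sample.int(length(sites), 1L)]
          text <- paste0(text, " involving the left ")
          s2 <- nchar(text)
          text <- paste0(text, site)
          e2 <- nchar(text)
          spansList[[1]] <- rbind(c(s1, e1), c(s2, e2))
          text <- paste0(text, post)
        } else {
          s1 <- nchar(text)
          text <- paste0(text, ent)
          spansList[[1]] <- rbind(c(s1, nchar(text)))
          text <- paste0(text, post)
          if (mult >= 2L) {
            text <- paste0(text, " noted and again ")
            s2 <- nchar(text)
            text <- paste0(text, ent)
            spansList[[2]] <- rbind(c(s2, nchar(text)))
          }
          if (mult >= 3L) {
            text <- paste0(text, " observed once more with ")
            s3 <- nchar(text)
            text <- paste0(text, ent)
            spansList[[3]] <- rbind(c(s3, nchar(text)))
          }
        }
        text <- paste0(text, " .")

        for (sp in spansList) {
          eCounter <- eCounter + 1L
          mentions[[length(mentions) + 1L]] <- entityMention(
            sprintf("e%05d", eCounter), docIdStr, sp,
            surface = substrSpans(text, sp), labels = labels)
          made <- made + 1L
        }
      }
      text <- paste0(text, " ",
                     fillers[sample.int(length(fillers), 1L)])
      docs[[length(docs) + 1L]] <- document(docIdStr, text)
    }
    annotatedCorpus(schema, docs, mentions)
  })
}

#' Exact cue-lookup oracle
#'
#' Reconstructs every label from the context window by exact word-boundary
#' lookup of the cue phrases in [cueBank()]: for each modifier, the first
#' non-default label (in label order) whose cue matches the window wins,
#' otherwise the default. On generated corpora this oracle is exact, which
#' certifies that the learning task is solvable and gives model accuracy a
#' meaningful ceiling; distractor phrases must not fire it.
#'
#' @param examples an [ExampleSet-class] (windows already extracted).
#' @return integer prediction matrix shaped like [predictModifiers()].
#' @export
ruleOracle <- function(examples) {
  sch <- examples@schema
  bank <- cueBank()
  n <- nExamples(examples)
  out <- matrix(0L, n, length(sch@modifiers),
                dimnames = list(NULL, sch@modifiers))
  for (j in seq_along(sch@modifiers)) {
    mi <- sch@modifiers[j]
    labs <- sch@labels[[j]]
    pred <- rep(sch@defaults[[j]], n)
    cuesByLabel <- bank[[mi]]
    for (lab in labs) {
      if (is.null(cuesByLabel[[lab]])) next
      rx <- paste0("\\b(", paste(cuesByLabel[[lab]], collapse = "|"),
                   ")\\b")
      hit <- grepl(rx, examples@meta$left) & pred == sch@defaults[[j]]
      pred[hit] <- match(lab, labs)
    }
    out[, j] <- pred
  }
  out
}
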