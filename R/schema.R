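#' Construct a modifier schema
#'
#' @param name character(1) schema identifier.
#' @param modifiers named list: modifier name -> character label vocabulary.
#' @param defaults named character or integer: for each modifier, the default
#'   label (by name or 1-based index). Defaults to the first label.
#' @return a [ModifierSchema-class].
#' @examples
#' sch <- modifierSchema("demo",
#'   list(negation = c("no", "yes"), severity = c("unmarked", "slight")))
#' modifiers(sch)
#' @export
modifierSchema <- function(name, modifiers, defaults = NULL) {
  mn <- names(modifiers)
  if (is.null(mn) || any(!nzchar(mn)))
    stop("`modifiers` must be a named list of label vectors")
  di <- rep(1L, length(mn))
  names(di) <- mn
  if (!is.null(defaults)) {
    for (k in names(defaults)) {
      if (!k %in% mn) stop(sprintf("default for unknown modifier '%s'", k))
      v <- defaults[[k]]
      if (is.character(v)) {
        idx <- match(v, modifiers[[k]])
        if (is.na(idx))
          stop(sprintf("default '%s' is not a label of modifier '%s'", v, k))
        di[[k]] <- idx
      } else di[[k]] <- as.integer(v)
    }
  }
  labs <- lapply(modifiers, as.character)
  new("ModifierSchema", name = name, modifiers = mn,
      labels = labs[mn], defaults = di[mn])
}

#' @describeIn modifiers schema method
#' @export
setMethod("modifiers", "ModifierSchema", function(x) x@modifiers)

#' @describeIn labelSet schema method
#' @export
setMethod("labelSet", "ModifierSchema", function(x, modifier) {
  if (!modifier %in% x@modifiers)
    stop(sprintf("unknown modifier '%s'", modifier))
  x@labels[[modifier]]
})

#' @describeIn defaultLabel schema method
#' @export
setMethod("defaultLabel", "ModifierSchema", function(x, modifier) {
  x@labels[[modifier]][x@defaults[[modifier]]]
})

#' @describeIn schemaOf identity on a schema
#' @export
setMethod("schemaOf", "ModifierSchema", function(x) x)

setMethod("show", "ModifierSchema", function(object) {
  cat(sprintf("ModifierSchema '%s' with %d modifiers\n",
              object@name, length(object@modifiers)))
  for (mi in object@modifiers) {
    labs <- object@labels[[mi]]
    labs[object@defaults[[mi]]] <- paste0(labs[object@defaults[[mi]]], "*")
    cat(sprintf("  %-16s {%s}\n", mi, paste(labs, collapse = ", ")))
  }
  invisible(NULL)
})

#' Merge two schemas on modifier names
#'
#' Modifiers sharing a name must have identical label vocabularies and
#' default labels; the union keeps the first schema's order followed by the
#' second schema's novel modifiers. Used by [mergeCorpora()] to build the
#' combined-corpus ("both") configuration with one head per distinct
#' modifier name.
#'
#' @param a,b [ModifierSchema-class] objects.
#' @param name name for the merged schema.
#' @return a [ModifierSchema-class].
#' @export
mergeSchemas <- function(a, b, name = paste(a@name, b@name, sep = "+")) {
  for (mi in intersect(a@modifiers, b@modifiers)) {
    if (!identical(a@labels[[mi]], b@labels[[mi]]) ||
        a@defaults[[mi]] != b@defaults[[mi]])
      stop(sprintf(
        "schema conflict: modifier '%s' has different label lists", mi))
  }
  extra <- setdiff(b@modifiers, a@modifiers)
  labs <- c(a@labels, b@labels[extra])
  defs <- c(a@defaults, b@defaults[extra])
  new("ModifierSchema", name = name, modifiers = names(labs),
      labels = labs, defaults = defs)
}

#' Read / write a schema as YAML
#'
#' The on-disk format is a mapping with `name` and a `modifiers` sequence of
#' `{name, labels, default}` entries; `default` is the default label string.
#'
#' @param path file path.
#' @return `readSchemaYaml`: a [ModifierSchema-class].
#' @export
readSchemaYaml <- function(path) {
  y <- yaml::read_yaml(path)
  labs <- stats::setNames(
    lapply(y$modifiers, function(m) as.character(m$labels)),
    vapply(y$modifiers, function(m) m$name, character(1)))
  defs <- stats::setNames(
    lapply(y$modifiers, function(m) m$default),
    names(labs))
  modifierSchema(y$name, labs, defaults = defs)
}

#' @rdname readSchemaYaml
#' @param schema a [ModifierSchema-class] to serialize.
#' @return `writeSchemaYaml`: `path`, invisibly.
#' @export
writeSchemaYaml <- function(schema, path) {
  y <- list(
    name = schema@name,
    modifiers = lapply(schema@modifiers, function(mi) list(
      name = mi, labels = as.list(schema@labels[[mi]]),
      default = defaultLabel(schema, mi))))
  yaml::write_yaml(y, path)
  invisible(path)
}
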