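# Internal helpers shared across modules.

# Extract the substring(s) of `text` covered by a 0-based half-open span
# matrix and join fragments with a single space.
substrSpans <- function(text, spans) {
  paste(substring(text, spans[, 1] + 1L, spans[, 2]), collapse = " ")
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls do not perturb user-level randomness.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Derive a child seed from a master seed, kept within 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647L)
}

#' Tokenize text for the compact encoder and the token budget
#'
#' Case-sensitive split on runs of non-alphanumeric characters (apostrophes
#' kept inside tokens). Deliberately simple: clinical cue words, lab-panel
#' tokens and numbers ("0") survive intact, and the same tokenizer defines
#' the token budget of [encodePairLengthBudget()].
#'
#' @param x character vector.
#' @return list of character vectors, one per element of `x`.
#' @export
tokenizeText <- function(x) {
  out <- strsplit(x, "[^A-Za-z0-9']+")
  lapply(out, function(t) t[nzchar(t)])
}

# Start offsets (1-based, in characters) of each token in a single string.
tokenStarts <- function(x) {
  m <- gregexpr("[A-Za-z0-9']+", x)[[1]]
  if (length(m) == 1L && m[1] == -1L) integer(0) else as.integer(m)
}
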