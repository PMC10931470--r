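#' Default English stop-word list
#'
#' The classic Snowball English stop-word list (175 function words), the
#' de-facto standard list used by most text-mining toolkits. Override it
#' through [preprocess_config()] or, on the command line, with a
#' one-token-per-line file.
#'
#' @return Character vector of lower-case stop words.
#' @export
default_stopwords <- function() {
  c("i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
    "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
    "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
    "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
    "being", "have", "has", "had", "having", "do", "does", "did", "doing",
    "would", "should", "could", "ought", "i'm", "you're", "he's", "she's",
    "it's", "we're", "they're", "i've", "you've", "we've", "they've", "i'd",
    "you'd", "he'd", "she'd", "we'd", "they'd", "i'll", "you'll", "he'll",
    "she'll", "we'll", "they'll", "isn't", "aren't", "wasn't", "weren't",
    "hasn't", "haven't", "hadn't", "doesn't", "don't", "didn't", "won't",
    "wouldn't", "shan't", "shouldn't", "can't", "cannot", "couldn't",
    "mustn't", "let's", "that's", "who's", "what's", "here's", "there's",
    "when's", "where's", "why's", "how's", "a", "an", "the", "and", "but",
    "if", "or", "because", "as", "until", "while", "of", "at", "by", "for",
    "with", "about", "against", "between", "into", "through", "during",
    "before", "after", "above", "below", "to", "from", "up", "down", "in",
    "out", "on", "off", "over", "under", "again", "further", "then", "once",
    "here", "there", "when", "where", "why", "how", "all", "any", "both",
    "each", "few", "more", "most", "other", "some", "such", "no", "nor",
    "not", "only", "own", "same", "so", "than", "too", "very", "will",
    "shall", "may", "must", "can")
}

#' Preprocessing configuration
#'
#' Bundles the clause-text preprocessing options: lower-casing, stop-word
#' removal, and morphological reduction (`"none"`, `"stem"` for a
#' suffix-stripping stemmer, or `"lemma"` for a rule-based lemmatiser that
#' returns dictionary base forms, e.g. "caring" -> "care").
#'
#' The defaults (lower-case, remove stop words, lemmatise) are the standard
#' pipeline for clause-similarity analysis. For reproducing textbook TF-IDF
#' hand calculations that count every surface word, use
#' `preprocess_config(remove_stopwords = FALSE, reduction = "none")`.
#'
#' @param lowercase Lower-case the text before tokenisation.
#' @param remove_stopwords Drop tokens found in `stopwords`.
#' @param reduction One of `"none"`, `"stem"`, `"lemma"`.
#' @param stopwords Character vector of stop words; defaults to
#'   [default_stopwords()].
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(lowercase = TRUE, remove_stopwords = TRUE,
                              reduction = c("lemma", "stem", "none"),
                              stopwords = default_stopwords()) {
  reduction <- match.arg(reduction)
  structure(list(lowercase = isTRUE(lowercase),
                 remove_stopwords = isTRUE(remove_stopwords),
                 reduction = reduction,
                 stopwords = tolower(as.character(stopwords))),
            class = "preprocess_config")
}

#' Tokenise clause text
#'
#' Splits text into Unicode word tokens. Internal ASCII hyphens are kept, so
#' a compound like "health-related" is a single token; all other punctuation
#' (including em dashes) is dropped. Whitespace-only input yields an empty
#' token vector.
#'
#' @param text A single character string.
#' @param lowercase Lower-case before tokenising.
#' @return Character vector of tokens, free of whitespace and
#'   pure-punctuation entries.
#' @export
tokenize <- function(text, lowercase = TRUE) {
  stopifnot(is.character(text), length(text) == 1)
  if (lowercase) text <- tolower(text)
  toks <- stringr::str_extract_all(
    text, "[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*")[[1]]
  toks[nzchar(toks)]
}

#' Remove stop words from a token vector
#'
#' Order-preserving removal of tokens on the stop list (matched
#' case-insensitively). Pure-punctuation tokens, should any reach this stage,
#' are always removed.
#'
#' @param tokens Character vector of tokens.
#' @param stopwords Character vector of stop words.
#' @return Filtered token vector.
#' @export
remove_stopwords <- function(tokens, stopwords = default_stopwords()) {
  if (length(tokens) == 0) return(character(0))
  drop <- tolower(tokens) %in% tolower(stopwords) |
    grepl("^\\p{P}+$", tokens, perl = TRUE)
  tokens[!drop]
}

#' Reduce tokens to stems or lemmas
#'
#' Per-token morphological reduction; the output always has the same length
#' as the input. `"stem"` applies a compact suffix-stripping stemmer (so
#' "investigation" and "investigator" share the stem "investig");
#' `"lemma"` applies rule-based inflection stripping towards dictionary base
#' forms ("caring" -> "care", "measures" -> "measure"); `"none"` is the
#' identity. Both reducers are lightweight and deterministic; they are not
#' part-of-speech aware, and exact outputs differ from other stemmer
#' implementations.
#'
#' @param tokens Character vector of tokens.
#' @param mode One of `"none"`, `"stem"`, `"lemma"`.
#' @return Character vector of reduced tokens, same length as `tokens`.
#' @export
reduce_tokens <- function(tokens, mode = c("none", "stem", "lemma")) {
  if (length(mode) != 1 || !mode %in% c("none", "stem", "lemma")) {
    stop("unknown reduction mode; valid modes: none, stem, lemma",
         call. = FALSE)
  }
  if (length(tokens) == 0) return(character(0))
  switch(mode,
         none = tokens,
         stem = vapply(tokens, stem_token, character(1), USE.NAMES = FALSE),
         lemma = vapply(tokens, lemma_token, character(1), USE.NAMES = FALSE))
}

# Suffix-stripping stemmer: longest matching suffix is removed, provided at
# least 3 characters of stem remain. Hyphenated compounds are stemmed per
# component.
stem_token <- function(tok) {
  if (grepl("-", tok, fixed = TRUE)) {
    return(paste(vapply(strsplit(tok, "-", fixed = TRUE)[[1]], stem_token,
                        character(1)), collapse = "-"))
  }
  suffixes <- c("isations", "izations", "isation", "ization", "ational",
                "fulness", "ousness", "iveness", "ations", "ators", "ation",
                "ator", "ities", "ingly", "ments", "edly", "ance", "ence",
                "ment", "ness", "able", "ible", "ions", "ives", "ing", "ion",
                "ity", "ous", "ies", "ive", "ers", "ed", "er", "es", "ly",
                "s")
  for (suf in suffixes) {
    if (endsWith(tok, suf) && nchar(tok) - nchar(suf) >= 3) {
      stem <- substr(tok, 1, nchar(tok) - nchar(suf))
      # undo consonant doubling left by -ing/-ed stripping (running -> run)
      if (suf %in% c("ing", "ed", "ingly", "edly")) {
        n <- nchar(stem)
        last <- substr(stem, n, n)
        if (n >= 4 && last == substr(stem, n - 1, n - 1) &&
            !last %in% c("l", "s", "z")) {
          stem <- substr(stem, 1, n - 1)
        }
      }
      if (suf == "ies") stem <- paste0(stem, "i")
      return(stem)
    }
  }
  tok
}

is_vowel <- function(ch) ch %in% c("a", "e", "i", "o", "u")

# Rule-based lemmatiser for common English inflections (plural -s/-es/-ies,
# progressive -ing, past -ed). A consonant-vowel-consonant ending after
# stripping restores the elided "e" (caring -> car -> care); doubled final
# consonants are collapsed (stopped -> stopp -> stop).
lemma_token <- function(tok) {
  if (grepl("-", tok, fixed = TRUE)) {
    return(paste(vapply(strsplit(tok, "-", fixed = TRUE)[[1]], lemma_token,
                        character(1)), collapse = "-"))
  }
  n <- nchar(tok)
  restore <- function(stem) {
    m <- nchar(stem)
    if (m < 2) return(stem)
    last <- substr(stem, m, m)
    prev <- substr(stem, m - 1, m - 1)
    if (m >= 3 && last == prev && !last %in% c("l", "s", "z")) {
      return(substr(stem, 1, m - 1))
    }
    before <- if (m >= 3) substr(stem, m - 2, m - 2) else ""
    if (m >= 3 && !is_vowel(last) && !last %in% c("w", "x", "y") &&
        is_vowel(prev) && !is_vowel(before)) {
      return(paste0(stem, "e"))
    }
    stem
  }
  if (endsWith(tok, "ies") && n > 4) {
    return(paste0(substr(tok, 1, n - 3), "y"))
  }
  if (endsWith(tok, "ing") && n > 5) {
    return(restore(substr(tok, 1, n - 3)))
  }
  if (endsWith(tok, "ed") && n > 4 && !is_vowel(substr(tok, n - 2, n - 2))) {
    return(restore(substr(tok, 1, n - 2)))
  }
  if (endsWith(tok, "sses") && n > 5) {
    return(substr(tok, 1, n - 2))
  }
  if (endsWith(tok, "es") && n > 4 &&
      grepl("(s|x|z|ch|sh)es$", tok)) {
    return(substr(tok, 1, n - 2))
  }
  if (endsWith(tok, "s") && n > 3 && !endsWith(tok, "ss") &&
      !endsWith(tok, "us") && !endsWith(tok, "is")) {
    return(substr(tok, 1, n - 1))
  }
  tok
}

#' Preprocess clause text into tokens
#'
#' Deterministic composition of [tokenize()], [remove_stopwords()] (when
#' enabled), and [reduce_tokens()], driven by a [preprocess_config()].
#'
#' @param text A single clause string.
#' @param config A [preprocess_config()].
#' @return Character vector of processed tokens.
#' @export
preprocess <- function(text, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  toks <- tokenize(text, lowercase = config$lowercase)
  if (config$remove_stopwords) {
    toks <- remove_stopwords(toks, config$stopwords)
  }
  reduce_tokens(toks, config$reduction)
}

#' Preprocess every clause in a corpus
#'
#' @param corpus A `treaty_corpus`.
#' @param config A [preprocess_config()].
#' @return Named list (by `treaty_id`) of token vectors.
#' @export
tokenize_corpus <- function(corpus, config = preprocess_config()) {
  stats::setNames(lapply(corpus$clause_text, preprocess, config = config),
                  corpus$treaty_id)
}
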