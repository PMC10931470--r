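# Fixture builders shared across test files. Everything is generated in
# code; no fixture files on disk.

# The two six-word example sentences used throughout the TF-IDF tests.
example_sentences <- function() {
  c(D1 = "Investment agreements should protect health-related measures.",
    D2 = "Investment agreements should protect climate-related measures.")
}

# Pass-through preprocessing: count every surface word, as in textbook
# TF-IDF hand calculations.
passthrough_config <- function() {
  preprocess_config(remove_stopwords = FALSE, reduction = "none")
}

example_docs <- function() {
  lapply(example_sentences(), preprocess, config = passthrough_config())
}

# Small hand-written corpus: 5 dyadic treaties, mixed categories/decades.
tiny_corpus <- function() {
  treaty_corpus(tibble::tibble(
    treaty_id = paste0("T", 1:5),
    country_a = c("Canada", "Canada", "Nigeria", "Canada", "Spain"),
    country_b = c("Nigeria", "Singapore", "Singapore", "Ghana", "Ghana"),
    date_signed = c("1995-04-01", "2003-09-12", "2003", "2011-01-30",
                    "2018-06-05"),
    categories = c("defensive", "defensive;neutral", "neutral",
                   "offensive", "defensive"),
    clause_text = c(
      "each party shall protect public health measures",
      "each party shall protect public health measures",
      "each party shall protect public health measures",
      "investors must respect sanitary regulation of the host state",
      "tariff schedules apply to maritime cargo manifests only")
  ), label = "tiny fixture")
}

# Random dyadic corpus over a closed vocabulary of plain lower-case words
# (no stop words, no inflection), so pass-through preprocessing and naive
# whitespace splitting tokenise it identically.
random_corpus <- function(n, seed, vocab_size = 12, clause_len = 8,
                          n_countries = 6) {
  withr::with_seed(seed, {
    vocab <- paste0("w", seq_len(vocab_size))
    countries <- paste0("C", seq_len(n_countries))
    pairs <- t(replicate(n, sample(countries, 2)))
    treaty_corpus(tibble::tibble(
      treaty_id = sprintf("R%03d", seq_len(n)),
      country_a = pairs[, 1],
      country_b = pairs[, 2],
      date_signed = as.Date("2000-01-01") + sample.int(7000, n,
                                                       replace = TRUE),
      categories = sample(category_levels(), n, replace = TRUE),
      clause_text = replicate(n, paste(sample(vocab, clause_len,
                                              replace = TRUE),
                                       collapse = " "))
    ))
  })
}
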