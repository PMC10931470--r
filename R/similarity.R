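#' Fit a TF-IDF model on tokenised documents
#'
#' Builds the corpus vocabulary and per-term document frequencies used to
#' weight terms. The weight of term \eqn{i} in document \eqn{j} is
#' \deqn{w_{i,j} = TF_{i,j} \times \log(N / DF_i)}
#' where \eqn{TF_{i,j}} is the relative frequency of the term within the
#' document (occurrences divided by document length), \eqn{N} the number of
#' documents, and \eqn{DF_i} the number of documents containing the term.
#' No smoothing is applied; a term present in every document has IDF 0 and
#' therefore weight 0 everywhere.
#'
#' @param docs Named list (by treaty id) of token vectors, e.g. from
#'   [tokenize_corpus()].
#' @param vocabulary Optional character vector restricting the model to a
#'   subset of terms (every term must occur in at least one document).
#'   Relative term frequencies are still computed over the full document
#'   length, so restricting the vocabulary does not change the TF of the
#'   retained terms.
#' @param log_base Base of the IDF logarithm. Natural log by default; cosine
#'   similarity is invariant to this choice because changing base rescales
#'   every weight of a model by the same positive constant.
#' @return A `tfidf_model` with fields `N`, `vocabulary`, `df`, `idf`,
#'   `log_base`.
#' @export
fit_tfidf <- function(docs, vocabulary = NULL, log_base = exp(1)) {
  if (length(docs) == 0) stop("cannot fit TF-IDF on an empty corpus",
                              call. = FALSE)
  if (is.null(names(docs)) || any(!nzchar(names(docs)))) {
    names(docs) <- if (is.null(names(docs))) as.character(seq_along(docs))
                   else names(docs)
  }
  n_tok <- vapply(docs, length, integer(1))
  if (any(n_tok == 0)) {
    stop("document(s) empty after preprocessing: ",
         paste(names(docs)[n_tok == 0], collapse = ", "), call. = FALSE)
  }
  uniq <- lapply(docs, unique)
  df_tab <- table(unlist(uniq, use.names = FALSE))
  all_terms <- sort(names(df_tab))
  if (is.null(vocabulary)) {
    vocabulary <- all_terms
  } else {
    vocabulary <- unique(as.character(vocabulary))
    absent <- setdiff(vocabulary, all_terms)
    if (length(absent) > 0) {
      stop("vocabulary term(s) absent from the corpus: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  df <- as.integer(df_tab[vocabulary])
  names(df) <- vocabulary
  N <- length(docs)
  idf <- log(N / df) / log(log_base)
  structure(list(N = N, vocabulary = vocabulary, df = df, idf = idf,
                 log_base = log_base,
                 model_id = rlang::hash(list(N, vocabulary, df, log_base))),
            class = "tfidf_model")
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat("<tfidf_model> N =", x$N, "documents,", length(x$vocabulary),
      "terms, log base", format(x$log_base), "\n")
  invisible(x)
}

#' TF-IDF vector for one document
#'
#' @param tokens Token vector for the document (terms outside the model
#'   vocabulary contribute to the document length but receive no weight).
#' @param model A [fit_tfidf()] model.
#' @param treaty_id Optional document id carried on the result.
#' @return A `tfidf_vector`: named numeric weights over the vocabulary terms
#'   present in the document (possibly 0 where IDF vanishes).
#' @export
vectorize <- function(tokens, model, treaty_id = NULL) {
  stopifnot(inherits(model, "tfidf_model"))
  if (length(tokens) == 0) stop("cannot vectorise a zero-length document",
                                call. = FALSE)
  len <- length(tokens)
  counts <- table(tokens[tokens %in% model$vocabulary])
  w <- (as.numeric(counts) / len) * model$idf[names(counts)]
  names(w) <- names(counts)
  structure(w, treaty_id = treaty_id, model_id = model$model_id,
            class = "tfidf_vector")
}

#' Cosine similarity of two TF-IDF vectors
#'
#' Standard cosine of the angle between the two weight vectors. Because all
#' TF-IDF weights are non-negative the score lies in \[0, 1\]. Vectors with
#' vanishing norm (every term shared by all documents, so all IDFs are 0)
#' follow the convention: both norms zero gives 1 (the documents are
#' indistinguishable over the modelled terms), exactly one zero gives 0.
#'
#' @param u,v `tfidf_vector`s from the same model.
#' @return Similarity score in \[0, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (!identical(attr(u, "model_id"), attr(v, "model_id"))) {
    stop("cosine_similarity: vectors come from different TF-IDF models",
         call. = FALSE)
  }
  nu <- sqrt(sum(unclass(u)^2))
  nv <- sqrt(sum(unclass(v)^2))
  if (nu == 0 && nv == 0) return(1)
  if (nu == 0 || nv == 0) return(0)
  common <- intersect(names(u), names(v))
  dot <- if (length(common) == 0) 0 else
    sum(unclass(u)[common] * unclass(v)[common])
  min(max(dot / (nu * nv), 0), 1)
}

#' All pairwise clause similarities in a corpus
#'
#' Preprocesses every clause, fits a TF-IDF model on the corpus, and scores
#' every unordered pair of documents by cosine similarity: \eqn{N} documents
#' give \eqn{N(N-1)/2} scores. Pairs are emitted in lexicographic order of
#' corpus position, so output is reproducible.
#'
#' @param corpus A `treaty_corpus` with at least 2 records.
#' @param config A [preprocess_config()].
#' @param log_base IDF logarithm base (scores are invariant to it).
#' @return A `similarity_pairs` tibble with columns `id_a`, `id_b`, `score`
#'   and attributes `n_docs` and `label`.
#' @export
pairwise_similarities <- function(corpus, config = preprocess_config(),
                                  log_base = exp(1)) {
  if (nrow(corpus) < 2) {
    stop("pairwise similarity needs at least 2 documents", call. = FALSE)
  }
  docs <- tokenize_corpus(corpus, config)
  model <- fit_tfidf(docs, log_base = log_base)
  W <- tfidf_matrix(docs, model)
  norms <- sqrt(Matrix::rowSums(W^2))
  zero <- norms == 0
  scale <- ifelse(zero, 1, norms)
  Wn <- W / scale
  S <- as.matrix(Matrix::tcrossprod(Wn))
  # zero-norm convention: both zero -> 1, exactly one zero -> 0
  if (any(zero)) {
    S[zero, ] <- 0
    S[, zero] <- 0
    S[zero, zero] <- 1
  }
  idx <- which(upper.tri(S), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  scores <- pmin(pmax(S[idx], 0), 1)
  out <- tibble::tibble(id_a = corpus$treaty_id[idx[, 1]],
                        id_b = corpus$treaty_id[idx[, 2]],
                        score = scores)
  structure(out, n_docs = nrow(corpus), label = corpus_label(corpus),
            class = c("similarity_pairs", class(tibble::tibble())))
}

# sparse document-term weight matrix (documents x vocabulary)
tfidf_matrix <- function(docs, model) {
  vocab_index <- stats::setNames(seq_along(model$vocabulary),
                                 model$vocabulary)
  triplets <- lapply(seq_along(docs), function(j) {
    toks <- docs[[j]]
    toks <- toks[toks %in% model$vocabulary]
    if (length(toks) == 0) return(NULL)
    counts <- table(toks)
    cbind(j, vocab_index[names(counts)],
          (as.numeric(counts) / length(docs[[j]])) * model$idf[names(counts)])
  })
  trip <- do.call(rbind, triplets)
  Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                       dims = c(length(docs), length(model$vocabulary)))
}

#' Summary statistics of a similarity-score distribution
#'
#' The eight descriptive statistics conventionally tabulated for a pairwise
#' similarity distribution: count, mean, standard deviation (sample, n-1),
#' minimum, quartiles and median (linear-interpolation quantiles), maximum.
#'
#' @param pairs A `similarity_pairs` table with at least one pair.
#' @return A one-row tibble with columns `count`, `mean`, `sd`, `min`, `q25`,
#'   `median`, `q75`, `max`.
#' @export
summarize_similarities <- function(pairs) {
  if (nrow(pairs) == 0) stop("no similarity pairs to summarise",
                             call. = FALSE)
  s <- pairs$score
  q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(count = length(s), mean = mean(s),
                 sd = if (length(s) > 1) stats::sd(s) else 0,
                 min = min(s), q25 = q[1], median = q[2], q75 = q[3],
                 max = max(s))
}

#' Retrospective percentile-based threshold selection
#'
#' Selecting the similarity cutoff retrospectively from the score
#' distribution: the returned threshold is the smallest observed score
#' \eqn{t} such that at least `ceiling` of all scores are \eqn{\le t}
#' (the empirical quantile of the score multiset). With 90 scores 0.01,
#' 0.02, ..., 0.90 and a 60% ceiling this returns 0.54.
#'
#' @param pairs A `similarity_pairs` table, or a bare numeric score vector.
#' @param ceiling Fraction in (0, 1): the proportion of scores the threshold
#'   must sit above (or tie with).
#' @return The selected threshold, an observed score value.
#' @export
select_threshold <- function(pairs, ceiling) {
  scores <- if (is.numeric(pairs)) pairs else pairs$score
  if (length(scores) == 0) stop("no scores to select a threshold from",
                                call. = FALSE)
  if (!is.numeric(ceiling) || length(ceiling) != 1 ||
      ceiling <= 0 || ceiling >= 1) {
    stop("ceiling must be a fraction strictly between 0 and 1",
         call. = FALSE)
  }
  sorted <- sort(scores)
  sorted[ceiling(ceiling * length(sorted))]
}

#' Histogram export of a similarity distribution
#'
#' Writes fixed-width bins with per-bin and cumulative counts, the data
#' behind a cumulative-distribution chart of the scores.
#'
#' @param pairs A `similarity_pairs` table.
#' @param path Output CSV path.
#' @param bins Number of equal-width bins over \[0, 1\].
#' @return `path`, invisibly.
#' @export
export_similarity_histogram <- function(pairs, path, bins = 50) {
  edges <- seq(0, 1, length.out = bins + 1)
  cut_idx <- pmin(findInterval(pairs$score, edges, rightmost.closed = TRUE),
                  bins)
  counts <- tabulate(cut_idx, nbins = bins)
  out <- tibble::tibble(bin_low = edges[-(bins + 1)], bin_high = edges[-1],
                        count = counts, cumulative = cumsum(counts))
  readr::write_csv(out, path)
  invisible(path)
}
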