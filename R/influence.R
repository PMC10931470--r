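#' Retain high-similarity pairs at a threshold
#'
#' Keeps every pair whose score is at least `t` (inclusive). The retained
#' pairs (M of them) reference a multiset of 2M document ids, the raw
#' material for the document weighting. Scores are compared after rounding
#' to 12 decimal places so platform-level floating-point noise cannot flip a
#' tie. M = 0 is legal and flows through the pipeline as an all-zero result.
#'
#' @param pairs A `similarity_pairs` table.
#' @param t Threshold in \[0, 1\].
#' @return A `thresholded_pairs` list with fields `threshold`, `pairs`
#'   (the retained rows), `M`, and `doc_ids` (the 2M-element id multiset).
#' @export
filter_pairs <- function(pairs, t) {
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 1) {
    stop("threshold t must be a number in [0, 1]", call. = FALSE)
  }
  keep <- round(pairs$score, 12) >= round(t, 12)
  retained <- pairs[keep, , drop = FALSE]
  structure(list(threshold = t,
                 pairs = tibble::as_tibble(retained),
                 M = nrow(retained),
                 doc_ids = c(rbind(retained$id_a, retained$id_b))),
            class = "thresholded_pairs")
}

#' @export
print.thresholded_pairs <- function(x, ...) {
  cat("<thresholded_pairs> t =", format(x$threshold), ", M =", x$M,
      "retained pair(s)\n")
  invisible(x)
}

#' Frequency weights of the distinct retained documents
#'
#' Counts how often each distinct document appears among the 2M document
#' slots of the retained pairs, then normalises each frequency by 2M so the
#' weights sum to 1. Documents recurring across many high-similarity pairs
#' receive proportionally more weight.
#'
#' @param tps A `thresholded_pairs` object from [filter_pairs()].
#' @return A `doc_weight_table` tibble with columns `treaty_id`, `frequency`,
#'   `weight` and attributes `M`, `D`, `threshold`. With M = 0 the table is
#'   empty, a signal consumed by [compute_inf()].
#' @export
doc_weights <- function(tps) {
  stopifnot(inherits(tps, "thresholded_pairs"))
  if (tps$M == 0) {
    out <- tibble::tibble(treaty_id = character(), frequency = integer(),
                          weight = numeric())
  } else {
    freq <- table(tps$doc_ids)
    out <- tibble::tibble(treaty_id = names(freq),
                          frequency = as.integer(freq),
                          weight = as.integer(freq) / (2 * tps$M))
    out <- out[order(out$treaty_id), , drop = FALSE]
  }
  structure(out, M = tps$M, D = nrow(out), threshold = tps$threshold,
            class = c("doc_weight_table", class(tibble::tibble())))
}

#' Aggregate document weights into per-country influence scores
#'
#' The influence (INF) score of a country is the sum of the normalised
#' weights of the distinct high-similarity documents in which it is one of
#' the two parties. Scores lie in \[0, 1\]; since each document carries
#' exactly two distinct parties, the scores across all countries sum to 2
#' whenever at least one pair was retained. Countries present in the corpus
#' but absent from every retained document are reported with INF 0, so
#' rankings are comparable across thresholds.
#'
#' @param weights A [doc_weights()] table.
#' @param corpus The `treaty_corpus` the weights refer to.
#' @return An `influence_table` tibble with columns `country`, `inf`
#'   (descending, ties broken lexically) and attributes `threshold`, `M`,
#'   `D`, `label`, `no_pairs` (TRUE when M = 0).
#' @export
compute_inf <- function(weights, corpus) {
  stopifnot(inherits(weights, "doc_weight_table"))
  countries <- sort(unique(c(corpus$country_a, corpus$country_b)))
  inf <- stats::setNames(numeric(length(countries)), countries)
  no_pairs <- nrow(weights) == 0
  if (no_pairs) {
    warning("no pairs retained at threshold ",
            format(attr(weights, "threshold")),
            "; all INF scores are 0 (insufficient data)", call. = FALSE)
  } else {
    missing_ids <- setdiff(weights$treaty_id, corpus$treaty_id)
    if (length(missing_ids) > 0) {
      stop("weighted document id(s) not in corpus: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    pos <- match(weights$treaty_id, corpus$treaty_id)
    for (k in seq_along(pos)) {
      w <- weights$weight[k]
      inf[corpus$country_a[pos[k]]] <- inf[corpus$country_a[pos[k]]] + w
      inf[corpus$country_b[pos[k]]] <- inf[corpus$country_b[pos[k]]] + w
    }
  }
  out <- tibble::tibble(country = countries, inf = as.numeric(inf))
  out <- out[order(-out$inf, out$country), , drop = FALSE]
  structure(out, threshold = attr(weights, "threshold"),
            M = attr(weights, "M"), D = attr(weights, "D"),
            label = corpus_label(corpus), no_pairs = no_pairs,
            class = c("influence_table", class(tibble::tibble())))
}

#' @export
print.influence_table <- function(x, ...) {
  cat("<influence_table> t =", format(attr(x, "threshold")),
      " M =", attr(x, "M"), " D =", attr(x, "D"),
      if (nzchar(attr(x, "label") %||% "")) paste0(" [", attr(x, "label"), "]")
      else "", "\n", sep = "")
  NextMethod()
}

#' Full influence pipeline
#'
#' Runs the four-stage calculation end to end: preprocess each clause, score
#' every document pair by TF-IDF cosine similarity, retain pairs at the
#' threshold (either given directly or selected as an empirical quantile of
#' the score distribution via `ceiling`), weight the distinct retained
#' documents by normalised frequency, and aggregate weights per country.
#'
#' @param corpus A `treaty_corpus` with at least 2 records.
#' @param config A [preprocess_config()].
#' @param threshold Similarity cutoff in \[0, 1\]. Exactly one of
#'   `threshold` and `ceiling` must be given.
#' @param ceiling Fraction in (0, 1) passed to [select_threshold()].
#' @return An `influence_table` (see [compute_inf()]); its attributes record
#'   the threshold used, M and D.
#' @export
inf_pipeline <- function(corpus, config = preprocess_config(),
                         threshold = NULL, ceiling = NULL) {
  if (is.null(threshold) == is.null(ceiling)) {
    stop("exactly one of threshold and ceiling must be given", call. = FALSE)
  }
  pairs <- pairwise_similarities(corpus, config)
  t <- if (is.null(threshold)) select_threshold(pairs, ceiling) else threshold
  compute_inf(doc_weights(filter_pairs(pairs, t)), corpus)
}

#' Detect the hub of a star-topology corpus
#'
#' A corpus whose treaties all share one common party forms a star network;
#' that hub country attains INF 1 at any threshold retaining at least one
#' pair. Returns the hub when exactly one country appears in every record,
#' otherwise `NULL` (a single-record corpus has two such countries and is
#' ambiguous).
#'
#' @param corpus A non-empty `treaty_corpus`.
#' @return The hub country name, or `NULL`.
#' @export
detect_star <- function(corpus) {
  if (nrow(corpus) == 0) return(NULL)
  common <- Reduce(intersect,
                   Map(c, corpus$country_a, corpus$country_b))
  if (length(common) == 1) common else NULL
}

#' Export the treaty network as an edge list
#'
#' One edge per record, labelled with the signature date, in corpus order:
#' the dyadic network behind the influence scores (a star when one country
#' is party to every treaty).
#'
#' @param corpus A `treaty_corpus`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_edgelist <- function(corpus, path) {
  out <- tibble::tibble(country_a = corpus$country_a,
                        country_b = corpus$country_b,
                        date_signed = format(corpus$date_signed, "%Y-%m-%d"),
                        treaty_id = corpus$treaty_id)
  readr::write_csv(out, path)
  invisible(path)
}
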