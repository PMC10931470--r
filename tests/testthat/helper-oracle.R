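# Brute-force reference implementation of the whole influence calculation,
# written with explicit loops and dense matrices, independent of the package
# internals. Documents are tokenised by whitespace splitting, so it applies
# to corpora whose clauses are plain space-separated lower-case words.

oracle_tfidf_matrix <- function(clauses) {
  docs <- strsplit(clauses, " +")
  N <- length(docs)
  vocab <- sort(unique(unlist(docs)))
  df <- vapply(vocab, function(term) {
    sum(vapply(docs, function(d) term %in% d, logical(1)))
  }, numeric(1))
  W <- matrix(0, N, length(vocab), dimnames = list(NULL, vocab))
  for (j in seq_len(N)) {
    for (term in vocab) {
      tf <- sum(docs[[j]] == term) / length(docs[[j]])
      W[j, term] <- tf * log(N / df[[term]])
    }
  }
  W
}

oracle_cosine <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Materialises every intermediate multiset explicitly: all C(N,2) scores,
# the retained pairs, the 2M document slots, per-document frequencies, and
# the per-country sums.
oracle_inf <- function(corpus, t) {
  W <- oracle_tfidf_matrix(corpus$clause_text)
  N <- nrow(corpus)
  slots <- character(0)
  for (i in seq_len(N - 1)) {
    for (j in seq(i + 1, N)) {
      s <- oracle_cosine(W[i, ], W[j, ])
      if (round(s, 12) >= round(t, 12)) {
        slots <- c(slots, corpus$treaty_id[i], corpus$treaty_id[j])
      }
    }
  }
  countries <- sort(unique(c(corpus$country_a, corpus$country_b)))
  inf <- stats::setNames(numeric(length(countries)), countries)
  if (length(slots) > 0) {
    for (id in unique(slots)) {
      w <- sum(slots == id) / length(slots)
      k <- which(corpus$treaty_id == id)
      inf[corpus$country_a[k]] <- inf[corpus$country_a[k]] + w
      inf[corpus$country_b[k]] <- inf[corpus$country_b[k]] + w
    }
  }
  inf
}

# Streaming-moment + manual linear-interpolation quantile reference for the
# similarity summary.
oracle_summary <- function(scores) {
  n <- length(scores)
  s1 <- 0; s2 <- 0
  for (x in scores) { s1 <- s1 + x; s2 <- s2 + x^2 }
  mean <- s1 / n
  var <- if (n > 1) (s2 - n * mean^2) / (n - 1) else 0
  qlin <- function(p) {
    srt <- sort(scores)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    srt[lo] + (h - lo) * (srt[hi] - srt[lo])
  }
  list(count = n, mean = mean, sd = sqrt(max(var, 0)), min = min(scores),
       q25 = qlin(0.25), median = qlin(0.5), q75 = qlin(0.75),
       max = max(scores))
}

# Order-statistic reference for threshold selection: the smallest observed
# value with at least frac * n of the scores at or below it.
oracle_threshold <- function(scores, frac) {
  srt <- sort(scores)
  n <- length(srt)
  for (v in unique(srt)) {
    if (sum(srt <= v) >= frac * n) return(v)
  }
  srt[n]
}
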