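make_pairs <- function(id_a, id_b, score) {
  structure(tibble::tibble(id_a = id_a, id_b = id_b, score = score),
            class = c("similarity_pairs", class(tibble::tibble())))
}

test_that("threshold filtering is inclusive and counts the 2M doc slots", {
  pairs <- make_pairs(c("A", "A", "B"), c("B", "C", "C"), c(0.9, 0.8, 0.6))
  tps <- filter_pairs(pairs, 0.8)
  expect_equal(tps$M, 2)
  expect_length(tps$doc_ids, 4)
  expect_equal(sort(tps$doc_ids), c("A", "A", "B", "C"))
  expect_equal(filter_pairs(pairs, 0)$M, 3)       # vacuous threshold
  expect_equal(filter_pairs(pairs, 0.95)$M, 0)    # M = 0 is legal
  expect_error(filter_pairs(pairs, 1.2), "in \\[0, 1\\]")
  # brute-force count on random scores
  withr::with_seed(3, s <- stats::runif(200))
  rnd <- make_pairs(paste0("a", 1:200), paste0("b", 1:200), s)
  expect_equal(filter_pairs(rnd, 0.7)$M, sum(s >= 0.7))
})

test_that("near-tie scores compare after rounding to 12 decimals", {
  pairs <- make_pairs("A", "B", 0.7 - 1e-14)
  expect_equal(filter_pairs(pairs, 0.7)$M, 1)
  expect_equal(filter_pairs(make_pairs("A", "B", 0.7 - 1e-10), 0.7)$M, 0)
})

test_that("document weights are normalised frequencies over the 2M slots", {
  tps <- filter_pairs(make_pairs(c("A", "A"), c("B", "C"), c(0.9, 0.9)), 0.5)
  w <- doc_weights(tps)
  expect_equal(stats::setNames(w$weight, w$treaty_id),
               c(A = 0.5, B = 0.25, C = 0.25))
  expect_equal(sum(w$frequency), 2 * tps$M)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  single <- doc_weights(filter_pairs(make_pairs("A", "B", 0.9), 0.5))
  expect_equal(single$weight, c(0.5, 0.5))
  empty <- doc_weights(filter_pairs(make_pairs("A", "B", 0.1), 0.9))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "M"), 0)
})

test_that("influence aggregates document weights per party country", {
  corpus <- tiny_corpus()
  pairs <- pairwise_similarities(corpus, passthrough_config())
  tab <- compute_inf(doc_weights(filter_pairs(pairs, 0.9)), corpus)
  # records T1-T3 share a clause: retained pairs (T1,T2),(T1,T3),(T2,T3)
  expect_equal(attr(tab, "M"), 3)
  expect_equal(attr(tab, "D"), 3)
  inf <- stats::setNames(tab$inf, tab$country)
  expect_equal(unname(inf["Canada"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(inf["Singapore"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(inf["Nigeria"]), 2 / 3, tolerance = 1e-12)
  # parties only in unretained documents are present with INF 0
  expect_equal(unname(inf["Spain"]), 0)
  expect_equal(unname(inf["Ghana"]), 0)
  expect_equal(sum(tab$inf), 2, tolerance = 1e-12)
})

test_that("a weighted document id missing from the corpus is an error", {
  corpus <- tiny_corpus()
  w <- doc_weights(filter_pairs(make_pairs("T1", "ZZ9", 0.95), 0.5))
  expect_error(compute_inf(w, corpus), "not in corpus.*ZZ9")
})

test_that("an empty retained set warns and returns an all-zero table", {
  corpus <- treaty_corpus(tibble::tibble(
    treaty_id = c("U1", "U2"), country_a = c("A", "C"),
    country_b = c("B", "D"), date_signed = "2005", categories = "neutral",
    clause_text = c("alpha beta gamma", "delta epsilon zeta")))
  pairs <- pairwise_similarities(corpus, passthrough_config())
  expect_warning(
    tab <- compute_inf(doc_weights(filter_pairs(pairs, 0.5)), corpus),
    "insufficient data")
  expect_true(all(tab$inf == 0))
  expect_true(attr(tab, "no_pairs"))
  expect_setequal(tab$country,
                  unique(c(corpus$country_a, corpus$country_b)))
})

test_that("pipeline equals the explicit composition and records metadata", {
  corpus <- tiny_corpus()
  cfg <- passthrough_config()
  direct <- compute_inf(
    doc_weights(filter_pairs(pairwise_similarities(corpus, cfg), 0.7)),
    corpus)
  piped <- inf_pipeline(corpus, cfg, threshold = 0.7)
  expect_equal(piped$inf, direct$inf)
  expect_equal(piped$country, direct$country)
  expect_equal(attr(piped, "threshold"), 0.7)
  expect_error(inf_pipeline(corpus, cfg), "exactly one")
  expect_error(inf_pipeline(corpus, cfg, threshold = 0.5, ceiling = 0.9),
               "exactly one")
})

test_that("two identical clauses sharing country X give X twice the leaf score", {
  corpus <- treaty_corpus(tibble::tibble(
    treaty_id = c("P1", "P2"),
    country_a = c("X", "X"),
    country_b = c("Y", "Z"),
    date_signed = c("2001", "2002"),
    categories = "neutral",
    clause_text = "the host state shall maintain sanitary standards"
  ))
  tab <- inf_pipeline(corpus, passthrough_config(), threshold = 0.9)
  inf <- stats::setNames(tab$inf, tab$country)
  expect_equal(unname(inf["X"]), 1)
  expect_equal(unname(inf["Y"]), 0.5)
  expect_equal(unname(inf["Z"]), 0.5)
})

test_that("INF invariants hold across random corpora and thresholds", {
  for (seed in 1:10) {
    n <- 4 + (seed %% 5)
    corpus <- random_corpus(n, seed = 400 + seed)
    for (t in c(0.2, 0.5, 0.8)) {
      tab <- suppressWarnings(
        inf_pipeline(corpus, passthrough_config(), threshold = t))
      expect_true(all(tab$inf >= 0 & tab$inf <= 1))
      if (attr(tab, "M") >= 1) {
        expect_equal(sum(tab$inf), 2, tolerance = 1e-12)
      } else {
        expect_true(all(tab$inf == 0))
      }
    }
  }
})

test_that("pipeline matches the brute-force enumeration oracle", {
  for (seed in 1:25) {
    n <- 3 + (seed %% 8)
    corpus <- random_corpus(n, seed = 900 + seed)
    t <- c(0.3, 0.5, 0.7, 0.9)[1 + (seed %% 4)]
    got <- suppressWarnings(
      inf_pipeline(corpus, passthrough_config(), threshold = t))
    want <- oracle_inf(corpus, t)
    expect_equal(stats::setNames(got$inf, got$country)[names(want)], want,
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("higher thresholds do not monotonically raise INF", {
  # a documented counter-example: raising t can drop a country's score
  corpus <- treaty_corpus(tibble::tibble(
    treaty_id = c("A", "B", "C"),
    country_a = c("P", "P", "Q"),
    country_b = c("Q", "R", "R"),
    date_signed = "2010",
    categories = "defensive",
    clause_text = c("alpha beta gamma delta",
                    "alpha beta gamma epsilon",
                    "alpha beta zeta eta")
  ))
  cfg <- passthrough_config()
  pairs <- pairwise_similarities(corpus, cfg)
  s <- sort(pairs$score, decreasing = TRUE)
  low <- inf_pipeline(corpus, cfg, threshold = s[2])
  high <- inf_pipeline(corpus, cfg, threshold = s[1])
  inf_low <- stats::setNames(low$inf, low$country)
  inf_high <- stats::setNames(high$inf, high$country)
  expect_lt(inf_high["Q"], inf_low["Q"])
})

test_that("star detection returns the unique common country or nothing", {
  star <- generate_star_corpus("Brazil", 6, mutation_rate = 0, seed = 1)
  expect_equal(detect_star(star), "Brazil")
  disjoint <- treaty_corpus(tibble::tibble(
    treaty_id = c("X1", "X2"), country_a = c("A", "C"),
    country_b = c("B", "D"), date_signed = "2000",
    categories = "neutral", clause_text = "text"))
  expect_null(detect_star(disjoint))
  expect_null(detect_star(disjoint[1, ]))  # single record is ambiguous
  expect_null(detect_star(disjoint[0, ]))
  for (k in c(3, 9, 20)) {
    rs <- generate_star_corpus("Finland", k, mutation_rate = 0.3,
                               seed = 50 + k)
    expect_equal(detect_star(rs), "Finland")
  }
})

test_that("edge list export is one dated edge per record", {
  star <- generate_star_corpus("Brazil", 6, mutation_rate = 0, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  export_edgelist(star, path)
  edges <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(edges), 6)
  expect_true(all(edges$country_a == "Brazil" | edges$country_b == "Brazil"))
  expect_equal(edges$treaty_id, star$treaty_id)
  expect_false(anyNA(as.Date(edges$date_signed)))
  empty <- star[0, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_edgelist(empty, path2)
  expect_length(readLines(path2), 1)
})
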