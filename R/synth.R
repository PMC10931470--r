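# Closed vocabulary of treaty-flavoured tokens used to build synthetic
# clauses; mutation substitutes tokens uniformly from this pool, giving
# continuous control over expected pairwise similarity.
treaty_vocabulary <- function() {
  c("investment", "investor", "agreement", "treaty", "contracting", "party",
    "measure", "health", "public", "protection", "protect", "safeguard",
    "clause", "policy", "regulation", "dispute", "settlement", "arbitration",
    "expropriation", "compensation", "national", "treatment", "fair",
    "equitable", "territory", "enterprise", "capital", "transfer", "state",
    "host", "foreign", "market", "access", "standard", "provision",
    "article", "exception", "obligation", "promote", "encourage",
    "sustainable", "development", "environment", "sanitary", "welfare",
    "security", "tobacco", "pharmaceutical", "right", "sovereign",
    "necessary", "legitimate", "objective", "ensure", "maintain", "adopt",
    "enforce", "restrict", "benefit", "economic")
}

# Pool of party names for generated corpora; extended with numbered state
# names when a generator needs more than the pool provides.
country_pool <- function(n = NULL) {
  pool <- c("Germany", "Canada", "Brazil", "Turkey", "Finland", "USA",
            "Mauritius", "Singapore", "Kuwait", "China", "Egypt", "Ethiopia",
            "Oman", "Yemen", "BLEU", "Ecuador", "UAE", "Guyana", "Suriname",
            "Bangladesh", "Ghana", "Jordan", "Guinea", "Cameroon", "Kosovo",
            "Spain", "Nigeria", "France", "Italy", "Japan", "Korea", "India",
            "Pakistan", "Indonesia", "Malaysia", "Thailand", "Vietnam",
            "Chile", "Peru", "Argentina", "Mexico", "Colombia", "Morocco",
            "Tunisia", "Kenya", "Tanzania", "Uganda", "Senegal", "Poland",
            "Hungary", "Romania", "Bulgaria", "Croatia", "Serbia", "Albania",
            "Georgia", "Armenia", "Mongolia", "Nepal", "Laos")
  if (is.null(n)) return(pool)
  if (n <= length(pool)) return(pool[seq_len(n)])
  c(pool, sprintf("State%03d", seq_len(n - length(pool))))
}

mutate_clause <- function(text, mutation_rate, vocab = treaty_vocabulary()) {
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  hit <- stats::runif(length(toks)) < mutation_rate
  if (any(hit)) {
    toks[hit] <- sample(vocab, sum(hit), replace = TRUE)
  }
  paste(toks, collapse = " ")
}

default_base_clause <- function(length = 40) {
  paste(rep(c("the contracting party shall protect public health measure",
              "and ensure fair equitable treatment of foreign investment"),
            length.out = length), collapse = " ")
}

#' Generate a star-topology treaty corpus
#'
#' Every generated treaty has the hub country as one party and a distinct
#' leaf country as the other; all clauses derive from one base clause with
#' independent per-token mutations. With `mutation_rate = 0` all clauses are
#' identical, every pairwise similarity is 1, and the hub attains INF 1 at
#' any threshold.
#'
#' @param hub Hub country name.
#' @param n_leaves Number of leaf countries (distinct treaties).
#' @param base_clause Clause text to replicate; a built-in treaty-flavoured
#'   clause by default.
#' @param mutation_rate Per-token substitution probability in \[0, 1\].
#' @param seed Integer seed; fixes all randomness.
#' @param categories Category label(s) given to every record.
#' @return A `treaty_corpus` of `n_leaves` records.
#' @export
generate_star_corpus <- function(hub, n_leaves, base_clause = NULL,
                                 mutation_rate = 0, seed = 1,
                                 categories = "offensive") {
  stopifnot(n_leaves >= 1)
  leaves <- setdiff(country_pool(), hub)
  if (n_leaves > length(leaves)) {
    stop("n_leaves exceeds the ", length(leaves),
         " available leaf country names", call. = FALSE)
  }
  if (is.null(base_clause)) base_clause <- default_base_clause()
  withr::with_seed(seed, {
    leaves <- leaves[seq_len(n_leaves)]
    dates <- sort(as.Date("2018-03-01") +
                    sample.int(700, n_leaves, replace = FALSE))
    clauses <- vapply(seq_len(n_leaves), function(i) {
      mutate_clause(base_clause, mutation_rate)
    }, character(1))
    treaty_corpus(tibble::tibble(
      treaty_id = sprintf("STAR%03d", seq_len(n_leaves)),
      country_a = hub,
      country_b = leaves,
      date_signed = dates,
      categories = list(categories),
      clause_text = clauses
    ), label = paste0("synthetic star hub=", hub))
  })
}

#' Parameters for the synthetic diffusion-corpus generator
#'
#' Defaults emulate the structure of a real health-safeguard BIT corpus:
#' 555 dyadic treaties signed over 1959-2021, category labels drawn with
#' weights proportional to the defensive/neutral/offensive class sizes
#' (419/263/22 per-class slots), 125/555 of records carrying two labels and
#' 12/555 three, and clause texts produced by template reuse with token
#' mutation so the pairwise similarity distribution is right-skewed.
#'
#' @param n_treaties Number of records to generate.
#' @param n_countries Number of distinct party names to draw from.
#' @param hub Optional country seeded as the dominant clause disseminator;
#'   copied clauses always involve the hub as a party.
#' @param n_templates Number of distinct base clauses.
#' @param mutation_rate Per-token substitution probability in \[0, 1\].
#' @param copy_prob Probability that a new treaty copies an earlier treaty's
#'   clause (a hub treaty, when `hub` is set) instead of starting from a
#'   fresh template.
#' @param year_range `c(first_year, last_year)` for signature dates.
#' @param category_weights Named weights over the three categories.
#' @param p_two_labels,p_three_labels Probability a record receives a second
#'   (resp. third) category label.
#' @param template_length Tokens per clause template.
#' @param seed Integer seed; fixes all randomness.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_treaties = 555, n_countries = 120, hub = NULL,
                         n_templates = 25, mutation_rate = 0.05,
                         copy_prob = 0.5, year_range = c(1959, 2021),
                         category_weights = c(defensive = 419, neutral = 263,
                                              offensive = 22),
                         p_two_labels = 125 / 555,
                         p_three_labels = 12 / 555,
                         template_length = 40, seed = 1) {
  stopifnot(n_treaties >= 1, n_countries >= 2,
            mutation_rate >= 0, mutation_rate <= 1,
            copy_prob >= 0, copy_prob <= 1,
            n_templates >= 1, length(year_range) == 2,
            year_range[1] <= year_range[2])
  structure(list(n_treaties = n_treaties, n_countries = n_countries,
                 hub = hub, n_templates = n_templates,
                 mutation_rate = mutation_rate, copy_prob = copy_prob,
                 year_range = year_range,
                 category_weights = category_weights,
                 p_two_labels = p_two_labels,
                 p_three_labels = p_three_labels,
                 template_length = template_length, seed = seed),
            class = "synth_params")
}

#' Generate a synthetic treaty corpus with known diffusion structure
#'
#' Treaties are generated in signature-date order. Each new treaty either
#' copies the clause of a uniformly chosen earlier treaty (one involving the
#' hub, when a hub is set) with probability `copy_prob`, or instantiates a
#' fresh random template; either way the clause is then mutated token-wise
#' at `mutation_rate`. Copying treaties involve the hub as one party, so the
#' hub is the planted ground-truth top influencer. Low `copy_prob` yields
#' the right-skewed pairwise-similarity distribution typical of real treaty
#' corpora.
#'
#' @param params A [synth_params()] list.
#' @return A list with elements `corpus` (a `treaty_corpus`) and
#'   `ground_truth` (list with the planted `hub`, or `NULL` hub when none
#'   was set).
#' @export
generate_diffusion_corpus <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  vocab <- treaty_vocabulary()
  withr::with_seed(p$seed, {
    countries <- country_pool(p$n_countries)
    hub <- p$hub
    others <- setdiff(countries, hub)
    templates <- replicate(p$n_templates,
                           paste(sample(vocab, p$template_length,
                                        replace = TRUE), collapse = " "))
    years <- sort(sample(seq(p$year_range[1], p$year_range[2]),
                         p$n_treaties, replace = TRUE))
    dates <- as.Date(sprintf("%d-01-01", years)) +
      sample.int(364, p$n_treaties, replace = TRUE) - 1
    dates <- sort(dates)
    cats <- lapply(seq_len(p$n_treaties), function(i) {
      w <- p$category_weights[category_levels()]
      w[is.na(w)] <- 0
      k <- 1 + (stats::runif(1) < p$p_two_labels) +
        (stats::runif(1) < p$p_three_labels)
      k <- min(k, sum(w > 0))
      sample(category_levels()[w > 0], k, prob = w[w > 0] / sum(w[w > 0]))
    })
    clauses <- character(p$n_treaties)
    country_a <- character(p$n_treaties)
    country_b <- character(p$n_treaties)
    hub_idx <- integer(0)
    for (i in seq_len(p$n_treaties)) {
      copy_pool <- if (is.null(hub)) seq_len(i - 1) else hub_idx
      copies <- length(copy_pool) > 0 && stats::runif(1) < p$copy_prob
      base <- if (copies) {
        clauses[copy_pool[sample.int(length(copy_pool), 1)]]
      } else {
        templates[sample.int(p$n_templates, 1)]
      }
      clauses[i] <- mutate_clause(base, p$mutation_rate, vocab)
      if (!is.null(hub) && (copies || i == 1)) {
        country_a[i] <- hub
        country_b[i] <- sample(others, 1)
        hub_idx <- c(hub_idx, i)
      } else {
        pair <- sample(if (is.null(hub)) countries else others, 2)
        country_a[i] <- pair[1]
        country_b[i] <- pair[2]
      }
    }
    corpus <- treaty_corpus(tibble::tibble(
      treaty_id = sprintf("SYN%04d", seq_len(p$n_treaties)),
      country_a = country_a, country_b = country_b,
      date_signed = dates, categories = cats, clause_text = clauses
    ), label = "synthetic diffusion corpus")
    list(corpus = corpus, ground_truth = list(hub = hub))
  })
}
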