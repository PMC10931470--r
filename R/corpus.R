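#' @importFrom rlang .data
NULL

#' Health-safeguard clause categories
#'
#' The three clause categories a bilateral investment treaty (BIT) record may
#' carry: *defensive* clauses preserve existing health-policy space, *neutral*
#' clauses uphold current norms, and *offensive* clauses proactively advance a
#' health agenda. A record may carry more than one label.
#'
#' @return Character vector of the three valid category labels.
#' @export
category_levels <- function() c("defensive", "neutral", "offensive")

#' Construct a treaty corpus
#'
#' A corpus is an ordered collection of bilateral treaty records. Each record
#' has a unique `treaty_id`, exactly two distinct party names, a signature
#' date, one or more categories, and a non-empty clause text. Validation
#' enforces all record invariants and fails loudly (with record ids and
#' counts) rather than silently dropping offending rows.
#'
#' @param records A data frame with columns `treaty_id`, `country_a`,
#'   `country_b`, `date_signed` (`Date`, or string parseable as ISO-8601 date
#'   or bare year), `categories` (list column of character vectors, or a
#'   character column with `";"`-separated labels), `clause_text`.
#' @param label Free-text provenance label for the corpus (e.g.
#'   `"defensive 2010-2019"`).
#' @return A `treaty_corpus`: a tibble with the columns above (categories as a
#'   list column of lower-case labels, dates as `Date`) and a `label`
#'   attribute.
#' @export
treaty_corpus <- function(records, label = "") {
  df <- tibble::as_tibble(records)
  required <- c("treaty_id", "country_a", "country_b", "date_signed",
                "categories", "clause_text")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("corpus schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$treaty_id <- as.character(df$treaty_id)
  df$country_a <- as.character(df$country_a)
  df$country_b <- as.character(df$country_b)
  df$clause_text <- as.character(df$clause_text)
  df$date_signed <- parse_treaty_date(df$date_signed, df$treaty_id)
  if (!is.list(df$categories)) {
    df$categories <- lapply(strsplit(as.character(df$categories), ";",
                                     fixed = TRUE),
                            function(x) trimws(x))
  }
  df$categories <- lapply(df$categories, function(x) {
    x <- tolower(trimws(as.character(x)))
    x[nzchar(x)]
  })
  validate_corpus_records(df)
  structure(df, label = as.character(label)[1],
            class = c("treaty_corpus", class(tibble::tibble())))
}

parse_treaty_date <- function(x, ids) {
  if (inherits(x, "Date")) return(x)
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  bare <- grepl("^\\d{4}$", x)
  if (any(iso)) out[iso] <- as.Date(x[iso])
  if (any(bare)) out[bare] <- as.Date(paste0(x[bare], "-01-01"))
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    stop("unparseable date_signed (expected YYYY-MM-DD or YYYY) for record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  out
}

validate_corpus_records <- function(df) {
  dup <- unique(df$treaty_id[duplicated(df$treaty_id)])
  if (length(dup) > 0) {
    stop("duplicate treaty_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  multi <- grepl(";", df$country_a, fixed = TRUE) |
    grepl(";", df$country_b, fixed = TRUE)
  if (any(multi)) {
    stop(sum(multi), " record(s) rejected: more than one party per country ",
         "slot (treaties must be bilateral): ",
         paste(df$treaty_id[multi], collapse = ", "), call. = FALSE)
  }
  same <- df$country_a == df$country_b
  if (any(same)) {
    stop(sum(same), " record(s) rejected: country_a equals country_b: ",
         paste(df$treaty_id[same], collapse = ", "), call. = FALSE)
  }
  empty_party <- !nzchar(trimws(df$country_a)) | !nzchar(trimws(df$country_b))
  if (any(empty_party)) {
    stop(sum(empty_party), " record(s) rejected: empty party name: ",
         paste(df$treaty_id[empty_party], collapse = ", "), call. = FALSE)
  }
  ncat <- vapply(df$categories, length, integer(1))
  if (any(ncat == 0)) {
    stop(sum(ncat == 0), " record(s) rejected: uncategorised: ",
         paste(df$treaty_id[ncat == 0], collapse = ", "), call. = FALSE)
  }
  unknown <- vapply(df$categories,
                    function(x) any(!x %in% category_levels()), logical(1))
  if (any(unknown)) {
    stop(sum(unknown), " record(s) rejected: unknown category label ",
         "(valid: ", paste(category_levels(), collapse = ", "), "): ",
         paste(df$treaty_id[unknown], collapse = ", "), call. = FALSE)
  }
  empty_clause <- !nzchar(trimws(df$clause_text))
  if (any(empty_clause)) {
    stop(sum(empty_clause), " record(s) rejected: empty clause_text: ",
         paste(df$treaty_id[empty_clause], collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' @export
print.treaty_corpus <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<treaty_corpus> ", nrow(x), " record(s)",
      if (nzchar(lab)) paste0("  [", lab, "]") else "", "\n", sep = "")
  NextMethod()
}

#' Corpus provenance label
#' @param corpus A `treaty_corpus`.
#' @return The label string.
#' @export
corpus_label <- function(corpus) attr(corpus, "label") %||% ""

#' Read a treaty corpus from CSV or JSON
#'
#' The CSV schema (header required) is
#' `treaty_id,country_a,country_b,date_signed,categories,clause_text`, with
#' categories as a `";"`-separated list (case-insensitive; stored lower-case)
#' and dates as ISO-8601 (`YYYY-MM-DD`) or a bare year. JSON input is an array
#' of objects with the same keys. All record invariants are validated at
#' load; invalid records abort the read with their ids reported.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; by default guessed from the file
#'   extension.
#' @param label Corpus label; defaults to the file name.
#' @return A [treaty_corpus()].
#' @export
read_corpus <- function(path, format = c("auto", "csv", "json"),
                        label = basename(path)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character())),
    json = {
      x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (length(x) == 0) {
        tibble::tibble(treaty_id = character(), country_a = character(),
                       country_b = character(), date_signed = character(),
                       categories = character(), clause_text = character())
      } else tibble::as_tibble(x)
    })
  treaty_corpus(df, label = label)
}

#' Write a treaty corpus to CSV or JSON
#'
#' Inverse of [read_corpus()]: categories are joined with `";"` and dates
#' written as ISO-8601, so a write/read round trip reproduces the corpus
#' record for record.
#'
#' @param corpus A `treaty_corpus`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("csv", "json")) {
  format <- match.arg(format)
  flat <- tibble::tibble(
    treaty_id = corpus$treaty_id,
    country_a = corpus$country_a,
    country_b = corpus$country_b,
    date_signed = format(corpus$date_signed, "%Y-%m-%d"),
    categories = vapply(corpus$categories, paste, character(1),
                        collapse = ";"),
    clause_text = corpus$clause_text
  )
  if (format == "csv") {
    readr::write_csv(flat, path)
  } else {
    jsonlite::write_json(flat, path, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Slice a corpus by clause category and/or signature period
#'
#' Keeps records whose category set contains `category` (a record labelled
#' with several categories qualifies for each of them) and whose signature
#' year falls within `period` inclusive. Record order is preserved, and the
#' two filters commute.
#'
#' @param corpus A `treaty_corpus`.
#' @param category Optional single category label (see [category_levels()]).
#' @param period Optional `c(start_year, end_year)` with `start <= end`.
#' @return The filtered `treaty_corpus`; its label is extended with the
#'   filter description.
#' @export
filter_corpus <- function(corpus, category = NULL, period = NULL) {
  keep <- rep(TRUE, nrow(corpus))
  parts <- character(0)
  if (!is.null(category)) {
    category <- tolower(as.character(category)[1])
    if (!category %in% category_levels()) {
      stop("unknown category '", category, "'; valid labels: ",
           paste(category_levels(), collapse = ", "), call. = FALSE)
    }
    keep <- keep & vapply(corpus$categories, function(x) category %in% x,
                          logical(1))
    parts <- c(parts, category)
  }
  if (!is.null(period)) {
    if (length(period) != 2 || anyNA(period)) {
      stop("period must be c(start_year, end_year)", call. = FALSE)
    }
    period <- as.integer(period)
    if (period[1] > period[2]) {
      stop("period start_year must be <= end_year", call. = FALSE)
    }
    yr <- signature_year(corpus)
    keep <- keep & yr >= period[1] & yr <= period[2]
    parts <- c(parts, paste0(period[1], "-", period[2]))
  }
  lab <- corpus_label(corpus)
  new_lab <- paste(c(if (nzchar(lab)) lab, parts), collapse = " ")
  out <- corpus[keep, , drop = FALSE]
  structure(out, label = new_lab,
            class = c("treaty_corpus", class(tibble::tibble())))
}

#' Signature year of each record
#' @param corpus A `treaty_corpus`.
#' @return Integer vector of calendar years.
#' @export
signature_year <- function(corpus) {
  as.integer(format(corpus$date_signed, "%Y"))
}

#' Write a result table to disk
#'
#' Writes an influence table or a pairwise-similarity table in a
#' deterministic, sorted order so identical inputs give byte-identical
#' output. Influence tables are sorted by descending INF with ties broken
#' lexically by country name; similarity scores are printed at 6 decimal
#' places.
#'
#' @param x An `influence_table` or `similarity_pairs` object.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "json")) {
  UseMethod("write_report")
}

#' @export
write_report.influence_table <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  ord <- order(-x$inf, x$country)
  sorted <- x[ord, , drop = FALSE]
  if (format == "csv") {
    out <- tibble::tibble(
      country = sorted$country,
      inf = sorted$inf,
      threshold = attr(x, "threshold"),
      M = attr(x, "M"),
      D = attr(x, "D"),
      label = attr(x, "label") %||% ""
    )
    readr::write_csv(out, path)
  } else {
    jsonlite::write_json(as.list(stats::setNames(sorted$inf, sorted$country)),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @export
write_report.similarity_pairs <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  out <- tibble::tibble(id_a = x$id_a, id_b = x$id_b,
                        score = sprintf("%.6f", x$score))
  if (format == "csv") {
    readr::write_csv(out, path)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
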