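#' Read and write tweet-style records as JSON lines
#'
#' Records are one JSON object per line with fields `tweet_id`, `user_id`,
#' `text`, `tweet_lang`, `user_lang`, `lat`, `lon` and optionally
#' `side_label` (a flattened subset of a Twitter v1.1 payload).
#'
#' @param path File path.
#' @param records A data frame of records.
#' @return `read_jsonl()` returns a tibble with one row per parseable line;
#'   malformed lines are skipped with a warning. `write_jsonl()` returns
#'   `path` invisibly.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parsed <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
  })
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad)) {
    warn(sprintf("skipped %d malformed JSON line(s) in %s", sum(bad), path))
  }
  if (all(bad)) return(tibble())
  bind_rows(lapply(parsed[!bad], function(x) as_tibble(x[lengths(x) == 1])))
}

#' @rdname read_jsonl
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(as.list(records[i, , drop = FALSE]),
                     auto_unbox = TRUE, na = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a token-score lexicon from TSV
#'
#' Expects two tab-separated columns, `token` and `score`, with an optional
#' header line. Scores outside `bounds` raise an error, so that word-scale
#' (1-9) and emoji-scale (-1..1) lexica cannot be mixed up silently.
#'
#' @param path File path.
#' @param bounds Length-2 numeric; allowed score range.
#' @return A tibble with columns `token` (character) and `score` (numeric).
#' @export
read_lexicon <- function(path, bounds = c(-Inf, Inf)) {
  x <- readr::read_tsv(path, col_names = c("token", "score"),
                       col_types = "cd", progress = FALSE,
                       skip = if (lexicon_has_header(path)) 1L else 0L)
  if (any(x$score < bounds[1] | x$score > bounds[2], na.rm = TRUE)) {
    abort(sprintf("lexicon %s has scores outside [%g, %g]",
                  path, bounds[1], bounds[2]))
  }
  x
}

lexicon_has_header <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  parts <- strsplit(first, "\t", fixed = TRUE)[[1]]
  length(parts) >= 2 && is.na(suppressWarnings(as.numeric(parts[2])))
}

#' Write an n-gram count table or score table to TSV
#'
#' @param x A tibble (e.g. from [build_counts()] or [score_corpus_pair()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Bundled emoticon lexicon
#'
#' One keyboard-character emoticon per line (e.g. `:)`, `;-(`, `:D`). Used by
#' [tokenize_text()] so that punctuation sequences matching an emoticon
#' survive the punctuation-stripping rule.
#'
#' @param path Optional path to an alternative lexicon file.
#' @return Character vector of emoticon strings.
#' @export
load_emoticons <- function(path = natlex_resource("emoticons.txt")) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- x[nzchar(x)]
  unique(x)
}

#' Bundled English stopword list
#'
#' A standard function-word stoplist used by [apply_lexical_filters()].
#'
#' @param path Optional path to an alternative list (one token per line).
#' @return Character vector of stopwords.
#' @export
load_stopwords <- function(path = natlex_resource("stopwords_en.txt")) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  unique(tolower(x[nzchar(x)]))
}

#' Spelling-variant map
#'
#' Tab-separated `variant<TAB>canonical` pairs; variants are normalised
#' toward the canonical (US) form before count filtering, so that e.g.
#' "centre" and "center" contribute to a single entry.
#'
#' @param path Optional path to an alternative map.
#' @return Named character vector: `names()` are variants, values canonical.
#' @export
load_spelling_map <- function(path = natlex_resource("spelling_variants.tsv")) {
  x <- readr::read_tsv(path, col_names = c("variant", "canonical"),
                       col_types = "cc", progress = FALSE)
  setNames(tolower(x$canonical), tolower(x$variant))
}

#' Gazetteer and common-word samples
#'
#' `load_gazetteer()` returns place names (one per line, possibly multiword);
#' `load_common_words()` returns the exception list of ordinary words: a
#' place name composed entirely of common words (e.g. "river bend") is kept
#' in the vocabulary, any other gazetteer match is removed.
#'
#' @param path Optional path to an alternative file.
#' @return Character vector, lower-cased.
#' @export
load_gazetteer <- function(path = natlex_resource("gazetteer_sample.txt")) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  unique(tolower(x[nzchar(x)]))
}

#' @rdname load_gazetteer
#' @export
load_common_words <- function(path = natlex_resource("common_words_sample.txt")) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  unique(tolower(x[nzchar(x)]))
}

#' Reference survey tables
#'
#' `ncs_speaker_profiles()` returns the published facet-level rating summary
#' for hypothetical speakers of each nation's diagnostic vocabulary (per
#' facet: n, mean, sd for the Canadian-words and American-words conditions).
#' `ncs_difference_scores()` returns the published US-minus-Canada facet
#' difference columns from the original survey and its replication.
#' `reference_difference_vectors()` returns standardized US-minus-Canada
#' facet differences from self-report NEO-PI-R data and from the
#' language-based survey, consumed as external reference profiles.
#'
#' @return A tibble keyed by NCS facet code (N1..C6).
#' @export
ncs_speaker_profiles <- function() {
  readr::read_tsv(natlex_resource("ncs_speaker_profiles.tsv"),
                  col_types = "cciddidd", progress = FALSE)
}

#' @rdname ncs_speaker_profiles
#' @export
ncs_difference_scores <- function() {
  readr::read_tsv(natlex_resource("ncs_difference_scores.tsv"),
                  col_types = "cdd", progress = FALSE)
}

#' @rdname ncs_speaker_profiles
#' @export
reference_difference_vectors <- function() {
  readr::read_tsv(natlex_resource("reference_difference_vectors.tsv"),
                  col_types = "cdd", progress = FALSE)
}
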