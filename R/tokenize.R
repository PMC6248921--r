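## Tokenization of tweet-style text into word / emoji / emoticon unigrams.
##
## Unigram definition: any single emoji (including modifier, variation-
## selector, zero-width-joiner and flag sequences), any punctuation sequence
## matching the emoticon lexicon, or any run of two or more letters, digits,
## hyphens or underscores (case-folded). Hashtags, @-mentions and URLs are
## stripped before extraction; leftover single characters and unmatched
## punctuation are dropped.

emoji_base_class <- paste0(
  "[\\x{2300}-\\x{23FF}",   # misc technical (watch, hourglass)
  "\\x{2600}-\\x{27BF}",    # misc symbols + dingbats
  "\\x{2B00}-\\x{2BFF}",    # arrows/stars (e.g. white medium star)
  "\\x{1F000}-\\x{1FAFF}]"  # main emoji planes
)
emoji_modifier_class <- "[\\x{FE0F}\\x{1F3FB}-\\x{1F3FF}]"
regional_indicator_class <- "[\\x{1F1E6}-\\x{1F1FF}]"

emoji_sequence_regex <- function() {
  paste0(
    "(?:", regional_indicator_class, regional_indicator_class, "|",
    emoji_base_class, emoji_modifier_class, "*",
    "(?:\\x{200D}", emoji_base_class, emoji_modifier_class, "*)*", ")"
  )
}

word_regex <- "[\\p{L}\\p{N}_-]{2,}"

escape_regex <- function(x) {
  gsub("([\\\\^$.|?*+()\\[\\]{}])", "\\\\\\1", x, perl = TRUE)
}

token_extraction_regex <- function(emoticons) {
  emo <- emoticons[order(-nchar(emoticons), emoticons)]  # longest match first
  paste0("(?:", paste(escape_regex(emo), collapse = "|"), ")|",
         emoji_sequence_regex(), "|", word_regex)
}

strip_entities <- function(texts) {
  texts <- stringi::stri_replace_all_regex(
    texts, "(?:https?://|www\\.)\\S+", " ")
  stringi::stri_replace_all_regex(texts, "[@#]\\w+", " ")
}

#' Classify tokens as word, emoji or emoticon
#'
#' @param tokens Character vector of token surfaces.
#' @param emoticons Emoticon lexicon (see [load_emoticons()]).
#' @return Character vector: `"word"`, `"emoji"` or `"emoticon"`.
#' @export
token_category <- function(tokens, emoticons = load_emoticons()) {
  out <- rep("word", length(tokens))
  out[tokens %in% emoticons] <- "emoticon"
  is_emoji <- stringi::stri_detect_regex(
    tokens, paste0("^(?:", emoji_sequence_regex(), ")+$"))
  out[out == "word" & is_emoji] <- "emoji"
  out
}

#' Tokenize tweet text into words, emojis and emoticons
#'
#' `tokenize_text()` converts one string into a token table;
#' `tokenize_corpus()` is the vectorized version used for whole corpora and
#' returns one character vector of token surfaces per input text.
#'
#' Hashtags (`#...`), usernames (`@...`) and URLs are removed first. Emojis
#' (single pictograph sequences) and punctuation sequences that exactly match
#' the emoticon lexicon are kept as tokens; remaining word tokens are maximal
#' runs of letters, digits, hyphens and underscores of length >= 2, folded to
#' lower case. Everything else (single characters, stray punctuation) is
#' dropped. Emoticon matching is longest-match and happens before punctuation
#' is discarded, so `":)"` survives.
#'
#' @param text A single string.
#' @param texts Character vector of strings.
#' @param emoticons Emoticon lexicon (one pattern per entry).
#' @return `tokenize_text()`: a tibble with columns `surface` and `category`.
#'   `tokenize_corpus()`: a list of character vectors of token surfaces.
#' @examples
#' tokenize_text("@user check http://x.co #leafs :)")
#' @export
tokenize_text <- function(text, emoticons = load_emoticons()) {
  stopifnot(length(text) == 1)
  toks <- tokenize_corpus(text, emoticons)[[1]]
  tibble(surface = toks, category = token_category(toks, emoticons))
}

#' @rdname tokenize_text
#' @export
tokenize_corpus <- function(texts, emoticons = load_emoticons()) {
  rx <- token_extraction_regex(emoticons)
  cleaned <- strip_entities(texts)
  raw <- stringi::stri_extract_all_regex(cleaned, rx, omit_no_match = TRUE)
  emoset <- unique(emoticons)
  lapply(raw, function(tk) {
    if (length(tk) == 0) return(character(0))
    keep_case <- tk %in% emoset
    tk[!keep_case] <- stringi::stri_trans_tolower(tk[!keep_case])
    tk
  })
}

#' Build a per-side unigram and bigram count table
#'
#' Counts unigrams and contiguous bigrams (space-joined) over a list of
#' tokenized texts. Bigrams never span text boundaries.
#'
#' @param token_lists List of character vectors from [tokenize_corpus()].
#' @param side Label for the corpus side (e.g. `"canada"`, `"us"`).
#' @return An object of class `ngram_counts`: a list with elements `side`,
#'   `counts` (tibble `ngram`, `n`) and `total_tokens` (sum of unigram
#'   counts).
#' @export
build_counts <- function(token_lists, side = "i") {
  token_lists <- token_lists[lengths(token_lists) > 0]
  all_tok <- unlist(token_lists, use.names = FALSE)
  lens <- lengths(token_lists)
  ends <- cumsum(lens)
  n_tok <- length(all_tok)
  bigrams <- character(0)
  if (n_tok >= 2) {
    first_pos <- setdiff(seq_len(n_tok - 1L), ends)
    if (length(first_pos) > 0) {
      bigrams <- paste(all_tok[first_pos], all_tok[first_pos + 1L])
    }
  }
  tab <- table(c(all_tok, bigrams))
  counts <- tibble(ngram = names(tab), n = as.integer(tab))
  counts <- counts[order(-counts$n, counts$ngram), ]
  structure(list(side = side, counts = counts, total_tokens = n_tok),
            class = "ngram_counts")
}

#' @export
print.ngram_counts <- function(x, ...) {
  cat(sprintf("<ngram_counts> side '%s': %d distinct n-grams, %d tokens\n",
              x$side, nrow(x$counts), x$total_tokens))
  print(head(x$counts, 10))
  invisible(x)
}

ngram_parts <- function(ngrams) {
  stringi::stri_split_fixed(ngrams, " ")
}

apply_spelling <- function(counts, spelling_map) {
  if (length(spelling_map) == 0) return(counts)
  parts <- ngram_parts(counts$ngram)
  mapped <- vapply(parts, function(p) {
    hit <- p %in% names(spelling_map)
    p[hit] <- unname(spelling_map[p[hit]])
    paste(p, collapse = " ")
  }, character(1))
  counts$ngram <- mapped
  counts |>
    group_by(.data$ngram) |>
    summarise(n = sum(.data$n), .groups = "drop")
}

#' Lexical filtering of n-gram count tables
#'
#' Applies, in order: spelling-variant merging (variants mapped to their
#' canonical form and counts summed), stopword removal (stopword unigrams
#' and any bigram containing a stopword), gazetteer removal (an n-gram that
#' exactly matches a place name is dropped unless every constituent word is
#' on the common-word exception list), and a minimum pooled-count threshold
#' (items whose frequency summed over all supplied tables is below
#' `min_count` are dropped; the default removes items seen twice or less).
#'
#' The count threshold is pooled across the supplied tables, so pass both
#' corpus sides together when filtering a two-corpus comparison.
#'
#' @param tables A single `ngram_counts` object or a list of them.
#' @param stoplist Character vector of stopwords.
#' @param spelling_map Named character vector, variant -> canonical.
#' @param gazetteer Character vector of place names (lower case).
#' @param common_words Character vector of ordinary words exempting a place
#'   name from removal.
#' @param min_count Minimum pooled frequency to retain an n-gram.
#' @return Filtered table(s), same shape as the input.
#' @export
apply_lexical_filters <- function(tables,
                                  stoplist = load_stopwords(),
                                  spelling_map = load_spelling_map(),
                                  gazetteer = load_gazetteer(),
                                  common_words = load_common_words(),
                                  min_count = 3) {
  single <- inherits(tables, "ngram_counts")
  if (single) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, logical(1), "ngram_counts")))

  tables <- lapply(tables, function(tb) {
    cnt <- apply_spelling(tb$counts, spelling_map)
    parts <- ngram_parts(cnt$ngram)
    has_stop <- vapply(parts, function(p) any(p %in% stoplist), logical(1))
    cnt <- cnt[!has_stop, ]
    parts <- parts[!has_stop]
    in_gaz <- cnt$ngram %in% gazetteer
    all_common <- vapply(parts, function(p) all(p %in% common_words),
                         logical(1))
    cnt <- cnt[!(in_gaz & !all_common), ]
    tb$counts <- cnt
    tb
  })

  pooled <- bind_rows(lapply(tables, function(tb) tb$counts)) |>
    group_by(.data$ngram) |>
    summarise(n = sum(.data$n), .groups = "drop")
  keep <- pooled$ngram[pooled$n >= min_count]

  tables <- lapply(tables, function(tb) {
    tb$counts <- tb$counts[tb$counts$ngram %in% keep, ]
    tb$counts <- tb$counts[order(-tb$counts$n, tb$counts$ngram), ]
    uni <- !stringi::stri_detect_fixed(tb$counts$ngram, " ")
    tb$total_tokens <- sum(tb$counts$n[uni])
    tb
  })
  if (single) tables[[1]] else tables
}
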