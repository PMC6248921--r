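test_that("mentions, URLs and hashtags are stripped; emoticons survive", {
  tk <- tokenize_text("@user check http://x.co #leafs :)")
  expect_identical(tk$surface, c("check", ":)"))
  expect_identical(tk$category, c("word", "emoticon"))
})

test_that("a realistic tweet yields its content words and no punctuation", {
  tk <- tokenize_text(paste("This girl sent me a text bout happy father's",
                            "day. I'm like.… who dis?"))
  expect_true(all(c("girl", "text", "bout", "happy", "day") %in% tk$surface))
  expect_false(any(grepl("^[[:punct:]]+$", tk$surface)))
})

test_that("words, emojis and emoticons are categorized and case-folded", {
  tk <- tokenize_text("Love \U0001F341 :(")
  expect_identical(tk$surface, c("love", "\U0001F341", ":("))
  expect_identical(tk$category, c("word", "emoji", "emoticon"))
  # multi-codepoint emoji: flag (regional indicators) kept as one token
  flag <- "\U0001F1E8\U0001F1E6"
  tk2 <- tokenize_text(paste("proud", flag))
  expect_identical(tk2$surface, c("proud", flag))
  expect_identical(tk2$category[2], "emoji")
})

test_that("single characters and stray punctuation are dropped", {
  tk <- tokenize_text("a b! cd -- ,, e_f 9 42")
  expect_setequal(tk$surface, c("cd", "--", "e_f", "42"))
})

test_that("tokenization is deterministic and order-independent", {
  texts <- c("one two three :)", "three two one", "\U0001F602 lol")
  t1 <- tokenize_corpus(texts)
  t2 <- tokenize_corpus(rev(texts))
  expect_identical(t1, rev(t2))
  expect_identical(t1, tokenize_corpus(texts))
})

test_that("unigram and bigram counts respect text boundaries", {
  ct <- build_counts(list(c("a1", "b1", "c1")))
  expect_setequal(ct$counts$ngram, c("a1", "b1", "c1", "a1 b1", "b1 c1"))
  expect_true(all(ct$counts$n == 1))
  expect_identical(ct$total_tokens, 3L)
  # bigrams never span tweets
  ct2 <- build_counts(list("a1", "b1"))
  expect_false(any(grepl(" ", ct2$counts$ngram)))
  # repeated tweets accumulate
  ct3 <- build_counts(rep(list(c("hi", "there")), 10))
  expect_identical(ct3$counts$n[ct3$counts$ngram == "hi there"], 10L)
})

test_that("bigram counts never exceed their parts' unigram counts", {
  withr::with_seed(11, {
    toks <- replicate(50, sample(letters[1:5], rpois(1, 6) + 2,
                                 replace = TRUE), simplify = FALSE)
    toks <- lapply(toks, function(x) paste0(x, x))  # >= 2 chars
  })
  ct <- build_counts(toks)
  uni <- ct$counts[!grepl(" ", ct$counts$ngram), ]
  bi <- ct$counts[grepl(" ", ct$counts$ngram), ]
  for (k in seq_len(nrow(bi))) {
    parts <- strsplit(bi$ngram[k], " ")[[1]]
    expect_lte(bi$n[k], min(uni$n[match(parts, uni$ngram)]))
  }
  expect_identical(ct$total_tokens, sum(uni$n))
})

test_that("spelling variants are merged before the count threshold", {
  tb <- structure(list(side = "i",
                       counts = tibble::tibble(
                         ngram = c("centre", "center", "colour"),
                         n = c(5L, 7L, 2L)),
                       total_tokens = 14L),
                  class = "ngram_counts")
  out <- apply_lexical_filters(tb, stoplist = character(0),
                               gazetteer = character(0),
                               common_words = character(0), min_count = 3)
  expect_identical(out$counts$n[out$counts$ngram == "center"], 12L)
  expect_false("centre" %in% out$counts$ngram)
  # "colour" count 2 maps to "color" count 2: below the threshold, dropped
  expect_false(any(c("colour", "color") %in% out$counts$ngram))
})

test_that("gazetteer names are removed unless made of common words", {
  tb <- structure(list(side = "i",
                       counts = tibble::tibble(
                         ngram = c("greater london", "river bend", "toronto",
                                   "hockey"),
                         n = c(5L, 5L, 5L, 5L)),
                       total_tokens = 20L),
                  class = "ngram_counts")
  out <- apply_lexical_filters(
    tb, stoplist = character(0), spelling_map = character(0),
    gazetteer = c("greater london", "river bend", "toronto"),
    common_words = c("river", "bend"), min_count = 3)
  expect_setequal(out$counts$ngram, c("river bend", "hockey"))
})

test_that("stopword unigrams and bigrams containing them are removed", {
  tb <- structure(list(side = "i",
                       counts = tibble::tibble(
                         ngram = c("the", "feel like", "feel the", "feel"),
                         n = c(100L, 10L, 10L, 20L)),
                       total_tokens = 130L),
                  class = "ngram_counts")
  out <- apply_lexical_filters(tb, stoplist = "the",
                               spelling_map = character(0),
                               gazetteer = character(0),
                               common_words = character(0), min_count = 3)
  expect_setequal(out$counts$ngram, c("feel like", "feel"))
})

test_that("lexical filtering pools the count threshold across sides and is idempotent", {
  mk <- function(side, ngrams, ns) {
    structure(list(side = side,
                   counts = tibble::tibble(ngram = ngrams, n = ns),
                   total_tokens = sum(ns)),
              class = "ngram_counts")
  }
  # "shared" has 2 on each side: pooled 4 passes min_count 3
  ti <- mk("i", c("shared", "only-i"), c(2L, 2L))
  tj <- mk("j", c("shared"), 2L)
  out <- apply_lexical_filters(list(ti, tj), stoplist = character(0),
                               spelling_map = character(0),
                               gazetteer = character(0),
                               common_words = character(0), min_count = 3)
  expect_identical(out[[1]]$counts$ngram, "shared")
  expect_identical(out[[2]]$counts$ngram, "shared")
  again <- apply_lexical_filters(out, stoplist = character(0),
                                 spelling_map = character(0),
                                 gazetteer = character(0),
                                 common_words = character(0), min_count = 3)
  expect_identical(lapply(again, `[[`, "counts"),
                   lapply(out, `[[`, "counts"))
})

test_that("no output n-gram contains a mention, hashtag or URL fragment", {
  texts <- c("go @you win http://a.b/c #tag now", "see www.x.com #more fun",
             "@a @b #c http://d.e")
  ct <- build_counts(tokenize_corpus(texts))
  expect_false(any(grepl("[@#]|http|www\\.", ct$counts$ngram)))
})
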