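## Synthetic two-corpus and survey-table generators with planted ground
## truth. These stand in for undeposited social-media corpora and raw rating
## data: every downstream stage (filtering, tokenization, log-odds scoring,
## binning, survey statistics) can be validated against known effects.

# Small emoji pool mixed into synthetic vocabularies (all within the ranges
# the tokenizer recognises).
synthetic_emoji_pool <- function() {
  c("\U0001F600", "\U0001F602", "\U0001F60D", "\U0001F62D", "\U0001F644",
    "\U0001F64F", "\U0001F525", "\U0001F389", "\U0001F49C", "\U0001F499",
    "\U0001F341", "\U0001F3D2", "\U0001F37A", "\U0001F440", "\U0001F4AF",
    "\U0001F614", "\U0001F629", "\U0001F97A", "\U0001F973", "\U0001F9E1",
    "❤", "❄", "⛄", "⭐", "⚽", "☕",
    "\U0001F926", "\U0001F937", "\U0001F483", "\U0001F680")
}

#' Specification of a synthetic two-corpus tweet generator
#'
#' Defines a shared Zipf-distributed vocabulary of word, emoji and emoticon
#' tokens and a set of planted per-token log-odds shifts between side A and
#' side B. Token probabilities on side A are obtained from the side-B (base)
#' probabilities by shifting the log-odds of each planted token by exactly
#' its planted amount and rescaling the remaining probability mass over the
#' unplanted tokens (whose log-odds therefore move by a negligible common
#' amount; see the methods vignette).
#'
#' @param vocab_size Number of distinct tokens.
#' @param zipf_exponent Zipf exponent of the base frequency distribution.
#' @param n_users_per_side Users per corpus side.
#' @param tweets_per_user_mean,tweets_per_user_dispersion Mean and negative-
#'   binomial dispersion (`size`) of the per-user tweet count (minimum 1).
#' @param planted_biases Named numeric vector: token -> log-odds shift
#'   (natural log) of side A relative to side B. Tokens not present in the
#'   auto-built vocabulary replace words at evenly spaced mid-frequency
#'   ranks; with an explicit `vocab` they must be a subset of it.
#' @param emoji_fraction,emoticon_fraction Fractions of the vocabulary drawn
#'   from the emoji pool and the emoticon lexicon.
#' @param bot_specs List of [bot_spec()] objects; bot users are appended to
#'   the two sides alternately.
#' @param vocab Optional explicit vocabulary (overrides auto-construction).
#' @param tweet_length_mean Mean token count per tweet (truncated Poisson,
#'   capped at `tweet_length_max` to respect the 140-character format).
#' @param tweet_length_max Maximum tokens per tweet.
#' @param seed Integer seed; identical seeds give identical corpora.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(vocab_size = 5000, zipf_exponent = 1.08,
                        n_users_per_side = 500,
                        tweets_per_user_mean = 30,
                        tweets_per_user_dispersion = 10,
                        planted_biases = numeric(0),
                        emoji_fraction = 0.05, emoticon_fraction = 0.02,
                        bot_specs = list(), vocab = NULL,
                        tweet_length_mean = 11, tweet_length_max = 23,
                        seed = 1L) {
  stopifnot(vocab_size >= 10, zipf_exponent > 0, n_users_per_side >= 1,
            tweets_per_user_mean > 0, tweets_per_user_dispersion > 0,
            emoji_fraction >= 0, emoji_fraction <= 1,
            emoticon_fraction >= 0, emoticon_fraction <= 1,
            emoji_fraction + emoticon_fraction < 1,
            tweet_length_mean > 0, tweet_length_max >= 2)
  if (length(planted_biases) > 0 &&
      (is.null(names(planted_biases)) || any(!nzchar(names(planted_biases))))) {
    abort("planted_biases must be a named numeric vector (token -> shift)")
  }
  if (!is.null(vocab)) {
    if (length(vocab) != length(unique(vocab))) {
      abort("explicit vocab contains duplicates")
    }
    if (!all(names(planted_biases) %in% vocab)) {
      abort("configuration error: planted tokens are not all in the vocabulary")
    }
    vocab_size <- length(vocab)
  }
  if (length(planted_biases) > vocab_size / 2) {
    abort("configuration error: vocabulary too small for the planted set")
  }
  structure(list(vocab_size = vocab_size, zipf_exponent = zipf_exponent,
                 n_users_per_side = n_users_per_side,
                 tweets_per_user_mean = tweets_per_user_mean,
                 tweets_per_user_dispersion = tweets_per_user_dispersion,
                 planted_biases = planted_biases,
                 emoji_fraction = emoji_fraction,
                 emoticon_fraction = emoticon_fraction,
                 bot_specs = bot_specs, vocab = vocab,
                 tweet_length_mean = tweet_length_mean,
                 tweet_length_max = tweet_length_max,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Specification of a templated bot account
#'
#' @param template_text Tweet template; each `{}` is a slot filled with a
#'   random short word, giving the small variation typical of automated
#'   accounts while keeping long common substrings between tweets.
#' @param urls_per_tweet Mean URLs appended per tweet (integer part is
#'   deterministic, the fractional part a Bernoulli draw).
#' @param n_tweets Number of tweets the account sends (>= 2).
#' @return An object of class `bot_spec`.
#' @export
bot_spec <- function(template_text, urls_per_tweet = 0, n_tweets = 50) {
  stopifnot(is.character(template_text), length(template_text) == 1,
            urls_per_tweet >= 0, n_tweets >= 2)
  structure(list(template_text = template_text,
                 urls_per_tweet = urls_per_tweet,
                 n_tweets = as.integer(n_tweets)),
            class = "bot_spec")
}

build_vocab <- function(spec) {
  if (!is.null(spec$vocab)) return(spec$vocab)
  v <- spec$vocab_size
  n_emoji <- round(spec$emoji_fraction * v)
  n_emoticon <- round(spec$emoticon_fraction * v)
  emojis <- head(synthetic_emoji_pool(), n_emoji)
  n_emoji <- length(emojis)  # pool may be smaller than requested
  emoticons <- head(load_emoticons(), n_emoticon)
  vocab <- character(v)
  # spread emoji/emoticon tokens over ranks so they span the frequency range
  special <- c(emojis, emoticons)
  if (length(special) > 0) {
    special_ranks <- unique(round(seq(3, v, length.out = length(special))))
    special <- head(special, length(special_ranks))
    vocab[special_ranks] <- special
  }
  n_empty <- sum(vocab == "")
  vocab[vocab == ""] <- sprintf("w%05d", seq_len(n_empty))
  planted <- names(spec$planted_biases)
  missing <- setdiff(planted, vocab)
  if (length(missing) > 0) {
    # give planted tokens evenly spaced mid-frequency ranks
    cand <- setdiff(seq(11, max(12, floor(v / 2))), which(vocab %in% special))
    if (length(cand) < length(missing)) {
      abort("configuration error: vocabulary too small for the planted set")
    }
    slots <- cand[unique(round(seq(1, length(cand),
                                   length.out = length(missing))))]
    vocab[slots] <- missing
  }
  vocab
}

corpus_side_probs <- function(spec, vocab) {
  v <- length(vocab)
  q <- seq_len(v)^(-spec$zipf_exponent)
  q <- q / sum(q)
  names(q) <- vocab
  p <- q
  planted <- names(spec$planted_biases)
  if (length(planted) > 0) {
    b <- spec$planted_biases
    odds <- q[planted] / (1 - q[planted]) * exp(b)
    p[planted] <- odds / (1 + odds)
    if (sum(p[planted]) >= 1) {
      abort("configuration error: planted shifts leave no probability mass for unplanted tokens")
    }
    rest <- setdiff(vocab, planted)
    p[rest] <- q[rest] * (1 - sum(p[planted])) / sum(q[rest])
  }
  list(a = p, b = q)
}

draw_side_records <- function(spec, vocab, prob, side, region) {
  n_users <- spec$n_users_per_side
  tweets_per_user <- pmax(1L, rnbinom(n_users,
                                      size = spec$tweets_per_user_dispersion,
                                      mu = spec$tweets_per_user_mean))
  n_tweets <- sum(tweets_per_user)
  lens <- pmin(spec$tweet_length_max,
               pmax(1L, rpois(n_tweets, spec$tweet_length_mean)))
  toks <- vocab[sample.int(length(vocab), sum(lens), replace = TRUE,
                           prob = prob)]
  tweet_of <- rep.int(seq_len(n_tweets), lens)
  texts <- vapply(split(toks, tweet_of), paste, character(1), collapse = " ")
  tibble(
    tweet_id = paste0(side, "_t", seq_len(n_tweets)),
    user_id = rep.int(sprintf("%s_u%04d", side, seq_len(n_users)),
                      tweets_per_user),
    text = unname(texts),
    tweet_lang = "en",
    user_lang = "en",
    lat = runif(n_tweets, region$lat_min, region$lat_max),
    lon = runif(n_tweets, region$lon_min, region$lon_max),
    side_label = side)
}

# Default side regions: two latitude bands sharing a longitude range, so
# side membership and geotag stay consistent.
side_regions <- function() {
  list(A = region_spec("side_A", 49, 60, -125, -55),
       B = region_spec("side_B", 30, 49, -125, -55))
}

#' Generate a pair of tweet corpora with planted log-odds biases
#'
#' Draws tokens per side from the probability vectors implied by the spec
#' (see [corpus_spec()]), packs them into tweets and users, fills language
#' tags and side-consistent geotags, and appends bot accounts per
#' `spec$bot_specs` (alternating sides, distinct user ids).
#'
#' @param spec A [corpus_spec()].
#' @return A list with elements `records_a`, `records_b` (tibbles of
#'   tweet-style records), `truth` (named numeric: the planted log-odds),
#'   `probs` (the side A / side B token probabilities) and `vocab`.
#' @export
generate_corpus_pair <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  vocab <- build_vocab(spec)
  pr <- corpus_side_probs(spec, vocab)
  regions <- side_regions()
  withr::with_seed(spec$seed, {
    rec_a <- draw_side_records(spec, vocab, pr$a, "A", regions$A)
    rec_b <- draw_side_records(spec, vocab, pr$b, "B", regions$B)
    if (length(spec$bot_specs) > 0) {
      for (k in seq_along(spec$bot_specs)) {
        side <- if (k %% 2 == 1) "A" else "B"
        reg <- regions[[side]]
        bot <- generate_bot_user(spec$bot_specs[[k]],
                                 seed = spec$seed + k,
                                 user_id = sprintf("%s_bot%02d", side, k))
        bot$lat <- runif(nrow(bot), reg$lat_min, reg$lat_max)
        bot$lon <- runif(nrow(bot), reg$lon_min, reg$lon_max)
        bot$side_label <- side
        bot$tweet_id <- sprintf("%s_bot%02d_t%d", side, k, seq_len(nrow(bot)))
        if (side == "A") rec_a <- bind_rows(rec_a, bot)
        else rec_b <- bind_rows(rec_b, bot)
      }
    }
  })
  list(records_a = rec_a, records_b = rec_b,
       truth = spec$planted_biases, probs = pr, vocab = vocab)
}

bot_slot_words <- c("sale", "deal", "shop", "win", "hot", "top", "buy",
                    "free", "now", "best", "look", "item")

#' Generate the tweets of one templated bot account
#'
#' Every tweet instantiates `template_text` (with `{}` slots filled by random
#' short words) and appends URLs at the specified mean rate, reproducing the
#' long shared substrings and link-heavy output typical of automated
#' accounts.
#'
#' @param spec A [bot_spec()].
#' @param seed Integer seed.
#' @param user_id User id for the account.
#' @return A tibble of tweet-style records (lat/lon left `NA`; the corpus
#'   generator fills them).
#' @export
generate_bot_user <- function(spec, seed = 1L, user_id = "bot1") {
  stopifnot(inherits(spec, "bot_spec"))
  withr::with_seed(as.integer(seed), {
    n <- spec$n_tweets
    n_slots <- stringi::stri_count_fixed(spec$template_text, "{}")
    texts <- vapply(seq_len(n), function(i) {
      txt <- spec$template_text
      if (n_slots > 0) {
        fill <- sample(bot_slot_words, n_slots, replace = TRUE)
        for (w in fill) {
          txt <- stringi::stri_replace_first_fixed(txt, "{}", w)
        }
      }
      txt
    }, character(1))
    n_urls <- floor(spec$urls_per_tweet) +
      rbinom(n, 1, spec$urls_per_tweet - floor(spec$urls_per_tweet))
    urls <- vapply(n_urls, function(k) {
      if (k == 0) return("")
      paste0(" ", paste(sprintf("http://t.co/%s",
                                stringi::stri_rand_strings(k, 8, "[a-z0-9]")),
                        collapse = " "))
    }, character(1))
    tibble(tweet_id = paste0(user_id, "_t", seq_len(n)),
           user_id = user_id,
           text = paste0(texts, urls),
           tweet_lang = "en", user_lang = "en",
           lat = NA_real_, lon = NA_real_,
           side_label = NA_character_)
  })
}

#' Generate a positivity lexicon with a planted mean shift
#'
#' Assigns each token a score drawn from a normal distribution centred at
#' `base_mean` (or `base_mean + planted_shift` for tokens in
#' `shifted_tokens`), clipped to the scale bounds.
#'
#' @param vocab Character vector of tokens.
#' @param planted_shift Score-unit shift applied to `shifted_tokens`.
#' @param shifted_tokens Tokens receiving the shift (subset of `vocab`).
#' @param base_mean,base_sd Baseline score distribution.
#' @param bounds Scale bounds (default the 1-9 word-positivity scale; use
#'   `c(-1, 1)` for an emoji-style scale).
#' @param seed Integer seed.
#' @return A tibble with columns `token` and `score`.
#' @export
generate_positivity_lexicon <- function(vocab, planted_shift = 0,
                                        shifted_tokens = character(0),
                                        base_mean = 5, base_sd = 1,
                                        bounds = c(1, 9), seed = 1L) {
  if (length(vocab) == 0) abort("empty vocabulary")
  stopifnot(all(shifted_tokens %in% vocab))
  mu <- base_mean + planted_shift * (vocab %in% shifted_tokens)
  if (any(mu < bounds[1]) || any(mu > bounds[2])) {
    abort("base_mean + planted_shift falls outside the scale bounds")
  }
  withr::with_seed(as.integer(seed), {
    score <- pmin(bounds[2], pmax(bounds[1], rnorm(length(vocab), mu,
                                                   base_sd)))
  })
  tibble(token = vocab, score = score)
}

#' Specification of a synthetic facet-rating survey
#'
#' Target per-facet rating means and SDs on the 1-5 scale for each condition,
#' plus contamination rates. Defaults reproduce the published facet summary
#' for speakers of each nation's diagnostic vocabulary
#' ([ncs_speaker_profiles()]): condition `"american_words"` takes the
#' US-words column, `"canadian_words"` the Canada-words column, with 200
#' raters per condition and the observed fast-responder (~3%) and
#' missing-cell (~1.5%) rates.
#'
#' @param facet_targets Tibble with columns `condition`, `facet`, `mean`,
#'   `sd` (means in `[1, 5]`, SDs positive).
#' @param n_raters Raters per condition.
#' @param missing_rate Probability that a single facet selection is missing.
#' @param fast_responder_rate Fraction of raters answering in under a
#'   minute.
#' @param seed Integer seed.
#' @return An object of class `survey_spec`.
#' @export
survey_spec <- function(facet_targets = NULL, n_raters = 200,
                        missing_rate = 0.015, fast_responder_rate = 0.03,
                        seed = 1L) {
  if (is.null(facet_targets)) {
    prof <- ncs_speaker_profiles()
    facet_targets <- bind_rows(
      tibble(condition = "american_words", facet = prof$facet,
             mean = prof$mean_us, sd = prof$sd_us),
      tibble(condition = "canadian_words", facet = prof$facet,
             mean = prof$mean_can, sd = prof$sd_can))
  }
  stopifnot(all(c("condition", "facet", "mean", "sd") %in%
                  names(facet_targets)),
            all(facet_targets$mean >= 1), all(facet_targets$mean <= 5),
            all(facet_targets$sd > 0),
            n_raters >= 2,
            missing_rate >= 0, missing_rate <= 1,
            fast_responder_rate >= 0, fast_responder_rate <= 1)
  structure(list(facet_targets = as_tibble(facet_targets),
                 n_raters = as.integer(n_raters),
                 missing_rate = missing_rate,
                 fast_responder_rate = fast_responder_rate,
                 seed = as.integer(seed)),
            class = "survey_spec")
}

# Mean of round(Normal(mu, sd)) clipped to {1..5}.
discretized_mean <- function(mu, sd) {
  cuts <- c(-Inf, 1.5, 2.5, 3.5, 4.5, Inf)
  p <- diff(pnorm(cuts, mean = mu, sd = sd))
  sum(p * (1:5))
}

# Latent mean such that the discretized 1..5 rating has the target mean.
calibrate_latent_mean <- function(target, sd) {
  uniroot(function(mu) discretized_mean(mu, sd) - target,
          lower = -6, upper = 12, tol = 1e-9)$root
}

#' Generate a synthetic facet-rating table
#'
#' Ratings are discretized truncated normals on the 1-5 radio-button scale.
#' The latent mean of each facet is calibrated (by root finding) so that the
#' *discretized* rating has the target mean; SDs are taken as the latent
#' scale and therefore only approximate after discretization. Fast
#' responders get durations under 60 seconds; missing selections are `NA`
#' values.
#'
#' @param spec A [survey_spec()].
#' @return A tibble with columns `rater_id`, `condition`, `facet`, `value`
#'   (integer 1-5 or `NA`), `duration_seconds`, and a logical
#'   `fast_responder` flag column for ground-truth checks.
#' @export
generate_survey_table <- function(spec) {
  stopifnot(inherits(spec, "survey_spec"))
  tg <- spec$facet_targets
  tg$latent_mean <- mapply(calibrate_latent_mean, tg$mean, tg$sd)
  withr::with_seed(spec$seed, {
    out <- lapply(unique(tg$condition), function(cond) {
      tgt <- tg[tg$condition == cond, ]
      n <- spec$n_raters
      rater_id <- sprintf("%s_r%04d", cond, seq_len(n))
      fast <- runif(n) < spec$fast_responder_rate
      duration <- ifelse(fast, round(runif(n, 5, 59)),
                         round(runif(n, 90, 900)))
      grid <- tidyr::expand_grid(r = seq_len(n), f = seq_len(nrow(tgt)))
      value <- pmin(5L, pmax(1L, as.integer(round(
        rnorm(nrow(grid), tgt$latent_mean[grid$f], tgt$sd[grid$f])))))
      value[runif(nrow(grid)) < spec$missing_rate] <- NA_integer_
      tibble(rater_id = rater_id[grid$r], condition = cond,
             facet = tgt$facet[grid$f], value = value,
             duration_seconds = duration[grid$r],
             fast_responder = fast[grid$r])
    })
  })
  bind_rows(out)
}
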