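#' Rectangular region specification
#'
#' A named half-open bounding box in decimal degrees: a point is inside when
#' `lat_min <= lat < lat_max` and `lon_min <= lon < lon_max`.
#'
#' @param name Region name.
#' @param lat_min,lat_max,lon_min,lon_max Box extents (degrees).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, lat_min, lat_max, lon_min, lon_max) {
  stopifnot(lat_min < lat_max, lon_min < lon_max,
            lat_min >= -90, lat_max <= 90,
            lon_min >= -180, lon_max <= 180)
  structure(list(name = name, lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max),
            class = "region_spec")
}

point_in_region <- function(lat, lon, region) {
  !is.na(lat) & !is.na(lon) &
    lat >= region$lat_min & lat < region$lat_max &
    lon >= region$lon_min & lon < region$lon_max
}

#' Apply corpus inclusion rules to tweet-style records
#'
#' A record is retained iff its tweet language tag and the author's default
#' language both equal `language`, its geotag lies inside `region`, and its
#' author has strictly more than `min_user_tweets - 1` records in the input
#' (the default keeps users with more than 10 tweets). Malformed records
#' (missing text or out-of-range coordinates) are skipped with a warning,
#' never an error. Each exclusion is attributed to the first failing
#' criterion, in the order: malformed, tweet language, user language,
#' geotag, user tweet count.
#'
#' @param records Tibble with columns `tweet_id`, `user_id`, `text`,
#'   `tweet_lang`, `user_lang`, `lat`, `lon` (see [read_jsonl()]).
#' @param region A [region_spec()].
#' @param language Language code, e.g. `"en"`.
#' @param min_user_tweets Minimum number of input records per retained user.
#' @return The retained records, with a `filter_report` attribute (tibble of
#'   per-criterion exclusion counts) retrievable via [filter_report()].
#' @export
filter_records <- function(records, region, language = "en",
                           min_user_tweets = 11) {
  records <- as_tibble(records)
  n0 <- nrow(records)
  if (n0 == 0) {
    return(structure(records,
                     filter_report = tibble(criterion = character(0),
                                            excluded = integer(0))))
  }
  malformed <- is.na(records$text) | !nzchar(records$text) |
    (!is.na(records$lat) & abs(records$lat) > 90) |
    (!is.na(records$lon) & abs(records$lon) > 180)
  if (any(malformed)) {
    warn(sprintf("skipping %d malformed record(s)", sum(malformed)))
  }
  bad_tweet_lang <- !malformed & records$tweet_lang != language
  bad_user_lang <- !malformed & !bad_tweet_lang &
    records$user_lang != language
  inside <- point_in_region(records$lat, records$lon, region)
  bad_geo <- !malformed & !bad_tweet_lang & !bad_user_lang & !inside
  passing_user <- !(malformed | bad_tweet_lang | bad_user_lang | bad_geo)
  user_n <- table(records$user_id)
  too_few <- passing_user &
    as.integer(user_n[records$user_id]) < min_user_tweets
  keep <- passing_user & !too_few

  report <- tibble(
    criterion = c("malformed", "tweet_lang", "user_lang", "geotag",
                  "min_user_tweets", "retained"),
    excluded = c(sum(malformed), sum(bad_tweet_lang), sum(bad_user_lang),
                 sum(bad_geo), sum(too_few), NA_integer_))
  report$excluded[report$criterion == "retained"] <- sum(keep)
  out <- records[keep, ]
  structure(out, filter_report = report)
}

#' @rdname filter_records
#' @param filtered Output of `filter_records()`.
#' @export
filter_report <- function(filtered) {
  attr(filtered, "filter_report")
}

#' Mean pairwise text dissimilarity via longest common substring
#'
#' For every unordered pair of texts (after sampling down to `max_sample`
#' texts with a fixed seed), computes `1 - |LCS(a, b)| / max(|a|, |b|)`,
#' where LCS is the longest common *contiguous* substring in Unicode
#' characters, and returns the mean. Identical texts give 0; texts sharing
#' no character give 1. Automated accounts that emit templated messages
#' score well below diverse human text.
#'
#' @param texts Character vector (>= 2 elements for a defined value).
#' @param max_sample Maximum number of texts entering the all-pairs
#'   computation.
#' @param seed Seed for the subsample draw (local to this call).
#' @return Mean dissimilarity in `[0, 1]`, or `NA` with a warning when fewer
#'   than two texts are supplied (insufficient data).
#' @export
pairwise_dissimilarity <- function(texts, max_sample = 500, seed = 1L) {
  if (length(texts) < 2) {
    warn("fewer than 2 texts: pairwise dissimilarity undefined")
    return(NA_real_)
  }
  if (length(texts) > max_sample) {
    texts <- withr::with_seed(seed, sample(texts, max_sample))
  }
  cp <- lapply(texts, utf8ToInt)
  mean_pairwise_dissimilarity_cpp(cp)
}

#' Longest common contiguous substring length
#'
#' @param a,b Strings.
#' @return Integer length in Unicode characters.
#' @export
lcs_length <- function(a, b) {
  lcs_length_cpp(utf8ToInt(a), utf8ToInt(b))
}

#' Mean URLs per text
#'
#' URLs are counted with a scheme-or-www-prefixed token pattern
#' (`http://...`, `https://...`, `www....`).
#'
#' @inheritParams pairwise_dissimilarity
#' @return Mean URL count per text over the (sampled) texts.
#' @export
url_rate <- function(texts, max_sample = 500, seed = 1L) {
  stopifnot(length(texts) >= 1)
  if (length(texts) > max_sample) {
    texts <- withr::with_seed(seed, sample(texts, max_sample))
  }
  mean(stringi::stri_count_regex(texts, "(?:https?://|www\\.)\\S+"))
}

#' Flag bot-like users from their tweet texts
#'
#' A user is flagged as a bot when their mean pairwise tweet dissimilarity is
#' below `dissim_threshold` (templated output) or their mean URL rate is at
#' least `url_threshold` (link spam); the thresholds default to the values
#' 0.8 and 1 used for the national corpora. Users with fewer than two texts
#' bypass the dissimilarity criterion (it is undefined) but remain subject to
#' the URL criterion. When both criteria fire, the dissimilarity reason is
#' reported.
#'
#' @param texts_by_user Named list: one character vector of texts per user,
#'   or a records tibble with `user_id` and `text` columns.
#' @param dissim_threshold Flag when mean dissimilarity `<` this value.
#' @param url_threshold Flag when mean URL rate `>=` this value (inclusive).
#' @param max_sample,seed Passed to the two metrics.
#' @return Tibble with one row per user: `user_id`, `n_tweets`,
#'   `mean_dissimilarity`, `mean_urls`, `flagged_bot`, `flag_reason`
#'   (`"dissimilarity"`, `"url_rate"` or `"none"`).
#' @export
flag_bots <- function(texts_by_user, dissim_threshold = 0.8,
                      url_threshold = 1, max_sample = 500, seed = 1L) {
  if (is.data.frame(texts_by_user)) {
    texts_by_user <- split(texts_by_user$text, texts_by_user$user_id)
  }
  stopifnot(length(texts_by_user) > 0, !is.null(names(texts_by_user)))
  rows <- lapply(names(texts_by_user), function(uid) {
    txt <- texts_by_user[[uid]]
    dis <- if (length(txt) >= 2) {
      pairwise_dissimilarity(txt, max_sample = max_sample, seed = seed)
    } else NA_real_
    urls <- url_rate(txt, max_sample = max_sample, seed = seed)
    by_dissim <- !is.na(dis) && dis < dissim_threshold
    by_url <- urls >= url_threshold
    tibble(user_id = uid, n_tweets = length(txt),
           mean_dissimilarity = dis, mean_urls = urls,
           flagged_bot = by_dissim || by_url,
           flag_reason = if (by_dissim) "dissimilarity"
                         else if (by_url) "url_rate" else "none")
  })
  bind_rows(rows)
}
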