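# Shared fixtures built in code.

toy_count_tables <- function() {
  list(
    i = tibble::tibble(ngram = c("aa", "bb", "cc", "dd"),
                       n = c(40L, 10L, 25L, 25L)),
    j = tibble::tibble(ngram = c("aa", "bb", "cc", "ee"),
                       n = c(10L, 40L, 25L, 25L))
  )
}

# Independent direct evaluation of the three log-odds formulas, written as a
# per-item loop straight from their definitions (no package helpers), used
# as the oracle for score_corpus_pair().
oracle_loridp <- function(counts_i, counts_j) {
  vocab <- sort(union(names(counts_i), names(counts_j)))
  yi <- as.numeric(counts_i[vocab])
  yj <- as.numeric(counts_j[vocab])
  yi[is.na(yi)] <- 0; yj[is.na(yj)] <- 0
  ni <- sum(yi); nj <- sum(yj)
  a0 <- ni + nj
  out <- data.frame(ngram = vocab, delta = NA_real_, variance = NA_real_,
                    z = NA_real_)
  for (k in seq_along(vocab)) {
    aw <- yi[k] + yj[k]
    d <- log((yi[k] + aw) / (ni + a0 - yi[k] - aw)) -
      log((yj[k] + aw) / (nj + a0 - yj[k] - aw))
    v <- 1 / (yi[k] + aw) + 1 / (yj[k] + aw)
    out$delta[k] <- d
    out$variance[k] <- v
    out$z[k] <- d / sqrt(v)
  }
  out
}

# Brute-force longest common contiguous substring: enumerate all substrings
# of the shorter string, test containment in the other.
oracle_lcs <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  na <- nchar(a)
  for (len in rev(seq_len(na))) {
    for (start in seq_len(na - len + 1)) {
      if (grepl(substr(a, start, start + len - 1), b, fixed = TRUE)) {
        return(len)
      }
    }
  }
  0L
}

random_records <- function(n, user_ids, region, lang = "en", seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    tweet_id = paste0("t", seq_len(n)),
    user_id = sample(user_ids, n, replace = TRUE),
    text = replicate(n, paste(sample(letters, 30, replace = TRUE),
                              collapse = "")),
    tweet_lang = lang,
    user_lang = lang,
    lat = runif(n, region$lat_min, region$lat_max),
    lon = runif(n, region$lon_min, region$lon_max)))
}
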