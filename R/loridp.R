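#' Weighted log-odds difference with an informative Dirichlet prior
#'
#' The core two-corpus comparison statistic. For an n-gram `w` with count
#' `y_i` out of `n_i` total n-gram tokens in corpus i (and `y_j`, `n_j` in
#' corpus j), with prior pseudo-counts `alpha_w` (the pooled count of `w`)
#' and `alpha_0` (the pooled total), the smoothed log-odds difference is
#'
#' \deqn{\delta_w = \log\frac{y_i + \alpha_w}{n_i + \alpha_0 - y_i - \alpha_w}
#'               - \log\frac{y_j + \alpha_w}{n_j + \alpha_0 - y_j - \alpha_w}}
#'
#' with estimated variance \eqn{\sigma^2 = 1/(y_i + \alpha_w) +
#' 1/(y_j + \alpha_w)} and standardized score \eqn{z = \delta/\sigma}
#' (optionally \eqn{\delta/\sigma^2}, see `sqrt_variance`). Positive values
#' indicate over-representation in corpus i. Shrinkage toward the pooled
#' corpus keeps very rare and very frequent items from dominating.
#'
#' @param y_i,y_j Counts of the n-gram in corpora i and j.
#' @param n_i,n_j Total n-gram token counts in corpora i and j.
#' @param alpha_w Prior pseudo-count for the n-gram (pooled count).
#' @param alpha_0 Prior total (pooled corpus size).
#' @param delta,variance Values from `loridp_delta()` / `loridp_variance()`.
#' @param sqrt_variance If `TRUE` (default) standardize by the standard
#'   deviation, giving a z-score; `FALSE` divides by the raw variance.
#' @return Numeric vector (vectorized over the count arguments).
#' @seealso [score_corpus_pair()] for the full pipeline over two count
#'   tables, [bonferroni_threshold()] for the selection cutoff.
#' @export
loridp_delta <- function(y_i, y_j, n_i, n_j, alpha_w, alpha_0) {
  stopifnot(all(y_i >= 0), all(y_j >= 0), all(alpha_w > 0),
            all(alpha_0 > alpha_w))
  den_i <- n_i + alpha_0 - y_i - alpha_w
  den_j <- n_j + alpha_0 - y_j - alpha_w
  if (any(den_i <= 0) || any(den_j <= 0)) {
    abort("non-positive smoothed denominator in log-odds computation")
  }
  log((y_i + alpha_w) / den_i) - log((y_j + alpha_w) / den_j)
}

#' @rdname loridp_delta
#' @export
loridp_variance <- function(y_i, y_j, alpha_w) {
  stopifnot(all(y_i >= 0), all(y_j >= 0), all(alpha_w > 0))
  1 / (y_i + alpha_w) + 1 / (y_j + alpha_w)
}

#' @rdname loridp_delta
#' @export
loridp_z <- function(delta, variance, sqrt_variance = TRUE) {
  stopifnot(all(variance > 0))
  if (sqrt_variance) delta / sqrt(variance) else delta / variance
}

#' Two-tailed Bonferroni-corrected normal cutoff
#'
#' The absolute z-score above which an item is selected when `m` simultaneous
#' comparisons are corrected to a family-wise level `alpha`. With
#' `m = 2761118` and `alpha = 0.01` the cutoff is 5.9 (one decimal).
#'
#' @param m Number of comparisons (n-grams scored).
#' @param alpha Family-wise two-tailed significance level.
#' @return The positive z cutoff.
#' @export
bonferroni_threshold <- function(m, alpha = 0.01) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  qnorm(1 - (alpha / m) / 2)
}

#' Score every n-gram of two count tables and select diagnostic items
#'
#' Builds the Dirichlet prior from the pooled tables (`alpha_w` = pooled
#' count of each n-gram times `prior_scale`, `alpha_0` = their sum), scores
#' every n-gram present in either table, and marks items whose |z| reaches
#' the Bonferroni cutoff for `m` = number of scored n-grams. Positive z means
#' over-represented in `table_i`.
#'
#' @param table_i,table_j N-gram count tables from [build_counts()] (or any
#'   data frame with columns `ngram` and `n`).
#' @param alpha Family-wise significance level for selection.
#' @param prior_scale Multiplier on the pooled-count prior; 1 uses the raw
#'   pooled frequencies as pseudo-counts.
#' @param sqrt_variance Passed to [loridp_z()].
#' @param orientation `"i_positive"` (default) reports z > 0 as corpus-i
#'   over-representation; `"i_negative"` flips every sign, matching report
#'   styles where the first corpus carries negative scores.
#' @return A tibble of class `loridp_scores` with columns `ngram`, `y_i`,
#'   `y_j`, `delta`, `variance`, `z`, `selected_side` (`"side_i"`,
#'   `"side_j"` or `"none"`), ordered by descending |z|, with attributes
#'   `m`, `cutoff`, `alpha`, `n_i`, `n_j`.
#' @export
score_corpus_pair <- function(table_i, table_j, alpha = 0.01,
                              prior_scale = 1, sqrt_variance = TRUE,
                              orientation = c("i_positive", "i_negative")) {
  orientation <- match.arg(orientation)
  ti <- as_count_table(table_i)
  tj <- as_count_table(table_j)
  u <- dplyr::full_join(ti, tj, by = "ngram", suffix = c("_i", "_j"))
  u$n_i[is.na(u$n_i)] <- 0L
  u$n_j[is.na(u$n_j)] <- 0L
  if (nrow(u) == 0) abort("empty vocabulary: nothing to score")
  n_i <- sum(u$n_i)
  n_j <- sum(u$n_j)
  alpha_w <- prior_scale * (u$n_i + u$n_j)
  alpha_0 <- prior_scale * (n_i + n_j)
  delta <- loridp_delta(u$n_i, u$n_j, n_i, n_j, alpha_w, alpha_0)
  variance <- loridp_variance(u$n_i, u$n_j, alpha_w)
  z <- loridp_z(delta, variance, sqrt_variance = sqrt_variance)
  if (orientation == "i_negative") {
    delta <- -delta
    z <- -z
  }
  m <- nrow(u)
  cutoff <- bonferroni_threshold(m, alpha)
  pos_side <- if (orientation == "i_positive") "side_i" else "side_j"
  neg_side <- if (orientation == "i_positive") "side_j" else "side_i"
  selected_side <- ifelse(z >= cutoff, pos_side,
                          ifelse(z <= -cutoff, neg_side, "none"))
  out <- tibble(ngram = u$ngram, y_i = u$n_i, y_j = u$n_j,
                delta = delta, variance = variance, z = z,
                selected_side = selected_side)
  out <- out[order(-abs(out$z), -(out$y_i + out$y_j), out$ngram), ]
  structure(out, m = m, cutoff = cutoff, alpha = alpha,
            n_i = n_i, n_j = n_j,
            class = c("loridp_scores", class(out)))
}

as_count_table <- function(x) {
  if (inherits(x, "ngram_counts")) x <- x$counts
  x <- as_tibble(x)
  if (!all(c("ngram", "n") %in% names(x))) {
    abort("count table must have columns `ngram` and `n`")
  }
  x[, c("ngram", "n")]
}

#' @export
print.loridp_scores <- function(x, ...) {
  cat(sprintf(
    "<loridp_scores> %d n-grams scored (n_i = %d, n_j = %d)\n",
    attr(x, "m"), attr(x, "n_i"), attr(x, "n_j")))
  cat(sprintf("  Bonferroni cutoff |z| >= %.3f at alpha = %g: %d side_i, %d side_j selected\n",
              attr(x, "cutoff"), attr(x, "alpha"),
              sum(x$selected_side == "side_i"),
              sum(x$selected_side == "side_j")))
  print(as_tibble(head(as.data.frame(x), 10)))
  invisible(x)
}

#' Extract a ranked top-k stimulus list for one side
#'
#' Selects the `k` n-grams with the largest |z| on the requested side,
#' after removing an exclusion list together with simple inflectional
#' variants (the excluded stem plus a common suffix), as done when turning
#' diagnostic vocabularies into survey stimuli. Ties in |z| are broken by
#' descending pooled frequency, then lexicographically, so lists are
#' deterministic.
#'
#' @param scores A `loridp_scores` table.
#' @param side `"side_i"` or `"side_j"`.
#' @param k List length.
#' @param exclusions Character vector of stems to remove (a bigram is
#'   removed when any constituent matches).
#' @param exclude_variants If `TRUE`, also remove tokens formed by adding a
#'   common inflectional suffix (s, es, ed, ing, er, ers, in, in') to an
#'   excluded stem.
#' @param selected_only If `TRUE` (default) only Bonferroni-selected items
#'   are eligible.
#' @return A tibble of class `stimulus_list` with columns `rank`, `ngram`,
#'   `z`; attributes `side`, `k`, `exclusions`. Warns when fewer than `k`
#'   items survive.
#' @export
top_k_stimuli <- function(scores, side = c("side_i", "side_j"), k = 120,
                          exclusions = character(), exclude_variants = TRUE,
                          selected_only = TRUE) {
  side <- match.arg(side)
  x <- as_tibble(scores)
  x <- if (selected_only) x[x$selected_side == side, ]
       else if (side == "side_i") x[x$z > 0, ] else x[x$z < 0, ]
  pooled <- x$y_i + x$y_j
  x <- x[order(-abs(x$z), -pooled, x$ngram), ]
  if (length(exclusions) > 0) {
    keep <- !vapply(x$ngram, matches_exclusion, logical(1),
                    stems = tolower(exclusions),
                    variants = exclude_variants)
    x <- x[keep, ]
  }
  if (nrow(x) < k) {
    warn(sprintf("only %d items available for %s (requested k = %d)",
                 nrow(x), side, k))
  }
  x <- head(x, k)
  structure(tibble(rank = seq_len(nrow(x)), ngram = x$ngram, z = x$z),
            side = side, k = k, exclusions = exclusions,
            class = c("stimulus_list", class(tibble())))
}

inflection_suffixes <- c("", "s", "es", "ed", "ing", "er", "ers", "in", "in'")

matches_exclusion <- function(ngram, stems, variants) {
  parts <- strsplit(ngram, " ", fixed = TRUE)[[1]]
  sufs <- if (variants) inflection_suffixes else ""
  forms <- unique(as.vector(outer(stems, sufs, paste0)))
  any(parts %in% forms)
}
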