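## Decile binning of each side's diagnostic items and positivity comparison
## between matched bins: the top 1-10% most side-A items against the top
## 1-10% most side-B items, and so on, with Welch tests, Bonferroni
## adjustment and Cohen's d per bin pair.

#' Rank-bin one side's diagnostic items
#'
#' Items are ranked by descending |z| within the side and split into
#' `n_bins` contiguous rank bins: bin 1 holds the most diagnostic decile.
#' Bin sizes differ by at most one; when the item count is not a multiple of
#' `n_bins`, the leftover items go to the earliest bins (so 101 items give
#' one bin of 11 followed by nine bins of 10).
#'
#' @param scores A `loridp_scores` table (or any data frame with `ngram` and
#'   `z` columns), already restricted to one side's items — e.g.
#'   `dplyr::filter(scores, selected_side == "side_i")`, optionally further
#'   restricted to one token category.
#' @param n_bins Number of bins.
#' @return The input rows with added columns `rank` and `bin`, ordered by
#'   rank.
#' @export
rank_bins <- function(scores, n_bins = 10) {
  x <- as_tibble(scores)
  if (nrow(x) < n_bins) {
    abort(sprintf("only %d items: cannot form %d bins", nrow(x), n_bins))
  }
  x <- x[order(-abs(x$z), x$ngram), ]
  n <- nrow(x)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + (seq_len(n_bins) <= extra)
  x$rank <- seq_len(n)
  x$bin <- rep.int(seq_len(n_bins), sizes)
  x
}

#' Merge word-positivity lexica
#'
#' Combines two or more token-score lexica; a token present in several gets
#' the arithmetic mean of its scores.
#'
#' @param ... Tibbles with columns `token` and `score`.
#' @return A single merged lexicon tibble.
#' @export
merge_lexica <- function(...) {
  bind_rows(...) |>
    group_by(.data$token) |>
    summarise(score = mean(.data$score), .groups = "drop")
}

#' Attach lexicon scores to rank bins
#'
#' Joins a positivity lexicon onto binned items; items without a lexicon
#' score are dropped from comparisons, and per-bin coverage is reported.
#' Word-scale (1-9) and emoji-scale (-1..1) lexica must be joined onto
#' separately binned item sets, never mixed.
#'
#' @param bins Output of [rank_bins()].
#' @param lexicon Tibble with columns `token` and `score` (see
#'   [read_lexicon()] or [merge_lexica()]).
#' @return The scored rows (columns of `bins` plus `score`), with a
#'   `coverage` attribute: per-bin tibble of item counts before and after
#'   the join.
#' @export
join_lexicon <- function(bins, lexicon) {
  stopifnot(all(c("token", "score") %in% names(lexicon)))
  scored <- left_join(bins, lexicon[, c("token", "score")],
                      by = c(ngram = "token"))
  coverage <- scored |>
    group_by(.data$bin) |>
    summarise(n_items = dplyr::n(), n_scored = sum(!is.na(.data$score)),
              coverage = .data$n_scored / .data$n_items, .groups = "drop")
  if (all(coverage$n_scored == 0)) {
    warn("lexicon covers no binned item; comparisons will be skipped")
  }
  out <- scored[!is.na(scored$score), ]
  structure(out, coverage = coverage)
}

cohens_d_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

mean_ci <- function(x, conf = 0.95) {
  n <- length(x)
  m <- mean(x)
  half <- qt(1 - (1 - conf) / 2, df = n - 1) * sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Compare positivity between matched rank bins of two sides
#'
#' For each bin index present in both sides, runs a Welch two-sample t-test
#' on the lexicon scores, Bonferroni-adjusts the p-value by `n_tests`
#' (capped at 1), and reports Cohen's d with pooled SD (sign convention:
#' side A minus side B) together with per-side means and t-based 95%
#' confidence intervals. Bins with fewer than two scored items on either
#' side are skipped with `NA` statistics.
#'
#' @param scored_a,scored_b Outputs of [join_lexicon()] for the two sides.
#' @param n_tests Bonferroni multiplier (default 10, one per bin).
#' @param conf Confidence level for the per-side mean CIs.
#' @return A tibble with one row per bin: item counts, means, CIs, Welch `t`,
#'   `df`, raw `p`, `p_adj`, and `cohens_d`.
#' @export
compare_bins <- function(scored_a, scored_b, n_tests = 10, conf = 0.95) {
  bins <- sort(union(unique(scored_a$bin), unique(scored_b$bin)))
  rows <- lapply(bins, function(b) {
    xa <- scored_a$score[scored_a$bin == b]
    xb <- scored_b$score[scored_b$bin == b]
    base <- tibble(bin = b, n_a = length(xa), n_b = length(xb))
    if (length(xa) < 2 || length(xb) < 2) {
      warn(sprintf("bin %d skipped: fewer than 2 scored items on a side", b))
      return(mutate(base, mean_a = NA_real_, ci_lo_a = NA_real_,
                    ci_hi_a = NA_real_, mean_b = NA_real_,
                    ci_lo_b = NA_real_, ci_hi_b = NA_real_, t = NA_real_,
                    df = NA_real_, p = NA_real_, p_adj = NA_real_,
                    cohens_d = NA_real_))
    }
    ca <- mean_ci(xa, conf); cb <- mean_ci(xb, conf)
    tt <- if (sd(xa) == 0 && sd(xb) == 0) {
      list(statistic = c(t = if (mean(xa) == mean(xb)) 0 else Inf),
           parameter = c(df = NA_real_),
           p.value = if (mean(xa) == mean(xb)) 1 else 0)
    } else {
      stats::t.test(xa, xb, var.equal = FALSE)
    }
    mutate(base, mean_a = ca[["mean"]], ci_lo_a = ca[["lo"]],
           ci_hi_a = ca[["hi"]], mean_b = cb[["mean"]],
           ci_lo_b = cb[["lo"]], ci_hi_b = cb[["hi"]],
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, p_adj = pmin(1, tt$p.value * n_tests),
           cohens_d = cohens_d_pooled(xa, xb))
  })
  bind_rows(rows)
}
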