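## Facet-rating survey statistics: response cleaning, 30-facet profiles,
## Welch facet tests with Bonferroni adjustment, ICC(1,k), within-subject
## adjusted standard errors, US-minus-Canada style difference vectors, and
## correlations between difference profiles from different instruments.

#' Canonical NCS facet order
#'
#' The 30 facet codes in the fixed order used by every profile and
#' difference vector: N1-N6, E1-E6, O1-O6, A1-A6, C1-C6.
#'
#' @return Character vector of length 30.
#' @export
ncs_facets <- function() ncs_facet_codes()

#' Clean raw facet ratings
#'
#' Removes raters whose response duration is under `min_duration_seconds`
#' (unrealistically fast responders), keeps only the first submission when a
#' rater appears more than once per condition and facet, and drops missing
#' facet selections cell-wise. Exclusion counts are attached as a
#' `cleaning_report` attribute.
#'
#' @param ratings Tibble with columns `rater_id`, `condition`, `facet`,
#'   `value`, `duration_seconds` (e.g. from [generate_survey_table()]).
#' @param min_duration_seconds Minimum duration; raters strictly below are
#'   dropped entirely.
#' @return The cleaned ratings tibble.
#' @export
clean_responses <- function(ratings, min_duration_seconds = 60) {
  ratings <- as_tibble(ratings)
  fast_ids <- unique(ratings$rater_id[
    ratings$duration_seconds < min_duration_seconds])
  x <- ratings[!(ratings$rater_id %in% fast_ids), ]
  n_dupes <- nrow(x)
  x <- distinct(x, .data$condition, .data$rater_id, .data$facet,
                .keep_all = TRUE)
  n_dupes <- n_dupes - nrow(x)
  n_missing <- sum(is.na(x$value))
  x <- x[!is.na(x$value), ]
  structure(x,
            cleaning_report = tibble(
              n_fast_raters = length(fast_ids),
              n_duplicate_cells = n_dupes,
              n_missing_cells = n_missing,
              n_retained_cells = nrow(x)))
}

#' @rdname clean_responses
#' @param cleaned Output of `clean_responses()`.
#' @export
cleaning_report <- function(cleaned) attr(cleaned, "cleaning_report")

#' Per-facet profile of one condition
#'
#' @param ratings Cleaned ratings.
#' @param condition Condition label to profile.
#' @return A tibble with one row per facet present: `facet`, `n`, `mean`,
#'   `sd`, ordered canonically. Facets with no ratings are reported with
#'   `n = 0` and `NA` statistics rather than silently omitted.
#' @export
facet_profile <- function(ratings, condition) {
  x <- ratings[ratings$condition == condition & !is.na(ratings$value), ]
  if (nrow(x) == 0) abort(sprintf("no ratings for condition '%s'", condition))
  prof <- x |>
    group_by(.data$facet) |>
    summarise(n = dplyr::n(), mean = mean(.data$value),
              sd = sd(.data$value), .groups = "drop")
  all_facets <- tibble(facet = ncs_facet_codes())
  prof <- left_join(all_facets, prof, by = "facet")
  prof$n[is.na(prof$n)] <- 0L
  prof$condition <- condition
  prof[, c("condition", "facet", "n", "mean", "sd")]
}

#' Welch tests per facet between two conditions
#'
#' One Welch two-sample t-test per facet, Bonferroni-adjusted for `n_tests`
#' comparisons (`p_adj = min(1, n_tests * p)`), with significance flags at
#' 0.05, 0.01 and 0.001.
#'
#' @param ratings Cleaned ratings containing both conditions.
#' @param condition_a,condition_b Condition labels; the test statistic is
#'   oriented a minus b.
#' @param n_tests Bonferroni multiplier (default 30, one per facet).
#' @return A tibble with one row per facet: means, `t`, `df`, `p`, `p_adj`
#'   and logical columns `sig_05`, `sig_01`, `sig_001`.
#' @export
facet_tests <- function(ratings, condition_a, condition_b, n_tests = 30) {
  facets <- intersect(ncs_facet_codes(), unique(ratings$facet))
  rows <- lapply(facets, function(f) {
    xa <- ratings$value[ratings$condition == condition_a &
                          ratings$facet == f & !is.na(ratings$value)]
    xb <- ratings$value[ratings$condition == condition_b &
                          ratings$facet == f & !is.na(ratings$value)]
    if (length(xa) < 2 || length(xb) < 2) {
      abort(sprintf("facet %s has fewer than 2 ratings in a condition", f))
    }
    if (sd(xa) == 0 && sd(xb) == 0) {
      t_stat <- if (mean(xa) == mean(xb)) 0 else Inf
      df <- NA_real_
      p <- if (mean(xa) == mean(xb)) 1 else 0
    } else {
      tt <- stats::t.test(xa, xb, var.equal = FALSE)
      t_stat <- unname(tt$statistic)
      df <- unname(tt$parameter)
      p <- tt$p.value
    }
    tibble(facet = f, n_a = length(xa), n_b = length(xb),
           mean_a = mean(xa), mean_b = mean(xb),
           t = t_stat, df = df, p = p, p_adj = min(1, p * n_tests))
  })
  out <- bind_rows(rows)
  out$sig_05 <- out$p_adj < 0.05
  out$sig_01 <- out$p_adj < 0.01
  out$sig_001 <- out$p_adj < 0.001
  out
}

#' Facet difference vector between two profiles
#'
#' Per-facet difference of means, condition A minus condition B (the
#' US-minus-Canada orientation when A is the American-words profile), in
#' canonical facet order.
#'
#' @param profile_a,profile_b Outputs of [facet_profile()] (or any data
#'   frame with `facet` and `mean`); all 30 facets must be present with
#'   non-missing means.
#' @return A tibble with columns `facet` and `difference` (30 rows).
#' @export
difference_vector <- function(profile_a, profile_b) {
  a <- align_facets(profile_a)
  b <- align_facets(profile_b)
  tibble(facet = ncs_facet_codes(), difference = a - b)
}

align_facets <- function(profile, col = "mean") {
  stopifnot("facet" %in% names(profile))
  if (!col %in% names(profile)) {
    num <- setdiff(names(profile)[vapply(profile, is.numeric, logical(1))],
                   c("n"))
    stopifnot(length(num) >= 1)
    col <- num[1]
  }
  v <- setNames(profile[[col]], profile$facet)
  missing <- setdiff(ncs_facet_codes(), names(v)[!is.na(v)])
  if (length(missing) > 0) {
    abort(paste0("missing facet(s): ", paste(missing, collapse = ", ")))
  }
  unname(v[ncs_facet_codes()])
}

#' Correlate two facet difference vectors
#'
#' Pearson correlation over the 30 matched facets, with
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2 = 28` degrees of freedom
#' and a two-sided p-value.
#'
#' @param v1,v2 Difference vectors: outputs of [difference_vector()], data
#'   frames with `facet` plus one numeric column, or bare numeric vectors of
#'   length 30 in canonical facet order.
#' @return A list with elements `r`, `t`, `df`, `p`.
#' @export
compare_difference_vectors <- function(v1, v2) {
  x <- as_difference_values(v1)
  y <- as_difference_values(v2)
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero-variance difference vector: correlation undefined")
    return(list(r = NA_real_, t = NA_real_, df = length(x) - 2,
                p = NA_real_))
  }
  r <- cor(x, y)
  df <- length(x) - 2
  t_stat <- r * sqrt(df) / sqrt(1 - r^2)
  list(r = r, t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

as_difference_values <- function(v) {
  if (is.numeric(v)) {
    stopifnot(length(v) == 30)
    return(unname(v))
  }
  align_facets(v, col = if ("difference" %in% names(v)) "difference"
                        else "mean")
}

#' Mean and SD of absolute facet differences
#'
#' @param v A difference vector (see [compare_difference_vectors()] for
#'   accepted forms).
#' @return A list with `mean_abs` and `sd_abs` (sample SD, n - 1).
#' @export
abs_difference_summary <- function(v) {
  x <- abs(as_difference_values(v))
  list(mean_abs = mean(x), sd_abs = sd(x))
}

#' One-way random-effects average-measures intraclass correlation, ICC(1,k)
#'
#' Treats the facets as the rated targets and the k raters as
#' interchangeable measurements: from the one-way ANOVA with facet as the
#' grouping factor, `ICC(1,k) = (MS_between - MS_within) / MS_between`. High
#' values mean raters agree on the average level of each facet.
#'
#' @param ratings_matrix Numeric matrix, raters in rows and facets in
#'   columns; rows with any missing value are dropped.
#' @return ICC(1,k) in `(-Inf, 1]`.
#' @export
icc_1k <- function(ratings_matrix) {
  m <- as.matrix(ratings_matrix)
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("ICC(1,k) needs at least 2 complete raters and 2 facets")
  }
  k <- nrow(m)        # raters (measurements per facet)
  f <- ncol(m)        # facets (targets)
  grand <- mean(m)
  col_means <- colMeans(m)
  ms_between <- k * sum((col_means - grand)^2) / (f - 1)
  ms_within <- sum(sweep(m, 2, col_means)^2) / (f * (k - 1))
  if (ms_between == 0) {
    warn("MS_between is 0: ICC(1,k) undefined")
    return(NA_real_)
  }
  (ms_between - ms_within) / ms_between
}

#' Ratings matrix for one condition
#'
#' Reshapes cleaned long-format ratings to a raters-by-facets matrix,
#' keeping only raters with a complete set of facets.
#'
#' @param ratings Cleaned ratings.
#' @param condition Condition label.
#' @return Numeric matrix (raters x 30 facets).
#' @export
ratings_matrix <- function(ratings, condition) {
  x <- ratings[ratings$condition == condition & !is.na(ratings$value), ]
  wide <- tidyr::pivot_wider(x[, c("rater_id", "facet", "value")],
                             names_from = "facet", values_from = "value")
  facets <- intersect(ncs_facet_codes(), names(wide))
  m <- as.matrix(wide[, facets])
  rownames(m) <- wide$rater_id
  m[complete.cases(m), , drop = FALSE]
}

#' Within-subject adjusted standard errors per facet
#'
#' For plotting within-participant comparisons: each rater's ratings are
#' centered at the rater's own mean and shifted back to the condition grand
#' mean, removing between-rater offset variance; the per-facet standard
#' error of the centered data is then inflated by `sqrt(k / (k - 1))` with
#' `k` the number of facets, correcting the variance deflation induced by
#' the centering. Only raters with a complete set of facets enter.
#'
#' @param ratings Cleaned ratings.
#' @param condition Condition label.
#' @return A tibble with one row per facet: `facet`, `n`, `mean`,
#'   `se_adjusted`.
#' @export
within_subject_se <- function(ratings, condition) {
  m <- ratings_matrix(ratings, condition)
  if (nrow(m) < 2) {
    warn(sprintf("condition '%s' has fewer than 2 complete raters", condition))
    return(tibble(facet = colnames(m), n = nrow(m),
                  mean = colMeans(m), se_adjusted = NA_real_))
  }
  k <- ncol(m)
  centered <- m - rowMeans(m) + mean(m)
  se <- apply(centered, 2, sd) / sqrt(nrow(m)) * sqrt(k / (k - 1))
  tibble(facet = colnames(m), n = nrow(m), mean = colMeans(m),
         se_adjusted = unname(se))
}
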