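make_ratings <- function(n_raters, cond, means, sds = rep(1, 30),
                         seed = 1, duration = 300) {
  facets <- ncs_facets()
  withr::with_seed(seed, {
    grid <- expand.grid(r = seq_len(n_raters), f = seq_along(facets))
    tibble::tibble(
      rater_id = sprintf("%s_r%03d", cond, grid$r),
      condition = cond,
      facet = facets[grid$f],
      value = pmin(5L, pmax(1L, as.integer(round(
        rnorm(nrow(grid), means[grid$f], sds[grid$f]))))),
      duration_seconds = duration)
  })
}

test_that("cleaning drops fast responders, duplicates and missing cells", {
  r <- make_ratings(5, "c", rep(3, 30), seed = 2)
  r$duration_seconds[r$rater_id == "c_r001"] <- 59
  r$value[r$rater_id == "c_r002" & r$facet == "N1"] <- NA
  dup <- r[r$rater_id == "c_r003", ][1, ]
  dup$value <- 5L
  r <- dplyr::bind_rows(r, dup)
  cl <- clean_responses(r)
  rep <- cleaning_report(cl)
  expect_identical(rep$n_fast_raters, 1L)        # the 59-second rater
  expect_identical(rep$n_missing_cells, 1L)      # 29 of 30 facets kept
  expect_identical(rep$n_duplicate_cells, 1L)    # first submission kept
  expect_false("c_r001" %in% cl$rater_id)
  expect_identical(sum(cl$rater_id == "c_r002"), 29L)
  first_kept <- cl$value[cl$rater_id == "c_r003" & cl$facet == dup$facet]
  expect_identical(first_kept,
                   r$value[r$rater_id == "c_r003" & r$facet == dup$facet][1])
})

test_that("the generator's fast-responder rate shows up in cleaning", {
  tab <- generate_survey_table(survey_spec(n_raters = 500,
                                           fast_responder_rate = 0.05,
                                           seed = 4))
  cl <- clean_responses(tab)
  removed <- 1 - length(unique(cl$rater_id)) / length(unique(tab$rater_id))
  expect_lt(abs(removed - 0.05), 0.02)
})

test_that("facet profiles report n, mean and sd per facet", {
  r <- make_ratings(4, "c", rep(3, 30), sds = rep(1e-9, 30), seed = 5)
  prof <- facet_profile(r, "c")
  expect_identical(nrow(prof), 30L)
  expect_true(all(prof$mean == 3))
  expect_true(all(prof$sd == 0))
  expect_true(all(prof$n <= 4))
})

test_that("facet Welch tests detect a planted gap and respect the null", {
  means_lo <- rep(2.5, 30)
  means_hi <- c(3.5, rep(2.5, 29))  # one-point gap on N1 only
  r <- dplyr::bind_rows(make_ratings(190, "a", means_hi, seed = 6),
                        make_ratings(190, "b", means_lo, seed = 7))
  ft <- facet_tests(r, "a", "b")
  expect_lt(ft$p_adj[ft$facet == "N1"], 0.001)
  expect_true(ft$sig_001[ft$facet == "N1"])
  # identical data: nothing significant
  same <- dplyr::bind_rows(
    make_ratings(50, "a", rep(3, 30), seed = 8),
    dplyr::mutate(make_ratings(50, "a", rep(3, 30), seed = 8),
                  condition = "b",
                  rater_id = sub("^a_", "b_", rater_id)))
  ft0 <- facet_tests(same, "a", "b")
  expect_true(all(ft0$p_adj == 1))
  expect_false(any(ft0$sig_05))
})

test_that("family-wise error under the null stays at the nominal level", {
  hits <- vapply(1:20, function(s) {
    r <- dplyr::bind_rows(make_ratings(40, "a", rep(3, 30), seed = 100 + s),
                          make_ratings(40, "b", rep(3, 30), seed = 200 + s))
    any(facet_tests(r, "a", "b")$sig_05)
  }, logical(1))
  expect_lte(mean(hits), 0.10)  # nominal 0.05 plus Monte-Carlo slack
})

test_that("difference vectors reproduce the published facet differences", {
  prof <- ncs_speaker_profiles()
  us <- tibble::tibble(facet = prof$facet, mean = prof$mean_us)
  can <- tibble::tibble(facet = prof$facet, mean = prof$mean_can)
  dv <- difference_vector(us, can)
  expect_identical(nrow(dv), 30L)
  expect_equal(dv$difference[dv$facet == "N1"], 3.10 - 1.87)
  ref <- ncs_difference_scores()
  ref <- ref[match(dv$facet, ref$facet), ]
  expect_true(all(abs(dv$difference - ref$study_2a) <= 0.01 + 1e-9))
  # identical profiles give the zero vector
  zero <- difference_vector(us, us)
  expect_true(all(zero$difference == 0))
  expect_error(difference_vector(us[-1, ], can), "missing facet")
})

test_that("difference-vector correlations behave like Pearson r", {
  v <- ncs_difference_scores()$study_2a
  expect_equal(compare_difference_vectors(v, 2 * v)$r, 1)
  expect_equal(compare_difference_vectors(v, -v)$r, -1)
  # symmetry and affine invariance
  w <- ncs_difference_scores()$study_2b
  expect_equal(compare_difference_vectors(v, w)$r,
               compare_difference_vectors(w, v)$r)
  expect_equal(compare_difference_vectors(3 * v - 1, w / 2 + 5)$r,
               compare_difference_vectors(v, w)$r)
  cst <- rep(1, 30)
  expect_warning(out <- compare_difference_vectors(v, cst), "zero-variance")
  expect_true(is.na(out$r))
})

test_that("absolute difference summaries use the sample SD", {
  z <- rep(0, 30)
  s <- abs_difference_summary(z)
  expect_equal(s$mean_abs, 0)
  expect_equal(s$sd_abs, 0)
  v <- ncs_difference_scores()$study_2a
  s2 <- abs_difference_summary(v)
  expect_equal(s2$mean_abs, mean(abs(v)))
  expect_equal(s2$sd_abs, sd(abs(v)))
})

test_that("ICC(1,k) is 1 for perfect agreement and near 0 for noise", {
  pattern <- seq(1, 5, length.out = 30)
  perfect <- matrix(pattern, nrow = 25, ncol = 30, byrow = TRUE)
  expect_equal(icc_1k(perfect), 1)
  iccs <- vapply(1:30, function(s) {
    withr::with_seed(300 + s,
                     icc_1k(matrix(rnorm(50 * 30), nrow = 50)))
  }, numeric(1))
  # noise-only ICC(1,k) centres near zero (slightly negative in finite
  # samples because 1/MS_between is convex)
  expect_gt(mean(iccs), -0.2)
  expect_lt(mean(iccs), 0.1)
})

test_that("ICC(1,k) grows with the number of raters (Spearman-Brown)", {
  facet_eff <- seq(-1, 1, length.out = 30)
  mk <- function(k, seed) {
    withr::with_seed(seed,
                     outer(rep(0, k), facet_eff, `+`) +
                       matrix(rnorm(k * 30, sd = 2), nrow = k))
  }
  icc_small <- mean(vapply(1:10, function(s) icc_1k(mk(10, s)), numeric(1)))
  icc_large <- mean(vapply(1:10, function(s) icc_1k(mk(80, s)), numeric(1)))
  expect_gt(icc_large, icc_small)
})

test_that("within-subject SEs are invariant to per-rater offsets", {
  base <- make_ratings(40, "c", rep(3, 30), seed = 20)
  shifted <- base
  withr::with_seed(21, {
    offs <- sample(-1:1, 40, replace = TRUE)
  })
  shifted$value <- shifted$value +
    offs[as.integer(factor(shifted$rater_id))]
  se0 <- within_subject_se(base, "c")
  se1 <- within_subject_se(shifted, "c")
  expect_equal(se1$se_adjusted, se0$se_adjusted)
})

test_that("without rater effects the adjusted SE matches the naive SE", {
  withr::with_seed(22, {
    m <- matrix(rnorm(200 * 30), nrow = 200)
  })
  r <- tibble::tibble(
    rater_id = rep(sprintf("r%03d", 1:200), each = 30),
    condition = "c",
    facet = rep(ncs_facets(), times = 200),
    value = as.vector(t(m)),
    duration_seconds = 300)
  adj <- within_subject_se(r, "c")$se_adjusted
  naive <- apply(m, 2, sd) / sqrt(200)
  expect_equal(mean(adj / naive), 1, tolerance = 0.02)
})
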