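ref_series <- function(ratings_by_temp, reps = 2) {
  # familiarization table where every repetition at a temperature has the
  # stated rating (vector input recycles per repetition)
  make_familiarization("P1", temps = as.numeric(names(ratings_by_temp)),
                       reps = reps,
                       rating_fun = function(g) {
                         unname(unlist(ratings_by_temp)[
                           match(g$stimulus_level,
                                 as.numeric(names(ratings_by_temp)))]) +
                           0 * g$repetition_index
                       })
}

test_that("binarization is strict against the reference mean", {
  d <- make_familiarization("P1", temps = c(43, 44), reps = 2,
                            rating_fun = function(g) {
                              ifelse(g$stimulus_level == 43, 3.0,
                                     c(2.5, 3.5)[g$repetition_index])
                            })
  b <- binarize_trials(d, 43, "ascending", "intensity")
  expect_equal(b$indicator, c(0L, 1L))
  expect_equal(unique(b$reference_rating), 3.0)

  # ties code 0 in both directions
  d_tie <- make_familiarization("P1", temps = c(43, 44, 49), reps = 2,
                                rating_fun = function(g) 3.0)
  expect_true(all(binarize_trials(d_tie, 43, "ascending")$indicator == 0))
  expect_true(all(binarize_trials(d_tie, 49, "descending")$indicator == 0))

  # descending: 1 iff strictly below the 49 degC reference mean
  d_desc <- make_familiarization("P1", temps = c(48, 49), reps = 2,
                                 rating_fun = function(g) {
                                   ifelse(g$stimulus_level == 49, 3,
                                          c(1, 5)[g$repetition_index])
                                 })
  b_desc <- binarize_trials(d_desc, 49, "descending", "intensity")
  expect_equal(b_desc$indicator, c(1L, 0L))
})

test_that("descending comparisons exclude the innocuous baseline", {
  co <- generate_cohort(cohort_config(n_participants = 3, seed = 30))
  b <- binarize_trials(co$ratings, 49, "descending")
  expect_true(all(b$comparison_temp >= 43 & b$comparison_temp < 49))
  expect_error(binarize_trials(dplyr::filter(co$ratings, stimulus_level != 43),
                               43, "ascending"),
               class = "painpsych_discrimination_error")
})

test_that("all-discriminated series get the conventional edge thresholds", {
  asc <- ref_series(c(`43` = 1, `44` = 5, `45` = 6, `46` = 7, `47` = 8,
                      `48` = 9, `49` = 9.5))
  t_asc <- fit_threshold(binarize_trials(asc, 43, "ascending"))
  expect_equal(t_asc$threshold, 43.5)
  expect_true(t_asc$edge_case)

  desc <- ref_series(c(`43` = 1, `44` = 2, `45` = 3, `46` = 4, `47` = 5,
                       `48` = 6, `49` = 9))
  t_desc <- fit_threshold(binarize_trials(desc, 49, "descending"))
  expect_equal(t_desc$threshold, 48.5)
  expect_true(t_desc$edge_case)
})

test_that("never-discriminated series are censored past the far end", {
  flat <- ref_series(c(`43` = 3, `44` = 3, `45` = 3, `46` = 3, `47` = 3,
                       `48` = 3, `49` = 3))
  t_asc <- fit_threshold(binarize_trials(flat, 43, "ascending"))
  expect_equal(t_asc$threshold, 49.5)
  expect_equal(t_asc$status, "none_discriminated")
  expect_false(t_asc$edge_case)
})

test_that("perfectly separated series use the boundary midpoint", {
  # ascending: all-0 through 45, all-1 from 46
  sep <- ref_series(c(`43` = 3, `44` = 2.9, `45` = 2.8, `46` = 5, `47` = 6,
                      `48` = 7, `49` = 8))
  t_sep <- fit_threshold(binarize_trials(sep, 43, "ascending"))
  expect_equal(t_sep$status, "separated")
  expect_equal(t_sep$threshold, 45.5)
})

test_that("fitted thresholds equal the probability-0.5 crossing", {
  # random logistic ground truths; grid-search over the fitted curve is the
  # oracle for the -intercept/slope rule
  set.seed(31)
  checked <- 0
  for (i in 1:100) {
    b1 <- runif(1, 0.8, 3)
    thr <- runif(1, 44, 48.5)
    b0 <- -b1 * thr
    temps <- rep(44:49, each = 8)
    ind <- rbinom(length(temps), 1, stats::plogis(b0 + b1 * temps))
    series <- tibble::tibble(participant_id = "P1", reference_temp = 43,
                             direction = "ascending", measure = "intensity",
                             reference_rating = 3, comparison_temp = temps,
                             repetition_index = seq_along(temps),
                             indicator = ind)
    out <- fit_threshold(series)
    if (out$status == "fitted" && !out$clamped && out$slope > 0) {
      # two-stage grid search: coarse crossing, then refine to 1e-8 steps
      coarse <- seq(40, 55, by = 1e-3)
      c1 <- coarse[which(stats::plogis(out$intercept + out$slope * coarse)
                         >= 0.5)[1]]
      fine <- c(seq(c1 - 1e-3, c1, by = 1e-8), c1) # include the endpoint
      oracle <- fine[which(stats::plogis(out$intercept + out$slope * fine)
                           >= 0.5)[1]]
      expect_equal(out$threshold, oracle, tolerance = 1e-6)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 50)
})

test_that("threshold decreases as the logistic intercept grows", {
  slope <- 2
  thr <- vapply(seq(-95, -85, by = 2), function(b0) -b0 / slope, numeric(1))
  expect_true(all(diff(thr) < 0))
})

test_that("class comparisons combine Kruskal-Wallis and Dunn", {
  set.seed(32)
  n_per <- 30
  thresholds <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:(3 * n_per)),
    direction = "ascending", measure = "intensity",
    threshold = c(rnorm(n_per, 45, 0.5), rnorm(n_per, 45, 0.5),
                  rnorm(n_per, 46, 0.5)), # Low shifted +1 degC
    edge_case = FALSE, status = "fitted",
    intercept = NA_real_, slope = NA_real_, clamped = FALSE,
    reference_temp = 43
  )
  assignments <- tibble::tibble(
    participant_id = thresholds$participant_id,
    class_label = rep(c("High", "Moderate", "Low"), each = n_per)
  )
  cmp <- compare_thresholds(thresholds, assignments)
  expect_lt(cmp$p.value, 0.001)
  dunn <- cmp$dunn[[1]]
  expect_equal(nrow(dunn), 3)
  expect_true(any(dunn$p.adjusted < 0.05))

  # a singleton class is refused
  tiny <- assignments
  tiny$class_label[1:(n_per - 1)] <- "Moderate"
  expect_error(compare_thresholds(thresholds, tiny),
               class = "painpsych_discrimination_error")
})

test_that("the full cohort threshold table covers all four series", {
  co <- generate_cohort(cohort_config(n_participants = 10, seed = 33))
  thr <- discrimination_thresholds(co$ratings)
  expect_equal(nrow(thr), 10 * 4)
  expect_setequal(unique(thr$direction), c("ascending", "descending"))
  expect_true(all(thr$threshold[thr$direction == "ascending"] >= 43.5))
  expect_true(all(thr$threshold[thr$direction == "descending"] <= 48.5))
})
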