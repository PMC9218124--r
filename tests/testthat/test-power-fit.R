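test_that("noiseless data invert the generator to machine precision", {
  d <- data.frame(stimulus_level = 43:49,
                  rating = rating_model(43:49, exponent = 3.88,
                                        constant = -9.79))
  fit <- fit_power(d, "stimulus_level", "rating")
  expect_equal(fit$exponent, 3.88, tolerance = 1e-10)
  expect_equal(fit$constant, -9.79, tolerance = 1e-10)
  expect_equal(c(fit$df1, fit$df2), c(1L, 5L)) # 7 temperatures -> F(1, 5)
  expect_gte(fit$statistic, 0)
})

test_that("a flat response gives zero slope and zero F", {
  d <- data.frame(stimulus_level = 43:49, rating = rep(4, 7))
  fit <- fit_power(d, "stimulus_level", "rating")
  expect_equal(fit$exponent, 0, tolerance = 1e-12)
  expect_equal(fit$statistic, 0)
})

test_that("rescaling ratings shifts the constant by log k, exponent unchanged", {
  set.seed(20)
  d <- data.frame(stimulus_level = 43:49,
                  rating = rating_model(43:49, exponent = 3, constant = -7) *
                    exp(rnorm(7, 0, 0.1)))
  f1 <- fit_power(d, "stimulus_level", "rating")
  d2 <- d; d2$rating <- d$rating * 2.5
  f2 <- fit_power(d2, "stimulus_level", "rating")
  expect_equal(f2$exponent, f1$exponent, tolerance = 1e-10)
  expect_equal(f2$constant, f1$constant + log(2.5), tolerance = 1e-10)
})

test_that("non-positive means are dropped with a warning; too few points error", {
  d <- data.frame(stimulus_level = 43:49,
                  rating = c(0, 0, 1, 2, 3, 4, 5))
  expect_warning(fit <- fit_power(d, "stimulus_level", "rating"), "dropping")
  expect_equal(fit$n_points, 5)
  expect_equal(fit$df2, 3)
  d_bad <- data.frame(stimulus_level = 43:46, rating = c(0, 0, 1, 2))
  expect_error(suppressWarnings(fit_power(d_bad, "stimulus_level", "rating")),
               class = "painpsych_power_error")
})

test_that("exponent recovery is unbiased enough under trial noise", {
  # per-participant design: 7 temperatures x 4 repetitions, log-scale noise
  set.seed(21)
  errs <- replicate(50, {
    mu <- rating_model(43:49, exponent = 3.88, constant = -9.79)
    means <- vapply(mu, function(m) {
      mean(pmin(pmax(exp(log(m + 0.01) + rnorm(4, 0, 0.15)) - 0.01, 0), 10))
    }, numeric(1))
    d <- data.frame(stimulus_level = 43:49, rating = means)
    abs(fit_power(d, "stimulus_level", "rating")$exponent - 3.88)
  })
  expect_lt(median(errs), 0.3)
})

test_that("per-class fits recover class coefficients on noiseless cohorts", {
  cfg <- cohort_config(n_participants = 30, rating_noise_sd = 0, seed = 22)
  co <- generate_cohort(cfg)
  truth_lab <- dplyr::select(co$truth$participants, participant_id, class)
  fits <- fit_power_by_class(co$ratings, truth_lab)
  pars <- dplyr::filter(default_class_params(), modality == "heat")
  joined <- dplyr::left_join(fits, pars, by = c("class", "measure"))
  expect_equal(joined$exponent.x, joined$exponent.y, tolerance = 1e-6)
  expect_equal(joined$constant.x, joined$constant.y, tolerance = 1e-6)
})

test_that("unpleasantness curves are steeper with lower constants per class", {
  cfg <- cohort_config(n_participants = 45, seed = 23)
  co <- generate_cohort(cfg)
  truth_lab <- dplyr::select(co$truth$participants, participant_id, class)
  fits <- fit_power_by_class(co$ratings, truth_lab)
  cmp <- compare_exponents(fits)
  expect_true(all(cmp$exponent_greater))
  expect_true(all(cmp$constant_lower))

  # identical fits for both measures -> both comparisons false
  same <- fits
  same[same$measure == "unpleasantness",
       c("exponent", "constant")] <-
    same[same$measure == "intensity", c("exponent", "constant")]
  cmp_same <- compare_exponents(same)
  expect_false(any(cmp_same$exponent_greater))
  expect_false(any(cmp_same$constant_lower))

  # generator control with the property inverted
  flipped <- fits
  flipped[flipped$measure == "unpleasantness", c("exponent", "constant")] <-
    data.frame(exponent = fits$exponent[fits$measure == "intensity"] - 1,
               constant = fits$constant[fits$measure == "intensity"] + 1)
  cmp_flip <- compare_exponents(flipped)
  expect_false(any(cmp_flip$exponent_greater))
  expect_false(any(cmp_flip$constant_lower))

  # missing measure errors
  expect_error(compare_exponents(dplyr::filter(fits, measure == "intensity")),
               class = "painpsych_power_error")
})
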