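test_that("a recoverable linear signal is predicted almost perfectly", {
  set.seed(70)
  n <- 40; dm <- c(6, 6, 6); nv <- 216
  base <- matrix(rnorm(n * nv, 0, 0.05), n, nv)
  comp <- rnorm(n, 0, 2)                 # one strong latent component
  pattern <- rnorm(nv)
  Y <- base + outer(comp, pattern)
  ratings <- 5 + comp                    # ratings are exactly that component
  maps <- make_bms(Y, dim = dm)
  fit <- lasso_pcr_fit(maps, ratings, k_folds = 5, n_repeats = 2, seed = 1)
  expect_gt(fit$r, 0.99)
  expect_lt(fit$rmse, 0.5)
})

test_that("fold splits and predictions are reproducible under a seed", {
  set.seed(71)
  n <- 25; nv <- 64
  Y <- matrix(rnorm(n * nv), n, nv)
  maps <- make_bms(Y, dim = c(4, 4, 4))
  ratings <- rnorm(n, 5)
  a <- lasso_pcr_fit(maps, ratings, n_repeats = 2, seed = 9)
  b <- lasso_pcr_fit(maps, ratings, n_repeats = 2, seed = 9)
  expect_identical(a$folds, b$folds)
  expect_identical(a$cv_pred, b$cv_pred)
  expect_identical(a$weights, b$weights)
})

test_that("lambda selection never sees the held-out fold", {
  set.seed(72)
  n <- 30; nv <- 125
  Y <- matrix(rnorm(n * nv), n, nv)
  ratings <- rnorm(n, 5)
  maps <- make_bms(Y, dim = c(5, 5, 5))
  fit <- lasso_pcr_fit(maps, ratings, n_repeats = 1, seed = 4)
  test_idx <- which(fit$folds[, 1] == 1)
  shuffled <- ratings
  shuffled[test_idx] <- rev(shuffled[test_idx])
  refit <- lasso_pcr_fit(maps, shuffled, n_repeats = 1, seed = 4)
  lam <- function(f) f$per_fold$lambda[f$per_fold$fold == 1 &
                                         f$per_fold$repeat_ == 1]
  expect_identical(lam(fit), lam(refit))
})

test_that("back-projected weights recover the planted pattern under coupling", {
  co <- generate_cohort(cohort_config(n_participants = 80, seed = 73))
  maps <- generate_beta_maps(co$truth, "heat", "coupled", noise_sd = 0.5,
                             seed = 74)
  fit <- lasso_pcr_fit(maps, mri_high_ratings(co$ratings), n_repeats = 1,
                       seed = 5)
  planted <- numeric(sum(maps$mask))
  planted[maps$truth$effect_voxels] <- 1
  expect_gt(cor(fit$weights, planted), 0.8)
})

test_that("degenerate inputs are refused", {
  Y <- matrix(rnorm(20 * 27), 20, 27)
  maps <- make_bms(Y, dim = c(3, 3, 3))
  expect_error(lasso_pcr_fit(maps, rep(4, 20)), class = "painpsych_lasso_error")
  expect_error(lasso_pcr_fit(make_bms(matrix(1, 20, 27), dim = c(3, 3, 3)),
                             rnorm(20)), class = "painpsych_lasso_error")
  expect_error(lasso_pcr_fit(maps, rnorm(20), k_folds = 30),
               class = "painpsych_lasso_error")
})

test_that("bootstrap z ranks planted voxels above noise voxels", {
  set.seed(75)
  co <- generate_cohort(cohort_config(n_participants = 50, seed = 76))
  maps <- generate_beta_maps(co$truth, "heat", "coupled", noise_sd = 0.5,
                             grid_dim = c(8, 8, 8), blob_size = 3, seed = 77)
  ratings <- mri_high_ratings(co$ratings)
  fit <- lasso_pcr_fit(maps, ratings, n_repeats = 1, seed = 6)
  bw <- bootstrap_weights(maps, ratings, fit, n_boot = 150, seed = 7)
  planted <- bw$voxel %in% maps$truth$effect_voxels
  expect_gt(median(abs(bw$z[planted])), median(abs(bw$z[!planted])))
  expect_error(bootstrap_weights(maps, ratings, fit, n_boot = 50),
               class = "painpsych_lasso_error")
})

test_that("moderate bootstrap samples approximate a larger run", {
  set.seed(78)
  n <- 25; dm <- c(5, 5, 5); nv <- 125
  comp <- rnorm(n)
  pattern <- c(rep(2, 10), rep(0, nv - 10))
  Y <- outer(comp, pattern) + matrix(rnorm(n * nv, 0, 0.5), n, nv)
  ratings <- 5 + comp + rnorm(n, 0, 0.2)
  maps <- make_bms(Y, dim = dm)
  fit <- lasso_pcr_fit(maps, ratings, n_repeats = 1, seed = 8)
  small <- bootstrap_weights(maps, ratings, fit, n_boot = 300, seed = 10)
  large <- bootstrap_weights(maps, ratings, fit, n_boot = 1500, seed = 11)
  expect_gt(cor(small$z, large$z), 0.9)
})
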