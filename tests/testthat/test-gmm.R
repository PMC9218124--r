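test_that("single-component BIC matches the closed-form Gaussian MLE", {
  set.seed(10)
  x <- matrix(rnorm(40 * 3, mean = 2), 40, 3)
  fit <- fit_mixture(x, k = 1, seed = 1)
  # oracle: per-feature Gaussian log-density at the MLE (variance over n)
  mu <- colMeans(x)
  s2 <- colMeans(sweep(x, 2, mu)^2)
  loglik <- sum(vapply(1:3, function(j) {
    sum(dnorm(x[, j], mu[j], sqrt(s2[j]), log = TRUE))
  }, numeric(1)))
  n_params <- 2 * 3 # means + diagonal variances, no free weight
  expect_equal(fit$loglik, loglik, tolerance = 1e-6)
  expect_equal(fit$bic, -2 * loglik + n_params * log(40), tolerance = 1e-6)
})

test_that("the BIC identity holds for every fitted model", {
  set.seed(11)
  x <- rbind(matrix(rnorm(60, 0), 20), matrix(rnorm(60, 5), 20))
  for (k in 1:3) {
    fit <- fit_mixture(x, k, seed = k)
    expect_equal(fit$bic, -2 * fit$loglik + fit$n_params * log(fit$n),
                 tolerance = 1e-8)
    expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
    expect_equal(rowSums(fit$responsibilities), rep(1, fit$n),
                 tolerance = 1e-8)
  }
})

test_that("well-separated clusters are recovered exactly", {
  set.seed(12)
  x <- rbind(matrix(rnorm(80, 0, 0.5), 40), matrix(rnorm(80, 10, 0.5), 40))
  truth <- rep(1:2, each = 40)
  fit <- fit_mixture(x, k = 2, seed = 3)
  expect_equal(ari(fit$assignment, truth), 1)
})

test_that("the EM solution agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC # Mclust resolves this in the caller's scope
  set.seed(13)
  x <- rbind(matrix(rnorm(100, 0), 25, 4), matrix(rnorm(100, 4), 25, 4))
  fit <- fit_mixture(x, k = 2, seed = 4)
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVI", verbose = FALSE)
  # same partition (up to label switching) and equivalent log-likelihood
  expect_equal(ari(fit$assignment, mc$classification), 1)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4)
})

test_that("fits are deterministic given a seed", {
  set.seed(14)
  x <- matrix(rnorm(200), 50, 4)
  a <- fit_mixture(x, k = 3, seed = 9)
  b <- fit_mixture(x, k = 3, seed = 9)
  expect_identical(a$bic, b$bic)
  expect_identical(a$assignment, b$assignment)
})

test_that("spurious-class elimination dominates BIC", {
  stub <- function(k, bic, smallest) {
    structure(list(k = k, loglik = 0, bic = bic, smallest_fraction = smallest),
              class = "pain_gmm")
  }
  chosen <- select_model(list(stub(3, 100, 0.08), stub(2, 120, 0.40)))
  expect_equal(chosen$k, 2)
  tab <- attr(chosen, "selection")
  expect_true(tab$spurious[tab$k == 3])
  # among non-spurious survivors the lowest BIC wins
  chosen2 <- select_model(list(stub(1, 23518.905, 1), stub(3, 19791.321, 0.22)))
  expect_equal(chosen2$k, 3)
  # single model passes through; all-spurious errors
  expect_equal(select_model(list(stub(2, 50, 0.5)))$k, 2)
  expect_error(select_model(list(stub(4, 10, 0.05))),
               class = "painpsych_gmm_error")
})

test_that("class labels are ordered by grand mean and relabeling-invariant", {
  base <- fit_mixture(rbind(matrix(rnorm(40, 2, 0.1), 20, 2),
                            matrix(rnorm(40, 5, 0.1), 20, 2),
                            matrix(rnorm(40, 8, 0.1), 20, 2)),
                      k = 3, seed = 5)
  lab <- label_classes(base)
  expect_s3_class(lab$class_label, "ordered")
  means_by_label <- tapply(rowMeans(base$responsibilities %*% base$means),
                           lab$class_label, mean)
  expect_true(means_by_label[["Low"]] < means_by_label[["Moderate"]])
  expect_true(means_by_label[["Moderate"]] < means_by_label[["High"]])

  # permuting the component order must not change any participant's label
  perm <- c(3, 1, 2)
  permuted <- base
  permuted$means <- base$means[perm, ]
  permuted$variances <- base$variances[perm, ]
  permuted$weights <- base$weights[perm]
  permuted$responsibilities <- base$responsibilities[, perm]
  permuted$assignment <- match(base$assignment, perm)
  expect_equal(label_classes(permuted)$class_label, lab$class_label)

  # degenerate two-class labelling
  two <- fit_mixture(rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
                           matrix(rnorm(20, 6, 0.1), 10, 2)), k = 2, seed = 6)
  expect_setequal(levels(label_classes(two)$class_label), c("Low", "High"))
})
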