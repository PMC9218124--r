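test_that("3-D labelling respects face connectivity", {
  x <- array(FALSE, c(6, 6, 6))
  x[2:3, 2:3, 2:3] <- TRUE          # 8-voxel cube
  x[5, 5, 5] <- TRUE                # isolated voxel
  x[6, 6, 6] <- TRUE                # touches (5,5,5) only diagonally
  lab <- label_clusters_3d(x)
  sizes <- sort(tabulate(lab[lab > 0]))
  expect_equal(sizes, c(1, 1, 8))   # diagonal neighbours are NOT connected
  expect_equal(max(lab), 3)
  expect_equal(unique(lab[x == FALSE]), 0L)
})

test_that("cluster tables report the constructed suprathreshold blobs", {
  mask <- array(TRUE, c(8, 8, 8))
  z <- rep(0, sum(mask))
  empty <- cluster_inference(z, mask)
  expect_equal(nrow(empty$clusters), 0)

  zvol <- array(0, c(8, 8, 8))
  zvol[2:6, 3, 3] <- 5              # 5-voxel positive line
  zvol[7, 7, 5:6] <- -4             # 2-voxel negative blob
  res <- cluster_inference(zvol[mask], mask, z_thresh = 3.1)
  expect_equal(nrow(res$clusters), 2)
  expect_setequal(res$clusters$size, c(5, 2))
  expect_setequal(res$clusters$sign, c("positive", "negative"))
  expect_equal(res$clusters$peak_z[res$clusters$sign == "positive"], 5)

  expect_error(cluster_inference(zvol[mask], mask, perm_fun = function(i) z,
                                 n_perm = 50),
               class = "painpsych_cluster_error")
  expect_error(cluster_inference(c(NA, z[-1]), mask),
               class = "painpsych_cluster_error")
})

test_that("covariate GLM recovers a noiseless slope exactly and centers", {
  set.seed(50)
  n <- 20; mask <- array(TRUE, c(4, 4, 4)); nv <- sum(mask)
  ratings <- runif(n, 1, 9)
  Y <- matrix(rnorm(n * nv, 0, 0.001), n, nv)
  Y[, 7] <- 2 * ratings             # exact linear voxel
  maps <- make_bms(Y, dim = c(4, 4, 4))
  g <- fit_covariate_glm(maps, ratings, n_perm = 0)
  expect_equal(g$slope[7], 2, tolerance = 1e-9)
  expect_equal(mean(g$covariate), 0, tolerance = 1e-12)

  # adding a constant to all ratings cannot change the slopes
  g2 <- fit_covariate_glm(maps, ratings + 7, n_perm = 0)
  expect_equal(g2$slope, g$slope, tolerance = 1e-12)
  expect_equal(g2$z, g$z, tolerance = 1e-12)

  expect_error(fit_covariate_glm(maps, rep(3, n), n_perm = 0),
               "identical", class = "painpsych_glm_error")
})

test_that("paired t map is zero for identical conditions and aligned only", {
  set.seed(51)
  H <- matrix(rnorm(10 * 27), 10, 27)
  maps <- make_bms(H, H, dim = c(3, 3, 3))
  pc <- paired_contrast(maps, n_perm = 0)
  expect_true(all(pc$t == 0))
  expect_equal(pc$df, 9)

  other <- make_bms(H[10:1, ], dim = c(3, 3, 3),
                    subjects = sprintf("S%02d", 10:1))
  expect_error(paired_contrast(make_bms(H, dim = c(3, 3, 3)), other),
               class = "painpsych_glm_error")
})

test_that("paired t matches the analytic expectation for a planted effect", {
  # planted difference d = sigma at n = 25 gives E[t] ~ d sqrt(n) / sigma = 5
  set.seed(52)
  n <- 25; nv <- 125; d <- 1; sigma <- 1
  mean_t <- replicate(8, {
    D <- matrix(rnorm(n * nv, d, sigma), n, nv)
    m <- colMeans(D)
    v <- apply(D, 2, var)
    mean(m / sqrt(v / n))
  })
  expect_equal(mean(mean_t), d * sqrt(n) / sigma, tolerance = 0.1)
  # and the package's map-level statistic agrees with the direct formula
  D <- matrix(rnorm(n * nv, d, sigma), n, nv)
  maps <- make_bms(D + 1, matrix(1, n, nv), dim = c(5, 5, 5))
  pc <- paired_contrast(maps, n_perm = 0)
  expect_equal(pc$t, colMeans(D) / sqrt(apply(D, 2, var) / n),
               tolerance = 1e-9)
})

test_that("class contrasts are null for identical classes and need >= 2 members", {
  n <- 18; nv <- 64
  Y <- matrix(rep(seq_len(nv), each = n), n, nv) # identical rows
  maps <- make_bms(Y, dim = c(4, 4, 4))
  asg <- tibble::tibble(participant_id = maps$subjects,
                        class_label = rep(c("Low", "Moderate", "High"), 6))
  cc <- class_contrasts(maps, asg, n_perm = 0)
  expect_true(all(cc$f_z < 1e-6))
  expect_equal(nrow(cc$pairwise), 6)

  solo <- asg
  solo$class_label <- c("Low", rep("High", n - 1))
  expect_error(class_contrasts(maps, solo, n_perm = 0),
               class = "painpsych_glm_error")
})

test_that("a planted class offset is detected and flagged significant", {
  set.seed(53)
  n <- 24; dm <- c(6, 6, 6); mask <- array(TRUE, dm); nv <- sum(mask)
  Y <- matrix(rnorm(n * nv), n, nv)
  cls <- rep(c("Low", "Moderate", "High"), each = 8)
  Y[cls == "High", 1:12] <- Y[cls == "High", 1:12] + 4
  maps <- make_bms(Y, dim = dm)
  asg <- tibble::tibble(participant_id = maps$subjects, class_label = cls)
  cc <- class_contrasts(maps, asg, z_thresh = 3.1, n_perm = 150, seed = 2)
  expect_gte(nrow(cc$f_test$clusters), 1)
  expect_true(any(cc$f_test$clusters$significant))
})
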