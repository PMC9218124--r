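#' LASSO-PCR: cross-validated prediction of ratings from beta maps
#'
#' Whole-brain multivariate regression in the canonical LASSO-PCR form: per
#' outer fold, training maps are column-centered, projected onto their
#' principal components (all `min(n_train - 1, n_voxels)` components retained;
#' the L1 penalty performs the selection), and an L1-penalized regression of
#' ratings on the component scores is fitted with lambda chosen by an inner
#' 5-fold cross-validation to minimize mean squared error (lambda path of
#' `nlambda` values down to `lambda_min_ratio * lambda_max`). Held-out
#' subjects are predicted by the fold's pipeline; the procedure runs `k_folds`
#' folds and is repeated `n_repeats` times with fresh splits, so every subject
#' is tested exactly once per repeat. Cross-validation error is reported as
#' RMSE in VAS units (MAE alongside). A final model on all subjects supplies
#' the back-projected voxel weight map.
#'
#' @param maps a [beta_map_set()].
#' @param ratings per-subject ratings (vector aligned to `maps$subjects` or
#'   data frame with `participant_id`, `rating`).
#' @param condition which condition's maps to use.
#' @param k_folds outer (and inner) fold count.
#' @param n_repeats outer repetitions.
#' @param seed integer seed; fixes fold splits and the lambda path draws.
#' @param nlambda,lambda_min_ratio lambda path geometry.
#' @return object of class `lasso_pcr`: `pred` (per-subject cross-validated
#'   prediction, averaged over repeats), `cv_pred` (n x repeats),
#'   `r` (mean within-test-fold correlation of observed and predicted,
#'   averaged over folds and repeats; `r_pooled` is the correlation over the
#'   concatenated held-out predictions), `rmse`, `mae` (mean
#'   over repeats of per-repeat held-out error), `per_fold` lambda table,
#'   `weights` (voxel weight map of the full-data model), `intercept`,
#'   `lambda_full`.
#' @export
lasso_pcr_fit <- function(maps, ratings, condition = "high", k_folds = 5,
                          n_repeats = 5, seed = 1L, nlambda = 50,
                          lambda_min_ratio = 1e-3) {
  stopifnot(inherits(maps, "beta_map_set"))
  Y <- maps$maps[[condition]]
  if (is.null(Y)) abort(sprintf("no '%s' condition in maps.", condition),
                        class = "painpsych_lasso_error")
  y <- align_ratings(ratings, maps$subjects)
  n <- nrow(Y)
  if (n < k_folds) abort("need at least `k_folds` subjects.",
                         class = "painpsych_lasso_error")
  if (var(y) == 0) abort("zero-variance ratings.", class = "painpsych_lasso_error")
  if (all(apply(Y, 2, var) == 0)) abort("constant maps (zero variance).",
                                        class = "painpsych_lasso_error")
  set.seed(seed)
  cv_pred <- matrix(NA_real_, n, n_repeats)
  folds <- matrix(NA_integer_, n, n_repeats)
  per_fold <- vector("list", n_repeats * k_folds)
  idx <- 0
  for (rep_i in seq_len(n_repeats)) {
    fold_id <- sample(rep(seq_len(k_folds), length.out = n))
    folds[, rep_i] <- fold_id
    for (f in seq_len(k_folds)) {
      test <- which(fold_id == f)
      train <- which(fold_id != f)
      fit <- lasso_pcr_train(Y[train, , drop = FALSE], y[train],
                             k_inner = k_folds, nlambda = nlambda,
                             lambda_min_ratio = lambda_min_ratio)
      cv_pred[test, rep_i] <- lasso_pcr_predict(fit, Y[test, , drop = FALSE])
      idx <- idx + 1
      per_fold[[idx]] <- tibble(repeat_ = rep_i, fold = f, lambda = fit$lambda)
    }
  }
  per_fold <- list_rbind(per_fold)
  # prediction r is the mean within-test-fold correlation: pooling held-out
  # predictions across folds anti-correlates fold-mean (intercept-only)
  # predictions with the held-out ratings (~ -1/sqrt(fold size)) even when the
  # maps carry no signal, so the pooled r is reported separately
  foldwise_r <- function(p, fold_id) {
    mean(vapply(unique(fold_id), function(f) {
      i <- fold_id == f
      if (sd(p[i]) == 0 || sd(y[i]) == 0) 0 else cor(p[i], y[i])
    }, numeric(1)))
  }
  per_repeat <- tibble(
    repeat_ = seq_len(n_repeats),
    rmse = apply(cv_pred, 2, function(p) sqrt(mean((p - y)^2))),
    mae = apply(cv_pred, 2, function(p) mean(abs(p - y))),
    r = vapply(seq_len(n_repeats),
               function(j) foldwise_r(cv_pred[, j], folds[, j]), numeric(1))
  )
  pred <- rowMeans(cv_pred)
  full <- lasso_pcr_train(Y, y, k_inner = k_folds, nlambda = nlambda,
                          lambda_min_ratio = lambda_min_ratio)
  structure(
    list(pred = pred, cv_pred = cv_pred, ratings = y,
         subjects = maps$subjects, folds = folds,
         r = mean(per_repeat$r),
         r_pooled = if (sd(pred) == 0) 0 else cor(pred, y),
         rmse = mean(per_repeat$rmse), mae = mean(per_repeat$mae),
         per_repeat = per_repeat, per_fold = per_fold,
         weights = full$weights, intercept = full$intercept,
         lambda_full = full$lambda, full_fit = full,
         k_folds = k_folds, n_repeats = n_repeats, condition = condition,
         mask = maps$mask),
    class = "lasso_pcr"
  )
}

# one PCA + inner-CV lasso pipeline on a training set; returns everything
# needed to predict new maps and to back-project voxel weights
lasso_pcr_train <- function(X, y, k_inner = 5, nlambda = 50,
                            lambda_min_ratio = 1e-3, lambda = NULL) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  n <- nrow(Xc)
  ncomp <- min(n - 1, ncol(Xc))
  sv <- svd(Xc, nu = ncomp, nv = ncomp)
  keep <- sv$d[seq_len(ncomp)] > max(sv$d) * 1e-10
  V <- sv$v[, keep, drop = FALSE]
  scores <- Xc %*% V
  if (ncol(scores) < 2) {
    # glmnet needs >= 2 predictors; pad with an inert zero column
    scores <- cbind(scores, 0)
    V <- cbind(V, 0)
  }
  if (is.null(lambda)) {
    foldid <- sample(rep(seq_len(k_inner), length.out = n))
    cv <- glmnet::cv.glmnet(scores, y, alpha = 1, foldid = foldid,
                            nlambda = nlambda,
                            lambda.min.ratio = lambda_min_ratio,
                            standardize = FALSE)
    lambda <- cv$lambda.min
    fit <- glmnet::glmnet(scores, y, alpha = 1, lambda = lambda,
                          standardize = FALSE)
  } else {
    fit <- glmnet::glmnet(scores, y, alpha = 1, lambda = lambda,
                          standardize = FALSE)
  }
  beta_pc <- as.numeric(fit$beta)
  b0 <- as.numeric(fit$a0)
  w <- as.numeric(V %*% beta_pc)
  list(center = ctr, loadings = V, coef_pc = beta_pc, weights = w,
       intercept = b0, lambda = lambda)
}

lasso_pcr_predict <- function(fit, Xnew) {
  Xc <- sweep(Xnew, 2, fit$center)
  as.numeric(fit$intercept + Xc %*% fit$weights)
}

#' @export
print.lasso_pcr <- function(x, ...) {
  cat(sprintf("<lasso_pcr> %d subjects, %d-fold x %d repeats; r = %.3f, RMSE = %.3f VAS, MAE = %.3f VAS\n",
              length(x$ratings), x$k_folds, x$n_repeats, x$r, x$rmse, x$mae))
  invisible(x)
}

#' @describeIn lasso_pcr_fit per-subject observed/predicted table.
#' @param x,object a `lasso_pcr`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.lasso_pcr <- function(x, ...) {
  tibble(participant_id = x$subjects, observed = x$ratings,
         predicted = x$pred)
}

#' @describeIn lasso_pcr_fit one-row model summary.
#' @exportS3Method generics::glance
glance.lasso_pcr <- function(x, ...) {
  tibble(r = x$r, rmse = x$rmse, mae = x$mae, k_folds = x$k_folds,
         n_repeats = x$n_repeats, n = length(x$ratings),
         lambda_full = x$lambda_full)
}

#' Observed vs cross-validated predicted ratings
#'
#' @param object a `lasso_pcr`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lasso_pcr <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$observed, y = .data$predicted)) +
    geom_abline(linetype = 2, colour = "grey60") +
    geom_point(alpha = 0.7) +
    labs(x = "observed rating (VAS)", y = "cross-validated prediction (VAS)",
         title = sprintf("r = %.2f, RMSE = %.2f VAS", object$r, object$rmse)) +
    theme_minimal()
}

#' Bootstrap inference on LASSO-PCR voxel weights
#'
#' Resamples subjects with replacement, refits the PCA + LASSO pipeline on
#' each bootstrap sample (lambda fixed at the full-data cross-validated
#' value), and summarizes each voxel's weight distribution as
#' `z = mean / sd` with a two-sided normal p-value. Voxels whose weight is
#' zero in every sample get `z = 0`.
#'
#' @param maps a [beta_map_set()].
#' @param ratings per-subject ratings (as in [lasso_pcr_fit()]).
#' @param model fitted `lasso_pcr`.
#' @param n_boot bootstrap samples (>= 100).
#' @param condition which condition's maps to use.
#' @param seed integer seed.
#' @return tibble: `voxel`, `weight_mean`, `weight_sd`, `z`, `p.value`.
#' @export
bootstrap_weights <- function(maps, ratings, model, n_boot = 5000,
                              condition = "high", seed = 1L) {
  stopifnot(inherits(maps, "beta_map_set"), inherits(model, "lasso_pcr"))
  if (n_boot < 100) abort("`n_boot` must be >= 100.", class = "painpsych_lasso_error")
  Y <- maps$maps[[condition]]
  y <- align_ratings(ratings, maps$subjects)
  n <- nrow(Y)
  set.seed(seed)
  W <- matrix(0, n_boot, ncol(Y))
  for (b in seq_len(n_boot)) {
    take <- sample.int(n, n, replace = TRUE)
    fit <- lasso_pcr_train(Y[take, , drop = FALSE], y[take],
                           lambda = model$lambda_full)
    W[b, ] <- fit$weights
  }
  wm <- colMeans(W)
  ws <- apply(W, 2, sd)
  z <- ifelse(ws == 0, 0, wm / ws)
  tibble(voxel = seq_len(ncol(Y)), weight_mean = wm, weight_sd = ws,
         z = z, p.value = ifelse(z == 0, 1, 2 * pnorm(-abs(z))))
}
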