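#' Fit a diagonal-covariance Gaussian mixture to rating features
#'
#' EM with per-class diagonal covariances (full covariances are
#' ill-conditioned at ~100 participants x 14 features), a ridge floor on the
#' variances, and multiple kmeans++-style restarts; the restart with the best
#' log-likelihood is kept. BIC is `-2 loglik + n_params log(n)` with
#' `n_params = (k - 1) + 2 k d` (mixing weights, means, diagonal variances).
#'
#' @param features feature tibble from [build_feature_matrix()] (or a plain
#'   numeric matrix).
#' @param k number of mixture components (>= 1).
#' @param n_restarts random initializations; best log-likelihood wins.
#' @param seed integer seed for reproducible initialization.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per restart.
#' @param var_floor ridge floor applied to every variance.
#'
#' @return object of class `pain_gmm`: weights, means, variances,
#'   log-likelihood, BIC, responsibilities, hard assignments (maximum
#'   responsibility, ties to the lowest class index), smallest-class fraction.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 4), 30))
#' fit <- fit_mixture(x, k = 2, seed = 1)
#' fit$bic
#' @export
fit_mixture <- function(features, k, n_restarts = 20, seed = NULL,
                        tol = 1e-8, max_iter = 500, var_floor = 1e-6) {
  x <- if (is.data.frame(features)) feature_matrix_values(features) else as.matrix(features)
  n <- nrow(x); d <- ncol(x)
  if (k < 1) abort("`k` must be >= 1.", class = "painpsych_gmm_error")
  if (n < k) abort("need at least as many rows as components.", class = "painpsych_gmm_error")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (r in seq_len(max(1L, if (k == 1) 1L else n_restarts))) {
    fit <- em_diag_gmm(x, k, tol, max_iter, var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  n_params <- (k - 1) + 2 * k * d
  bic <- -2 * best$loglik + n_params * log(n)
  assignment <- max.col(best$resp, ties.method = "first")
  frac <- tabulate(assignment, nbins = k) / n
  structure(
    list(k = k, weights = best$weights, means = best$means,
         variances = best$variances, loglik = best$loglik,
         n_params = n_params, bic = bic, responsibilities = best$resp,
         assignment = assignment, smallest_fraction = min(frac),
         class_fractions = frac, n = n, d = d,
         converged = best$converged, n_iter = best$iter,
         feature_names = colnames(x), participant_id = rownames(x)),
    class = "pain_gmm"
  )
}

# kmeans++-style seeding: spread initial centers, then one hard assignment
init_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- apply(x, 1, function(row) {
        min(colSums((t(centers[seq_len(j - 1), , drop = FALSE]) - row)^2))
      })
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    }
  }
  centers
}

em_diag_gmm <- function(x, k, tol, max_iter, var_floor) {
  n <- nrow(x); d <- ncol(x)
  centers <- init_centers(x, k)
  assign0 <- max.col(-outer(rowSums(x^2), rep(1, k)) +
                       2 * x %*% t(centers) -
                       outer(rep(1, n), rowSums(centers^2)),
                     ties.method = "first")
  weights <- pmax(tabulate(assign0, k), 1) / sum(pmax(tabulate(assign0, k), 1))
  means <- centers
  variances <- matrix(NA_real_, k, d)
  gvar <- pmax(apply(x, 2, var), var_floor)
  for (j in seq_len(k)) {
    rows <- which(assign0 == j)
    if (length(rows) >= 2) {
      means[j, ] <- colMeans(x[rows, , drop = FALSE])
      variances[j, ] <- pmax(apply(x[rows, , drop = FALSE], 2, var), var_floor)
    } else {
      variances[j, ] <- gvar
    }
  }

  loglik <- -Inf; converged <- FALSE; iter <- 0
  for (iter in seq_len(max_iter)) {
    # E step: log N(x | mu_j, diag(sigma2_j)) + log w_j
    logdens <- sapply(seq_len(k), function(j) {
      -0.5 * (d * log(2 * pi) + sum(log(variances[j, ])) +
                colSums((t(x) - means[j, ])^2 / variances[j, ]))
    })
    logdens <- matrix(logdens, n, k)
    logpost <- sweep(logdens, 2, log(weights), "+")
    m <- apply(logpost, 1, max)
    lse <- m + log(rowSums(exp(logpost - m)))
    new_loglik <- sum(lse)
    resp <- exp(logpost - lse)

    if (is.finite(loglik) &&
        abs(new_loglik - loglik) <= tol * (abs(loglik) + 1)) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik

    # M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    weights <- nk / n
    means <- (t(resp) %*% x) / nk
    for (j in seq_len(k)) {
      variances[j, ] <- pmax(
        colSums(resp[, j] * (t(t(x) - means[j, ]))^2) / nk[j], var_floor)
    }
  }
  list(weights = as.numeric(weights), means = means, variances = variances,
       resp = resp, loglik = loglik, converged = converged, iter = iter)
}

#' Select a mixture model by the spurious-class and BIC rules
#'
#' Models containing a spurious class -- one capturing at most
#' `spurious_fraction` of the participants -- are eliminated first (such
#' solutions reflect over-extraction rather than real subpopulations); among
#' the survivors the model with the lowest BIC is returned.
#'
#' @param models list of `pain_gmm` fits (typically k = 1..5).
#' @param spurious_fraction largest class fraction still counted as spurious.
#' @return the selected `pain_gmm`, with a `selection` attribute holding the
#'   per-model decision table.
#' @export
select_model <- function(models, spurious_fraction = 0.10) {
  if (length(models) == 0) abort("no models supplied.", class = "painpsych_gmm_error")
  stopifnot(all(vapply(models, inherits, TRUE, "pain_gmm")))
  tab <- tibble(
    k = vapply(models, `[[`, 0, "k"),
    loglik = vapply(models, `[[`, 0, "loglik"),
    bic = vapply(models, `[[`, 0, "bic"),
    smallest_fraction = vapply(models, `[[`, 0, "smallest_fraction"),
    spurious = .data$smallest_fraction <= spurious_fraction
  )
  survivors <- which(!tab$spurious)
  if (length(survivors) == 0) {
    abort("all candidate models contain a spurious class.",
          class = "painpsych_gmm_error")
  }
  pick <- survivors[which.min(tab$bic[survivors])]
  tab$selected <- seq_len(nrow(tab)) == pick
  out <- models[[pick]]
  attr(out, "selection") <- tab
  out
}

#' Order mixture classes into sensitivity labels
#'
#' Classes are ranked by the grand mean of their mean feature vector
#' (ascending): the class with the lowest average rating profile is `Low`, the
#' highest `High`. For three classes the labels are Low/Moderate/High; for two,
#' Low/High; otherwise ranked `C1 < C2 < ...`.
#'
#' @param model fitted `pain_gmm`.
#' @return tibble: `participant_id`, `class_label` (ordered factor),
#'   `max_responsibility`.
#' @export
label_classes <- function(model) {
  stopifnot(inherits(model, "pain_gmm"))
  grand <- rowMeans(model$means)
  if (anyDuplicated(grand)) {
    warn("tied class grand means; breaking ties by class index.")
  }
  ord <- order(grand, seq_along(grand))
  labels <- switch(as.character(model$k),
                   "1" = "All",
                   "2" = c("Low", "High"),
                   "3" = c("Low", "Moderate", "High"),
                   paste0("C", seq_len(model$k)))
  class_of_component <- character(model$k)
  class_of_component[ord] <- labels
  ids <- model$participant_id %||% sprintf("row%03d", seq_len(model$n))
  tibble(
    participant_id = ids,
    class_label = factor(class_of_component[model$assignment],
                         levels = labels, ordered = TRUE),
    max_responsibility = model$responsibilities[cbind(seq_len(model$n),
                                                      model$assignment)]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pain_gmm <- function(x, ...) {
  cat(sprintf("<pain_gmm> k = %d, n = %d, d = %d, loglik = %.3f, BIC = %.3f\n",
              x$k, x$n, x$d, x$loglik, x$bic))
  cat("class fractions:", paste(sprintf("%.2f", x$class_fractions), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn fit_mixture per-component summary (weight, grand mean, BIC).
#' @param x,object a `pain_gmm`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.pain_gmm <- function(x, ...) {
  tibble(component = seq_len(x$k),
         weight = x$weights,
         grand_mean = rowMeans(x$means),
         n_assigned = tabulate(x$assignment, x$k))
}

#' @describeIn fit_mixture one-row model summary.
#' @exportS3Method generics::glance
glance.pain_gmm <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, bic = x$bic, n_params = x$n_params,
         smallest_fraction = x$smallest_fraction, n = x$n,
         converged = x$converged)
}

#' BIC-by-k profile plot for a set of candidate mixtures
#'
#' @param models list of `pain_gmm` fits.
#' @param spurious_fraction threshold used to shade spurious models.
#' @return a ggplot.
#' @export
plot_bic_profile <- function(models, spurious_fraction = 0.10) {
  tab <- purrr::map(models, glance) %>% list_rbind()
  tab$spurious <- tab$smallest_fraction <= spurious_fraction
  ggplot(tab, aes(x = .data$k, y = .data$bic, colour = .data$spurious)) +
    geom_line(colour = "grey50") +
    geom_point(size = 3) +
    scale_colour_manual(values = c(`FALSE` = "#2c7fb8", `TRUE` = "#d95f02"),
                        name = "spurious class") +
    labs(x = "number of classes", y = "BIC") +
    theme_minimal()
}
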