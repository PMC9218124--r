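#' Voxelwise covariate GLM (second level)
#'
#' Regresses each voxel's contrast amplitude on the mean-centered per-subject
#' rating: `beta_v ~ intercept + centered(rating)`. The slope t statistic
#' (df `n - 2`) is converted to z via the normal-quantile transform, and
#' cluster-level inference uses covariate permutation: the rating vector is
#' randomly permuted against subjects, breaking any brain-rating coupling
#' while preserving both marginals.
#'
#' @param maps a [beta_map_set()].
#' @param ratings per-subject mean ratings: numeric vector aligned with
#'   `maps$subjects`, or a data frame (`participant_id`, `rating`).
#' @param condition which condition's maps to analyse.
#' @param z_thresh cluster-forming threshold.
#' @param alpha cluster-level alpha.
#' @param n_perm permutations for the cluster null (0 disables inference).
#' @param seed permutation seed.
#' @return object of class `covariate_glm`: per-voxel `slope`, `t`, `z`
#'   vectors, the centered covariate, and a [cluster_inference()] result.
#' @export
fit_covariate_glm <- function(maps, ratings, condition = "high",
                              z_thresh = 3.1, alpha = 0.05, n_perm = 1000,
                              seed = 1L) {
  stopifnot(inherits(maps, "beta_map_set"))
  Y <- maps$maps[[condition]]
  if (is.null(Y)) abort(sprintf("no '%s' condition in maps.", condition),
                        class = "painpsych_glm_error")
  x <- align_ratings(ratings, maps$subjects)
  if (var(x) == 0) abort("all ratings identical (zero-variance covariate).",
                         class = "painpsych_glm_error")
  n <- nrow(Y)
  xc <- x - mean(x)
  Yc <- sweep(Y, 2, colMeans(Y))
  Syy <- colSums(Yc^2)
  Sxx <- sum(xc^2)
  df <- n - 2
  stat <- covariate_stats(xc, Yc, Syy, Sxx, df)
  clus <- NULL
  if (n_perm > 0) {
    set.seed(seed)
    perm_fun <- function(i) {
      xp <- xc[sample.int(n)]
      covariate_stats(xp, Yc, Syy, Sxx, df)$z
    }
    clus <- cluster_inference(stat$z, maps$mask, z_thresh, alpha,
                              perm_fun, n_perm)
  } else {
    clus <- cluster_inference(stat$z, maps$mask, z_thresh, alpha)
  }
  structure(list(slope = stat$slope, t = stat$t, z = stat$z,
                 covariate = xc, df = df, condition = condition,
                 clusters = clus, mask = maps$mask),
            class = "covariate_glm")
}

covariate_stats <- function(xc, Yc, Syy, Sxx, df) {
  slope <- as.numeric(crossprod(xc, Yc)) / Sxx
  rss <- pmax(Syy - slope^2 * Sxx, 0)
  sigma2 <- rss / df
  t <- slope / sqrt(pmax(sigma2 / Sxx, .Machine$double.xmin))
  list(slope = slope, t = t, z = t_to_z(t, df))
}

align_ratings <- function(ratings, subjects) {
  if (is.data.frame(ratings)) {
    col <- intersect(c("rating", "mean_rating"), names(ratings))[1]
    if (is.na(col) || !"participant_id" %in% names(ratings)) {
      abort("rating data frame needs `participant_id` and `rating` columns.",
            class = "painpsych_glm_error")
    }
    x <- ratings[[col]][match(subjects, ratings$participant_id)]
    if (any(is.na(x))) abort("ratings missing for some subjects.",
                             class = "painpsych_glm_error")
    return(x)
  }
  if (length(ratings) != length(subjects)) {
    abort("ratings length must equal subject count.", class = "painpsych_glm_error")
  }
  as.numeric(ratings)
}

#' @export
print.covariate_glm <- function(x, ...) {
  cat(sprintf("<covariate_glm> condition '%s', df = %d, max |z| = %.2f\n",
              x$condition, x$df, max(abs(x$z))))
  print(x$clusters)
  invisible(x)
}

#' @describeIn fit_covariate_glm cluster table as a tibble.
#' @param x,object a `covariate_glm`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.covariate_glm <- function(x, ...) x$clusters$clusters

#' Within-individual paired contrast (high vs low intensity)
#'
#' Per-voxel paired t test on the high-minus-low difference maps
#' (df `n - 1`), converted to z. Cluster inference uses sign flipping of the
#' per-subject difference maps, exact under exchangeability of the
#' within-subject difference sign.
#'
#' @param maps a [beta_map_set()] with `high` and `low` conditions, or the
#'   high-condition set when `low` is supplied separately.
#' @param low optional second [beta_map_set()] holding the low condition.
#' @inheritParams fit_covariate_glm
#' @return object of class `paired_contrast`: per-voxel `t`, `z`, `df`, and a
#'   [cluster_inference()] result.
#' @export
paired_contrast <- function(maps, low = NULL, z_thresh = 3.1, alpha = 0.05,
                            n_perm = 1000, seed = 1L) {
  if (is.null(low)) {
    stopifnot(inherits(maps, "beta_map_set"))
    H <- maps$maps$high; L <- maps$maps$low
    mask <- maps$mask
    if (is.null(H) || is.null(L)) {
      abort("maps must contain both 'high' and 'low' conditions.",
            class = "painpsych_glm_error")
    }
  } else {
    stopifnot(inherits(maps, "beta_map_set"), inherits(low, "beta_map_set"))
    if (!identical(maps$subjects, low$subjects)) {
      abort("subject sets (and order) must match between conditions.",
            class = "painpsych_glm_error")
    }
    if (!identical(dim(maps$mask), dim(low$mask))) {
      abort("grids must match between conditions.", class = "painpsych_glm_error")
    }
    H <- maps$maps[[1]]; L <- low$maps[[1]]; mask <- maps$mask
  }
  D <- H - L
  n <- nrow(D)
  df <- n - 1
  D2 <- colSums(D^2)
  tstat <- paired_t_stats(colSums(D) / n, D2, n)
  z <- t_to_z(tstat, df)
  set.seed(seed)
  perm_fun <- function(i) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    m <- as.numeric(crossprod(s, D)) / n
    t_to_z(paired_t_stats(m, D2, n), df)
  }
  clus <- if (n_perm > 0) {
    cluster_inference(z, mask, z_thresh, alpha, perm_fun, n_perm)
  } else {
    cluster_inference(z, mask, z_thresh, alpha)
  }
  structure(list(t = tstat, z = z, df = df, clusters = clus, mask = mask),
            class = "paired_contrast")
}

# mean and sum-of-squares parameterization: sd recomputed per sign flip,
# exploiting that squared differences are flip-invariant
paired_t_stats <- function(m, D2, n) {
  v <- pmax((D2 - n * m^2) / (n - 1), 0)
  m / sqrt(pmax(v / n, .Machine$double.xmin))
}

#' @export
print.paired_contrast <- function(x, ...) {
  cat(sprintf("<paired_contrast> df = %d, max |z| = %.2f\n", x$df, max(abs(x$z))))
  print(x$clusters)
  invisible(x)
}

#' @describeIn paired_contrast cluster table as a tibble.
#' @param x,object a `paired_contrast`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.paired_contrast <- function(x, ...) x$clusters$clusters

#' Between-class contrasts on beta maps
#'
#' Per voxel, a one-way ANOVA F across sensitivity classes plus the directed
#' pairwise t contrasts (pooled within-class variance, df `n - k`). The F map
#' and each pair's |t| map are passed through permutation cluster inference
#' (class labels permuted across subjects); the two directed contrasts of a
#' pair share one two-sided inference with mirrored signs.
#'
#' @param maps a [beta_map_set()].
#' @param assignments tibble (`participant_id`, `class_label`).
#' @param condition which condition's maps to analyse.
#' @inheritParams fit_covariate_glm
#' @return list with `f_test` (cluster result + z map) and `pairwise` (tibble
#'   of directed contrasts with cluster counts), class `class_contrasts`.
#' @export
class_contrasts <- function(maps, assignments, condition = "high",
                            z_thresh = 3.1, alpha = 0.05, n_perm = 1000,
                            seed = 1L) {
  stopifnot(inherits(maps, "beta_map_set"))
  Y <- maps$maps[[condition]]
  lab_col <- if ("class_label" %in% names(assignments)) "class_label" else "class"
  g <- assignments[[lab_col]][match(maps$subjects, assignments$participant_id)]
  if (any(is.na(g))) abort("class labels missing for some subjects.",
                           class = "painpsych_glm_error")
  g <- factor(g)
  cnt <- table(g)
  if (nlevels(g) < 2 || any(cnt < 2)) {
    abort("need >= 2 classes with >= 2 members each.", class = "painpsych_glm_error")
  }
  n <- nrow(Y); k <- nlevels(g)
  anova_f <- function(gg) {
    G <- stats::model.matrix(~ gg - 1)
    ng <- colSums(G)
    M <- (t(G) %*% Y) / ng              # class means, k x p
    grand <- colMeans(Y)
    ssb <- colSums(ng * (sweep(M, 2, grand))^2)
    sst <- colSums(sweep(Y, 2, grand)^2)
    ssw <- pmax(sst - ssb, 0)
    f <- (ssb / (k - 1)) / pmax(ssw / (n - k), .Machine$double.xmin)
    list(f = f, M = M, s2p = ssw / (n - k), ng = ng)
  }
  obs <- anova_f(g)
  zf <- f_to_z(obs$f, k - 1, n - k)
  set.seed(seed)
  fperm <- function(i) f_to_z(anova_f(g[sample.int(n)])$f, k - 1, n - k)
  f_clus <- if (n_perm > 0) {
    cluster_inference(zf, maps$mask, z_thresh, alpha, fperm, n_perm)
  } else {
    cluster_inference(zf, maps$mask, z_thresh, alpha)
  }

  pairs <- utils::combn(levels(g), 2)
  pairwise <- map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ia <- which(levels(g) == a); ib <- which(levels(g) == b)
    tmap <- function(res) {
      (res$M[ia, ] - res$M[ib, ]) /
        sqrt(pmax(res$s2p * (1 / res$ng[ia] + 1 / res$ng[ib]),
                  .Machine$double.xmin))
    }
    zt <- t_to_z(tmap(obs), n - k)
    pperm <- function(i) t_to_z(tmap(anova_f(g[sample.int(n)])), n - k)
    clus <- if (n_perm > 0) {
      cluster_inference(zt, maps$mask, z_thresh, alpha, pperm, n_perm)
    } else {
      cluster_inference(zt, maps$mask, z_thresh, alpha)
    }
    tibble(contrast = c(paste(a, ">", b), paste(b, ">", a)),
           n_clusters = nrow(clus$clusters),
           n_significant = if (n_perm > 0) sum(clus$clusters$significant) else NA_integer_,
           result = list(clus, clus))
  }) %>% list_rbind()

  structure(list(f_z = zf, f_test = f_clus, pairwise = pairwise,
                 df1 = k - 1, df2 = n - k),
            class = "class_contrasts")
}

#' @export
print.class_contrasts <- function(x, ...) {
  cat(sprintf("<class_contrasts> F(%d,%d) map: %d cluster(s); pairwise contrasts: %d\n",
              x$df1, x$df2, nrow(x$f_test$clusters), nrow(x$pairwise)))
  invisible(x)
}
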