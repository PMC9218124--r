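#' Kruskal-Wallis rank test
#'
#' Thin wrapper over [stats::kruskal.test()] that also reports the
#' tie-correction factor and returns the degenerate all-tied case as
#' `H = 0, p = 1` instead of failing, so pipelines survive pathological
#' synthetic draws.
#'
#' @param x either a list of numeric vectors (one per group) or a numeric
#'   vector accompanied by `g`.
#' @param g optional grouping vector when `x` is numeric.
#' @return tibble: `statistic` (H), `df`, `p.value`, `tie_correction`,
#'   `n`, `k_groups`.
#' @export
kruskal_wallis <- function(x, g = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    g <- rep(seq_along(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  g <- factor(g)
  if (nlevels(g) < 2) abort("need >= 2 groups.", class = "painpsych_stats_error")
  tie_c <- tie_correction(x)
  if (length(unique(x)) == 1) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p.value = 1,
                  tie_correction = tie_c, n = length(x),
                  k_groups = nlevels(g)))
  }
  kt <- kruskal.test(x, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value, tie_correction = tie_c, n = length(x),
         k_groups = nlevels(g))
}

# 1 - sum(t^3 - t) / (N^3 - N) over tied groups of the pooled sample
tie_correction <- function(x) {
  n <- length(x)
  t <- table(x)
  1 - sum(t^3 - t) / (n^3 - n)
}

#' Dunn's post-hoc pairwise rank comparisons
#'
#' Standard Dunn z statistics from pooled rank sums with the tie correction
#' shared with [kruskal_wallis()]:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tied values. Two-sided p-values are adjusted
#' with [stats::p.adjust()] (default Bonferroni).
#'
#' @inheritParams kruskal_wallis
#' @param adjust adjustment method label accepted by [stats::p.adjust()].
#' @return tibble: `group1`, `group2`, `z`, `p.value`, `p.adjusted`, `method`.
#' @export
dunn_posthoc <- function(x, g = NULL, adjust = "bonferroni") {
  if (!adjust %in% p.adjust.methods) {
    abort(sprintf("unknown adjustment method '%s'.", adjust),
          class = "painpsych_stats_error")
  }
  if (is.list(x) && !is.data.frame(x)) {
    g <- rep(if (is.null(names(x))) seq_along(x) else names(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  g <- factor(g)
  if (nlevels(g) < 2) abort("need >= 2 groups.", class = "painpsych_stats_error")
  n <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)
  n_i <- tapply(rk, g, length)
  ties <- table(x)
  tie_sum <- sum(ties^3 - ties)
  var_term <- n * (n + 1) / 12 - tie_sum / (12 * (n - 1))
  pairs <- utils::combn(levels(g), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(var_term * (1 / n_i[[a]] + 1 / n_i[[b]]))
    z[j] <- if (se == 0) 0 else (mean_rank[[a]] - mean_rank[[b]]) / se
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p.value = p,
         p.adjusted = pmin(p.adjust(p, method = adjust), 1),
         method = adjust)
}

#' Paired t test
#'
#' One-sample t on the within-subject differences (`df = n - 1`). When every
#' difference is identical the t statistic is reported by convention as 0
#' (all zero) or signed infinity (all equal, non-zero) with a warning.
#'
#' @param x,y matched numeric vectors.
#' @return tibble: `statistic`, `df`, `p.value`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "painpsych_stats_error")
  }
  if (length(x) < 2) abort("need n >= 2.", class = "painpsych_stats_error")
  d <- x - y
  # floating-point residue (e.g. (x+1) - x) still counts as constant
  if (sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    warn("zero variance of differences; degenerate t convention applied.")
    t0 <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(tibble(statistic = t0, df = length(d) - 1L,
                  p.value = if (t0 == 0) 1 else 0, mean_diff = mean(d)))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (equal length >= 3, non-zero variance).
#' @return tibble: `estimate` (r), `df` (`n - 2`), `statistic`, `p.value`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "painpsych_stats_error")
  }
  if (length(x) < 3) abort("need n >= 3.", class = "painpsych_stats_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance input.", class = "painpsych_stats_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(estimate = unname(ct$estimate), df = unname(ct$parameter),
         statistic = unname(ct$statistic), p.value = ct$p.value)
}
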