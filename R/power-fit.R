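#' Fit a Stevens power function in double-log space
#'
#' Three-step procedure: (1) mean ratings and the temperature difference from
#' the 35 degC baseline are converted to natural logs, (2) an ordinary
#' least-squares regression of `log(rating)` on `log(delta)` is performed,
#' (3) the exponent `b` (slope) and proportionality constant `c` (intercept)
#' are extracted. The baseline temperature itself is never fitted
#' (`delta = 0` has no log), and any point with mean rating <= 0 is dropped
#' with a warning (no offset is added, since offsets bias the exponent).
#' The F statistic is the regression F for the slope, with
#' `(1, n_points - 2)` degrees of freedom.
#'
#' @param data data frame of per-temperature mean ratings.
#' @param temperature,rating column names (strings) holding the stimulus level
#'   and the mean rating.
#' @param baseline baseline temperature (degC), excluded from the fit.
#' @param measure optional label (`"intensity"` / `"unpleasantness"`) carried
#'   into the output.
#'
#' @return object of class `power_fit` with elements `exponent`, `constant`,
#'   `statistic` (F), `df1`, `df2`, `p.value`, `r.squared`, `n_points`,
#'   `dropped`.
#' @examples
#' d <- data.frame(temp = 43:49,
#'                 rating = rating_model(43:49, exponent = 3.88, constant = -9.79))
#' fit_power(d, "temp", "rating")
#' @export
fit_power <- function(data, temperature = "stimulus_level", rating = "rating",
                      baseline = 35, measure = NA_character_) {
  temp <- data[[temperature]]
  r <- data[[rating]]
  keep <- temp > baseline
  temp <- temp[keep]; r <- r[keep]
  bad <- r <= 0
  if (any(bad)) {
    warn(sprintf("dropping %d temperature(s) with mean rating <= 0.", sum(bad)))
    temp <- temp[!bad]; r <- r[!bad]
  }
  if (length(r) < 3) {
    abort("need at least 3 temperatures above baseline with positive mean rating.",
          class = "painpsych_power_error")
  }
  lx <- log(temp - baseline)
  ly <- log(r)
  if (var(ly) == 0) {
    # perfectly flat response: slope and F are exactly zero
    return(structure(list(exponent = 0, constant = ly[1], statistic = 0,
                          df1 = 1L, df2 = length(r) - 2L, p.value = 1,
                          r.squared = 0, n_points = length(r),
                          dropped = sum(bad), measure = measure,
                          baseline = baseline,
                          data = tibble(delta = temp - baseline, rating = r)),
                     class = "power_fit"))
  }
  fit <- lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))  # noiseless data trip "perfect fit"
  b <- unname(coef(fit)[2])
  c0 <- unname(coef(fit)[1])
  df2 <- length(r) - 2
  fstat <- if (sm$sigma == 0) {
    if (abs(b) < 1e-12) 0 else Inf
  } else {
    unname(sm$fstatistic[1])
  }
  r2 <- if (is.nan(sm$r.squared)) 0 else sm$r.squared
  p <- if (is.infinite(fstat)) 0 else pf(fstat, 1, df2, lower.tail = FALSE)
  structure(list(exponent = b, constant = c0, statistic = fstat,
                 df1 = 1L, df2 = df2, p.value = p, r.squared = r2,
                 n_points = length(r), dropped = sum(bad),
                 measure = measure, baseline = baseline,
                 data = tibble(delta = temp - baseline, rating = r)),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("<power_fit%s> exponent = %.3f, constant = %.3f, F(%d,%d) = %.2f, p = %.3g, R2 = %.3f\n",
              if (is.na(x$measure)) "" else paste0(": ", x$measure),
              x$exponent, x$constant, x$df1, x$df2, x$statistic, x$p.value,
              x$r.squared))
  invisible(x)
}

#' @describeIn fit_power one-row coefficient table.
#' @param x,object a `power_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.power_fit <- function(x, ...) {
  tibble(measure = x$measure, exponent = x$exponent, constant = x$constant,
         statistic = x$statistic, df1 = x$df1, df2 = x$df2,
         p.value = x$p.value, r.squared = x$r.squared, n_points = x$n_points)
}

#' @describeIn fit_power alias of `tidy()` for a single fit.
#' @exportS3Method generics::glance
glance.power_fit <- function(x, ...) tidy(x)

#' Per-class stimulus-response power fits
#'
#' Computes the class mean rating at each familiarization temperature (mean
#' over participants of per-participant means, for each measure) and fits the
#' power function per class and measure.
#'
#' @param dataset long rating tibble.
#' @param assignments tibble (`participant_id`, `class_label`) from
#'   [label_classes()] (or with ground-truth labels).
#' @param baseline baseline temperature excluded from fits.
#' @return tibble with one row per class x measure (tidied fits).
#' @export
fit_power_by_class <- function(dataset, assignments, baseline = 35) {
  lab_col <- if ("class_label" %in% names(assignments)) "class_label" else "class"
  means <- dataset %>%
    filter(.data$session == "QST", .data$modality == "heat") %>%
    left_join(assignments, by = "participant_id") %>%
    group_by(.data$participant_id, class = .data[[lab_col]], .data$stimulus_level) %>%
    summarise(intensity = mean(.data$intensity_rating),
              unpleasantness = mean(.data$unpleasantness_rating),
              .groups = "drop") %>%
    tidyr::pivot_longer(c("intensity", "unpleasantness"),
                        names_to = "measure", values_to = "rating") %>%
    group_by(.data$class, .data$measure, .data$stimulus_level) %>%
    summarise(rating = mean(.data$rating), .groups = "drop")
  means %>%
    group_by(.data$class, .data$measure) %>%
    tidyr::nest() %>%
    ungroup() %>%
    mutate(fit = map2(.data$data, .data$measure,
                      ~ tidy(fit_power(.x, "stimulus_level", "rating",
                                       baseline = baseline, measure = .y)))) %>%
    select("class", "fit") %>%
    tidyr::unnest("fit")
}

#' Compare exponents and constants between measures
#'
#' For each class, tests the characteristic ordering of the two stimulus
#' -response curves: the unpleasantness exponent exceeds the intensity
#' exponent while its proportionality constant is lower.
#'
#' @param fits tidied per-class fit table from [fit_power_by_class()].
#' @return tibble: `class`, `exponent_greater`, `constant_lower`.
#' @export
compare_exponents <- function(fits) {
  need <- c("intensity", "unpleasantness")
  wide <- fits %>%
    select("class", "measure", "exponent", "constant") %>%
    tidyr::pivot_wider(names_from = "measure",
                       values_from = c("exponent", "constant"))
  for (m in need) {
    if (!paste0("exponent_", m) %in% names(wide)) {
      abort(sprintf("missing fits for measure '%s'.", m),
            class = "painpsych_power_error")
    }
  }
  if (any(!stats::complete.cases(wide))) {
    abort("some classes lack a fit for one measure.",
          class = "painpsych_power_error")
  }
  wide %>%
    mutate(exponent_greater = .data$exponent_unpleasantness > .data$exponent_intensity,
           constant_lower = .data$constant_unpleasantness < .data$constant_intensity) %>%
    select("class", "exponent_greater", "constant_lower")
}

#' Stimulus-response curve plot for a power fit
#'
#' @param object a `power_fit`.
#' @param ... unused.
#' @return a ggplot of mean ratings vs temperature step with the fitted curve.
#' @exportS3Method ggplot2::autoplot
autoplot.power_fit <- function(object, ...) {
  grid <- tibble(delta = seq(min(object$data$delta), max(object$data$delta),
                             length.out = 100))
  grid$rating <- exp(object$exponent * log(grid$delta) + object$constant)
  ggplot(object$data, aes(x = .data$delta, y = .data$rating)) +
    geom_point(size = 2) +
    geom_line(data = grid, colour = "#2c7fb8") +
    labs(x = "temperature step from baseline (degC)", y = "mean VAS rating",
         title = sprintf("b = %.2f, c = %.2f", object$exponent, object$constant)) +
    theme_minimal()
}
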