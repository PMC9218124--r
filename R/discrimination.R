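#' Binarize familiarization trials against a reference temperature
#'
#' For the 43 degC-ascending series each trial at a comparison temperature
#' above 43 degC is coded 1 when its rating strictly exceeds the participant's
#' mean rating at 43 degC; for the 49 degC-descending series, 1 when the
#' rating falls strictly below the mean 49 degC rating. Ties code 0. The
#' innocuous 35 degC baseline is excluded from the comparison set.
#'
#' @param dataset long rating tibble (familiarization trials required).
#' @param reference_temp 43 (ascending) or 49 (descending) degC.
#' @param direction `"ascending"` or `"descending"`.
#' @param measure `"intensity"` or `"unpleasantness"`.
#' @return tibble: `participant_id`, `reference_temp`, `direction`, `measure`,
#'   `reference_rating`, `comparison_temp`, `repetition_index`, `indicator`.
#' @export
binarize_trials <- function(dataset, reference_temp = 43,
                            direction = c("ascending", "descending"),
                            measure = c("intensity", "unpleasantness")) {
  direction <- match.arg(direction)
  measure <- match.arg(measure)
  col <- paste0(measure, "_rating")
  fam <- dataset %>%
    filter(.data$session == "QST", .data$modality == "heat")
  refs <- fam %>%
    filter(.data$stimulus_level == reference_temp) %>%
    group_by(.data$participant_id) %>%
    summarise(reference_rating = mean(.data[[col]]), .groups = "drop")
  if (nrow(refs) == 0) {
    abort(sprintf("no trials at the %g degC reference temperature.", reference_temp),
          class = "painpsych_discrimination_error")
  }
  comp <- if (direction == "ascending") {
    fam %>% filter(.data$stimulus_level > reference_temp)
  } else {
    fam %>% filter(.data$stimulus_level < reference_temp,
                   .data$stimulus_level >= 43)
  }
  comp %>%
    left_join(refs, by = "participant_id") %>%
    mutate(indicator = if (direction == "ascending") {
      as.integer(.data[[col]] > .data$reference_rating)
    } else {
      as.integer(.data[[col]] < .data$reference_rating)
    },
    reference_temp = reference_temp, direction = direction,
    measure = measure) %>%
    select("participant_id", "reference_temp", "direction", "measure",
           "reference_rating", comparison_temp = "stimulus_level",
           "repetition_index", "indicator") %>%
    arrange(.data$participant_id, .data$comparison_temp, .data$repetition_index)
}

#' Rating-based discrimination thresholds
#'
#' Per participant, a logistic regression of the binarized indicator on the
#' comparison temperature (degC) is fitted; the threshold is the temperature at
#' which the fitted probability of a discriminated sensation reaches 0.5,
#' i.e. `-intercept / slope`. Participants who discriminate every trial at
#' every comparison temperature are assigned the conventional edge value half
#' a degree from the reference (43.5 degC ascending, 48.5 degC descending)
#' without a fit, reflecting discrimination finer than the 1 degC grid.
#' Participants who never discriminate are censored half a degree beyond the
#' farthest comparison temperature. If the data are perfectly separated by
#' temperature (logistic MLE undefined) the threshold is the midpoint between
#' the highest all-0 and lowest all-1 temperature. Fitted thresholds are
#' clamped to the attainable range (ascending >= 43.5, descending <= 48.5).
#'
#' @param series binarized tibble from [binarize_trials()] (any number of
#'   participants).
#' @return tibble: one row per participant with `threshold`, `edge_case`
#'   (all-discriminated rule applied), `status` (`"fitted"`,
#'   `"all_discriminated"`, `"none_discriminated"`, `"separated"`),
#'   `intercept`, `slope`.
#' @export
fit_threshold <- function(series) {
  stopifnot(all(c("participant_id", "comparison_temp", "indicator",
                  "direction") %in% names(series)))
  series %>%
    group_by(.data$participant_id, .data$direction, .data$measure,
             .data$reference_temp) %>%
    tidyr::nest() %>%
    ungroup() %>%
    mutate(fit = map2(.data$data, .data$direction, fit_threshold_one)) %>%
    select(-"data") %>%
    tidyr::unnest("fit")
}

fit_threshold_one <- function(d, direction) {
  asc <- direction == "ascending"
  lo <- if (asc) 43.5 else 42.5
  hi <- if (asc) 49.5 else 48.5
  edge_value <- if (asc) 43.5 else 48.5
  censor_value <- if (asc) 49.5 else 42.5
  if (n_distinct(d$comparison_temp) < 2) {
    abort("need >= 2 distinct comparison temperatures.",
          class = "painpsych_discrimination_error")
  }
  out <- tibble(threshold = NA_real_, edge_case = FALSE, status = "fitted",
                intercept = NA_real_, slope = NA_real_, clamped = FALSE)
  if (all(d$indicator == 1)) {
    out$threshold <- edge_value
    out$edge_case <- TRUE
    out$status <- "all_discriminated"
    return(out)
  }
  if (all(d$indicator == 0)) {
    out$threshold <- censor_value
    out$status <- "none_discriminated"
    return(out)
  }
  # perfect separation by temperature: MLE undefined, use the boundary midpoint
  t0 <- d$comparison_temp[d$indicator == 0]
  t1 <- d$comparison_temp[d$indicator == 1]
  separated <- if (asc) max(t0) < min(t1) else max(t1) < min(t0)
  if (separated) {
    out$threshold <- if (asc) (max(t0) + min(t1)) / 2 else (max(t1) + min(t0)) / 2
    out$status <- "separated"
    return(out)
  }
  fit <- suppressWarnings(glm(indicator ~ comparison_temp, binomial(), data = d))
  b0 <- unname(coef(fit)[1]); b1 <- unname(coef(fit)[2])
  out$intercept <- b0; out$slope <- b1
  if (!is.finite(b0) || !is.finite(b1) || b1 == 0) {
    out$threshold <- NA_real_
    out$status <- "no_fit"
    return(out)
  }
  thr <- -b0 / b1
  out$threshold <- min(max(thr, lo), hi)
  out$clamped <- out$threshold != thr
  out
}

#' All four discrimination-threshold series for a cohort
#'
#' Convenience wrapper running [binarize_trials()] + [fit_threshold()] for the
#' ascending (43 degC) and descending (49 degC) directions on both measures.
#'
#' @param dataset long rating tibble.
#' @return tibble of thresholds for every participant x direction x measure.
#' @export
discrimination_thresholds <- function(dataset) {
  grid <- tidyr::crossing(direction = c("ascending", "descending"),
                          measure = c("intensity", "unpleasantness"))
  pmap(grid, function(direction, measure) {
    ref <- if (direction == "ascending") 43 else 49
    binarize_trials(dataset, ref, direction, measure) %>% fit_threshold()
  }) %>% list_rbind()
}

#' Compare discrimination thresholds across sensitivity classes
#'
#' Kruskal-Wallis test plus Dunn post-hoc pairwise comparisons per
#' (direction, measure) series.
#'
#' @param thresholds tibble from [discrimination_thresholds()].
#' @param assignments tibble (`participant_id`, `class_label`).
#' @param adjust p-adjustment method for the Dunn tests.
#' @return tibble with one row per series: KW `statistic`, `df`, `p.value` and
#'   a `dunn` list-column of pairwise results.
#' @export
compare_thresholds <- function(thresholds, assignments, adjust = "bonferroni") {
  lab_col <- if ("class_label" %in% names(assignments)) "class_label" else "class"
  joined <- thresholds %>%
    left_join(assignments, by = "participant_id") %>%
    filter(!is.na(.data$threshold))
  if (any(is.na(joined[[lab_col]]))) {
    abort("every participant must have a class label.",
          class = "painpsych_discrimination_error")
  }
  small <- joined %>% count(.data$direction, .data$measure, .data[[lab_col]])
  if (any(small$n < 2)) {
    abort("each class needs >= 2 members per series.",
          class = "painpsych_discrimination_error")
  }
  joined %>%
    group_by(.data$direction, .data$measure) %>%
    tidyr::nest() %>%
    ungroup() %>%
    mutate(kw = map(.data$data,
                    ~ kruskal_wallis(.x$threshold, .x[[lab_col]])),
           dunn = map(.data$data,
                      ~ dunn_posthoc(.x$threshold, .x[[lab_col]],
                                     adjust = adjust))) %>%
    select(-"data") %>%
    tidyr::unnest("kw")
}

#' Threshold distribution plot by sensitivity class
#'
#' @param thresholds tibble from [discrimination_thresholds()].
#' @param assignments tibble (`participant_id`, `class_label`).
#' @return a ggplot.
#' @export
plot_thresholds <- function(thresholds, assignments) {
  lab_col <- if ("class_label" %in% names(assignments)) "class_label" else "class"
  joined <- left_join(thresholds, assignments, by = "participant_id")
  ggplot(joined, aes(x = .data[[lab_col]], y = .data$threshold,
                     fill = .data[[lab_col]])) +
    geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    facet_grid(direction ~ measure, scales = "free_y") +
    labs(x = "pain-sensitivity class", y = "discrimination threshold (degC)") +
    guides(fill = "none") +
    theme_minimal()
}
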