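#' Build the mixture-model feature matrix
#'
#' One row per participant; features are the mean pain intensity and mean pain
#' unpleasantness rating over the four repetitions at each noxious
#' familiarization temperature (43-49 degC), giving 14 features. The 35 degC
#' baseline is excluded, consistent with its exclusion from all noxious-range
#' analyses.
#'
#' @param dataset long rating tibble as produced by [generate_cohort()] (or
#'   read with [read_ratings()]).
#' @param temperatures familiarization temperatures to use as features.
#' @return tibble: `participant_id` plus `intensity_<temp>` and
#'   `unpleasantness_<temp>` columns.
#' @export
build_feature_matrix <- function(dataset, temperatures = 43:49) {
  fam <- dataset %>%
    filter(.data$session == "QST", .data$modality == "heat",
           .data$stimulus_level %in% temperatures)
  expected <- tidyr::crossing(participant_id = unique(dataset$participant_id),
                              stimulus_level = as.numeric(temperatures))
  missing <- anti_join(expected, fam, by = c("participant_id", "stimulus_level"))
  if (nrow(missing) > 0) {
    abort(paste0("missing familiarization trials: ",
                 paste(sprintf("%s@%g", missing$participant_id,
                               missing$stimulus_level)[seq_len(min(5, nrow(missing)))],
                       collapse = ", "),
                 if (nrow(missing) > 5) " ..."),
          class = "painpsych_features_error")
  }
  fam %>%
    group_by(.data$participant_id, .data$stimulus_level) %>%
    summarise(intensity = mean(.data$intensity_rating),
              unpleasantness = mean(.data$unpleasantness_rating),
              .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "stimulus_level",
                       values_from = c("intensity", "unpleasantness"),
                       names_sep = "_") %>%
    arrange(.data$participant_id)
}

# strip the id column, return numeric matrix with rownames
feature_matrix_values <- function(features) {
  stopifnot("participant_id" %in% names(features))
  m <- as.matrix(features[setdiff(names(features), "participant_id")])
  rownames(m) <- features$participant_id
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) {
    abort("feature matrix contains missing or non-finite entries.",
          class = "painpsych_features_error")
  }
  m
}
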