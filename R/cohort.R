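#' Configure a synthetic cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. Defaults
#' emulate the study conditions: 101 participants split into three latent
#' pain-sensitivity classes (High/Moderate/Low in proportions 23/41/37), the
#' published per-class power-function coefficients, log-scale trial noise, and
#' the full familiarization + scanner trial design. Between-participant
#' heterogeneity is a normal shift of the log-space constant, shared across
#' measures within a modality (a per-person sensitivity trait); it is wide for
#' auditory loudness, where individual ratings vary far more than the class
#' structure explains.
#'
#' @param n_participants cohort size.
#' @param class_proportions named simplex weights over classes (must sum to 1).
#'   Class counts are allocated deterministically by largest remainder, so the
#'   default reproduces counts 23/41/37 at n = 101.
#' @param class_params per-class (exponent, constant) table, see
#'   [default_class_params()].
#' @param rating_noise_sd trial-to-trial noise sd on the log-response scale.
#' @param participant_sd named per-modality sd of the per-participant shift of
#'   the log-space constant.
#' @param n_missing named count of participants with missing scanner data per
#'   modality (dropped from that modality's MRI trials only).
#' @param trial_design stimulus grid, see [default_trial_design()].
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#'
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 101,
                          class_proportions = c(High = 23, Moderate = 41, Low = 37) / 101,
                          class_params = default_class_params(),
                          rating_noise_sd = 0.15,
                          participant_sd = c(heat = 0, cold = 0.3, auditory = 1.0),
                          n_missing = c(heat = 0L, cold = 28L, auditory = 4L),
                          trial_design = default_trial_design(),
                          seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-12) {
    abort("`class_proportions` must sum to 1.", class = "painpsych_config_error")
  }
  if (any(class_proportions < 0)) {
    abort("`class_proportions` must be non-negative.", class = "painpsych_config_error")
  }
  if (rating_noise_sd < 0) {
    abort("`rating_noise_sd` must be >= 0.", class = "painpsych_config_error")
  }
  if (any(trial_design$n_reps < 1)) {
    abort("all repetition counts must be >= 1.", class = "painpsych_config_error")
  }
  missing_classes <- setdiff(names(class_proportions), unique(class_params$class))
  if (length(missing_classes)) {
    abort(paste0("no parameters for class: ", paste(missing_classes, collapse = ", ")),
          class = "painpsych_config_error")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      class_proportions = class_proportions,
      class_params = class_params,
      rating_noise_sd = rating_noise_sd,
      participant_sd = participant_sd,
      n_missing = n_missing,
      trial_design = trial_design,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# deterministic largest-remainder allocation of n into counts ~ proportions
allocate_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic rating cohort with ground truth
#'
#' Draws a cohort under the configured latent class structure. Each trial's
#' noiseless mean comes from [rating_model()] with the participant's class
#' coefficients (plus the per-participant constant shift); multiplicative noise
#' is applied as `exp(log(mu + eps) + N(0, sd)) - eps` with `eps = 0.01`, then
#' clipped to the VAS range, preserving the power-law structure in double-log
#' space.
#'
#' @param config a [cohort_config()].
#' @return list with elements
#'   * `ratings`: long tibble (`participant_id`, `session`, `modality`,
#'     `stimulus_level`, `condition`, `repetition_index`, `intensity_rating`,
#'     `unpleasantness_rating`),
#'   * `truth`: ground truth (per-participant class labels, true coefficient
#'     pairs, true noiseless mean rating per stimulus level, scanner-modality
#'     availability).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 12, seed = 7))
#' dplyr::count(cohort$truth$participants, class)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  eps <- 0.01
  n <- config$n_participants

  counts <- allocate_counts(n, config$class_proportions)
  participants <- tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    class = rep(names(config$class_proportions), counts)
  )

  # per-participant, per-modality shift of the log-space constant
  modalities <- unique(config$class_params$modality)
  shifts <- tidyr::crossing(participant_id = participants$participant_id,
                            modality = modalities) %>%
    mutate(shift = rnorm(n(), 0,
                         unname(config$participant_sd[.data$modality])))

  params <- participants %>%
    left_join(config$class_params, by = "class",
              relationship = "many-to-many") %>%
    left_join(shifts, by = c("participant_id", "modality")) %>%
    mutate(constant = .data$constant + .data$shift) %>%
    select(-"shift")

  # scanner-modality availability
  for (m in names(config$n_missing)) {
    nm <- min(config$n_missing[[m]], n)
    miss <- if (nm > 0) sample(participants$participant_id, nm) else character()
    participants[[paste0("has_", m)]] <- !(participants$participant_id %in% miss)
  }

  trials <- tidyr::crossing(participant_id = participants$participant_id,
                            config$trial_design) %>%
    tidyr::uncount(.data$n_reps, .id = "repetition_index") %>%
    left_join(tidyr::pivot_wider(params,
                                 names_from = "measure",
                                 values_from = c("exponent", "constant")),
              by = c("participant_id", "modality")) %>%
    mutate(
      delta = if_else(.data$modality == "cold",
                      .data$baseline - .data$stimulus_level,
                      .data$stimulus_level - .data$baseline),
      mu_intensity = power_mu(.data$delta, .data$exponent_intensity,
                              .data$constant_intensity),
      mu_unpleasantness = power_mu(.data$delta, .data$exponent_unpleasantness,
                                   .data$constant_unpleasantness)
    )

  noisy <- function(mu) {
    out <- exp(log(mu + eps) + rnorm(length(mu), 0, config$rating_noise_sd)) - eps
    pmin(pmax(out, 0), 10)
  }
  trials$intensity_rating <- noisy(trials$mu_intensity)
  trials$unpleasantness_rating <- noisy(trials$mu_unpleasantness)

  # drop scanner trials for participants with missing modality data
  for (m in names(config$n_missing)) {
    keep_ids <- participants$participant_id[participants[[paste0("has_", m)]]]
    trials <- trials %>%
      filter(!(.data$session == "MRI" & .data$modality == m &
                 !(.data$participant_id %in% keep_ids)))
  }

  ratings <- trials %>%
    select("participant_id", "session", "modality", "stimulus_level",
           "condition", "repetition_index",
           "intensity_rating", "unpleasantness_rating") %>%
    arrange(.data$participant_id, .data$session, .data$modality,
            .data$stimulus_level, .data$repetition_index)

  # true (noiseless) mean ratings per participant x level
  true_means <- trials %>%
    distinct(.data$participant_id, .data$session, .data$modality,
             .data$stimulus_level, .data$condition,
             .data$mu_intensity, .data$mu_unpleasantness) %>%
    rename(true_intensity = "mu_intensity",
           true_unpleasantness = "mu_unpleasantness")

  truth <- structure(
    list(participants = participants, params = params,
         true_means = true_means, config = config),
    class = "synthetic_truth"
  )
  list(ratings = ratings, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$participants), " participants; classes: ",
      paste(sprintf("%s=%d", names(table(x$participants$class)),
                    as.integer(table(x$participants$class))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
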