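#' Configure a full pipeline run
#'
#' Bundles the cohort configuration, the brain-coupling regime per scanner
#' modality (heat/cold dissociated, auditory coupled by default, reproducing
#' the study's empirical pattern), and the statistical defaults.
#'
#' @param cohort a [cohort_config()].
#' @param regimes named character vector: regime per modality.
#' @param z_thresh cluster-forming z threshold.
#' @param alpha cluster-level alpha.
#' @param k_folds,n_repeats LASSO-PCR cross-validation geometry.
#' @param n_perm cluster-inference permutations.
#' @param n_boot bootstrap samples for weight inference (0 disables).
#' @param noise_sd,gain_high,gain_low,grid_dim beta-map generator settings.
#' @param seed master seed for the whole run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            regimes = c(heat = "dissociated",
                                        cold = "dissociated",
                                        auditory = "coupled"),
                            z_thresh = 3.1, alpha = 0.05,
                            k_folds = 5, n_repeats = 5,
                            n_perm = 1000, n_boot = 0,
                            noise_sd = 1, gain_high = 0.5, gain_low = 0.25,
                            grid_dim = c(16, 16, 16), seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (!all(regimes %in% c("dissociated", "coupled"))) {
    abort("regimes must be 'dissociated' or 'coupled'.",
          class = "painpsych_config_error")
  }
  if (k_folds > cohort$n_participants) {
    abort("`k_folds` cannot exceed the number of participants.",
          class = "painpsych_config_error")
  }
  structure(list(cohort = cohort, regimes = regimes, z_thresh = z_thresh,
                 alpha = alpha, k_folds = k_folds, n_repeats = n_repeats,
                 n_perm = n_perm, n_boot = n_boot, noise_sd = noise_sd,
                 gain_high = gain_high, gain_low = gain_low,
                 grid_dim = grid_dim, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] and [cohort_config()]
#' arguments (`n_participants`, `rating_noise_sd`, `regimes`, `z_thresh`,
#' `alpha`, `k_folds`, `n_repeats`, `n_perm`, `n_boot`, `seed`, ...).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y[intersect(names(y),
                             c("n_participants", "rating_noise_sd", "seed"))]
  if (!is.null(y$class_proportions)) {
    cohort_args$class_proportions <- unlist(y$class_proportions)
  }
  cohort <- do.call(cohort_config, cohort_args)
  args <- y[intersect(names(y), c("z_thresh", "alpha", "k_folds", "n_repeats",
                                  "n_perm", "n_boot", "noise_sd", "gain_high",
                                  "gain_low", "seed"))]
  if (!is.null(y$regimes)) args$regimes <- unlist(y$regimes)
  if (!is.null(y$grid_dim)) args$grid_dim <- as.integer(unlist(y$grid_dim))
  args$cohort <- cohort
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> classify -> power fits -> discrimination thresholds ->
#' per-modality brain analyses (paired high-vs-low contrast, rating-covariate
#' GLM with permutation cluster inference, LASSO-PCR; plus signature
#' expression for heat) -> findings. Participants missing a modality are
#' dropped from that modality's analyses only, with logged counts. All
#' outputs are written under `out_dir` and the findings JSON states, per
#' modality, whether a rating-activation relationship was detected.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return the findings list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("painpsych_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("simulating cohort (n = %d, seed = %d)", config$cohort$n_participants,
      config$seed)
  cohort <- generate_cohort(config$cohort)
  write_ratings(cohort$ratings, file.path(out_dir, "ratings.csv"))
  jsonlite::write_json(
    list(participants = cohort$truth$participants,
         params = cohort$truth$params),
    file.path(out_dir, "truth.json"))

  say("classifying participants (mixture models k = 1..5)")
  features <- build_feature_matrix(cohort$ratings)
  models <- map(1:5, ~ fit_mixture(features, .x, seed = config$seed + .x))
  chosen <- select_model(models)
  assignments <- label_classes(chosen)
  readr::write_csv(assignments, file.path(out_dir, "class_assignments.csv"))
  jsonlite::write_json(attr(chosen, "selection"),
                       file.path(out_dir, "model_selection.json"))

  say("fitting power functions per class")
  power_table <- fit_power_by_class(cohort$ratings, assignments)
  readr::write_csv(power_table, file.path(out_dir, "power_fits.csv"))

  say("computing discrimination thresholds")
  thresholds <- discrimination_thresholds(cohort$ratings)
  readr::write_csv(thresholds %>% select(-dplyr::any_of("clamped")),
                   file.path(out_dir, "thresholds.csv"))
  threshold_tests <- compare_thresholds(thresholds, assignments)
  jsonlite::write_json(
    threshold_tests %>% mutate(dunn = map(.data$dunn, as.list)),
    file.path(out_dir, "threshold_comparisons.json"))

  findings <- list(seed = config$seed, modalities = list())
  for (m in names(config$regimes)) {
    say("brain analyses: %s (%s regime)", m, config$regimes[[m]])
    maps <- generate_beta_maps(cohort$truth, modality = m,
                               regime = config$regimes[[m]],
                               noise_sd = config$noise_sd,
                               grid_dim = config$grid_dim,
                               seed = config$seed + match(m, names(config$regimes)),
                               gain_high = config$gain_high,
                               gain_low = config$gain_low)
    say("  %d subjects in, %d dropped (missing %s data)",
        length(maps$subjects),
        config$cohort$n_participants - length(maps$subjects), m)
    obs_ratings <- cohort$ratings %>%
      filter(.data$session == "MRI", .data$modality == m,
             .data$condition == "high") %>%
      group_by(.data$participant_id) %>%
      summarise(rating = mean(.data$intensity_rating), .groups = "drop")

    contrast <- paired_contrast(maps, z_thresh = config$z_thresh,
                                alpha = config$alpha, n_perm = config$n_perm,
                                seed = config$seed)
    glm_res <- fit_covariate_glm(maps, obs_ratings,
                                 z_thresh = config$z_thresh,
                                 alpha = config$alpha, n_perm = config$n_perm,
                                 seed = config$seed)
    readr::write_csv(tidy(glm_res),
                     file.path(out_dir, sprintf("covariate_clusters_%s.csv", m)))
    readr::write_csv(tidy(contrast),
                     file.path(out_dir, sprintf("stimulation_clusters_%s.csv", m)))
    write_z_map(glm_res$z, maps$mask,
                file.path(out_dir, sprintf("covariate_z_%s.nii.gz", m)))

    lasso <- lasso_pcr_fit(maps, obs_ratings, k_folds = config$k_folds,
                           n_repeats = config$n_repeats, seed = config$seed)

    sig_tests <- NULL
    if (m == "heat") {
      sig <- synthetic_signature(maps)
      eh <- signature_expression(maps, sig, "high")
      el <- signature_expression(maps, sig, "low")
      sig_tests <- expression_tests(eh, el, obs_ratings)
    }

    n_cov <- if (config$n_perm > 0) sum(glm_res$clusters$clusters$significant)
             else nrow(glm_res$clusters$clusters)
    findings$modalities[[m]] <- list(
      regime = unname(config$regimes[[m]]),
      n_subjects = length(maps$subjects),
      stimulation_clusters = if (config$n_perm > 0)
        sum(contrast$clusters$clusters$significant)
      else nrow(contrast$clusters$clusters),
      covariate_clusters = n_cov,
      rating_relationship_detected = n_cov > 0,
      lasso_r = lasso$r, lasso_rmse = lasso$rmse,
      signature = if (!is.null(sig_tests)) list(
        paired_t = sig_tests$paired$statistic,
        paired_df = sig_tests$paired$df,
        correlation_r = sig_tests$correlation$estimate,
        correlation_df = sig_tests$correlation$df
      )
    )
  }

  jsonlite::write_json(findings, file.path(out_dir, "findings.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done; outputs in %s", out_dir)
  invisible(findings)
}
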