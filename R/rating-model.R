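#' Stevens power-function rating model
#'
#' Deterministic stimulus-response model underlying the synthetic cohort:
#' a VAS rating is `exp(b * log(delta) + c)` where `delta` is the distance of
#' the stimulus from a modality-specific innocuous baseline, `b` is the
#' power-function exponent and `c` the log-space proportionality constant.
#' Ratings are clipped to the VAS range \[0, 10\]. At or below the baseline
#' (`delta <= 0`) the rating is defined as 0: the baseline stimulus evokes no
#' painful (or loud) sensation and is excluded from all curve fits.
#'
#' For heat `delta = stimulus_level - baseline` (baseline 35 degC); for cold
#' the gradient is reversed, `delta = baseline - stimulus_level`; auditory
#' stimuli use dB re a quiet baseline (default 70 dB).
#'
#' @param stimulus_level numeric vector of stimulus levels (degC or dB).
#' @param baseline innocuous reference level (same units).
#' @param exponent power-function exponent `b` (dimensionless).
#' @param constant log-space proportionality constant `c`.
#' @param modality one of `"heat"`, `"cold"`, `"auditory"`; controls the sign
#'   of the baseline offset.
#'
#' @return numeric vector of noiseless VAS ratings in \[0, 10\].
#' @examples
#' rating_model(48, exponent = 2.93, constant = -5.49) # high-sensitivity 48 degC
#' rating_model(43:49, exponent = 3.88, constant = -9.79)
#' @export
rating_model <- function(stimulus_level, baseline = 35, exponent, constant,
                         modality = c("heat", "cold", "auditory")) {
  modality <- match.arg(modality)
  delta <- if (modality == "cold") baseline - stimulus_level else stimulus_level - baseline
  out <- ifelse(delta <= 0, 0, exp(exponent * log(pmax(delta, .Machine$double.xmin)) + constant))
  pmin(pmax(out, 0), 10)
}

# vectorized power-law mean on the baseline-offset scale (delta may vary by row)
power_mu <- function(delta, exponent, constant) {
  out <- ifelse(delta <= 0, 0,
                exp(exponent * log(pmax(delta, .Machine$double.xmin)) + constant))
  pmin(pmax(out, 0), 10)
}

#' Default per-class power-function parameters
#'
#' Exponent/constant pairs for the three latent pain-sensitivity classes
#' (High, Moderate, Low) used by the synthetic generator. Heat parameters are
#' the published class stimulus-response coefficients; cold parameters are
#' analogous class-specific defaults; auditory loudness is modelled as
#' independent of pain-sensitivity class (identical coefficients for all
#' classes, with wide between-participant variation supplied separately).
#' In every class the unpleasantness exponent exceeds the intensity exponent
#' and its constant is lower, reproducing the characteristic ordering of the
#' two measures.
#'
#' @return tibble with columns `class`, `modality`, `measure`, `exponent`,
#'   `constant`, `baseline`.
#' @export
default_class_params <- function() {
  heat <- tibble(
    class = rep(c("High", "Moderate", "Low"), each = 2),
    modality = "heat",
    measure = rep(c("intensity", "unpleasantness"), 3),
    exponent = c(2.93, 3.45, 4.46, 5.12, 3.88, 4.74),
    constant = c(-5.49, -6.88, -10.02, -11.84, -9.79, -12.1),
    baseline = 35
  )
  cold <- tibble(
    class = rep(c("High", "Moderate", "Low"), each = 2),
    modality = "cold",
    measure = rep(c("intensity", "unpleasantness"), 3),
    exponent = c(2.0, 2.3, 2.2, 2.5, 2.4, 2.7),
    constant = c(-5.70, -6.50, -6.87, -7.67, -8.32, -9.12),
    baseline = 35
  )
  auditory <- tibble(
    class = rep(c("High", "Moderate", "Low"), each = 2),
    modality = "auditory",
    measure = rep(c("intensity", "unpleasantness"), 3),
    exponent = rep(c(1.5, 1.7), 3),
    constant = rep(c(-4.49, -5.30), 3),
    baseline = 70
  )
  bind_rows(heat, cold, auditory)
}

#' Default trial design
#'
#' The stimulus grid of the emulated study: a familiarization series of eight
#' temperatures (35, 43-49 degC) with four repetitions each (QST session), and
#' the scanner tasks -- heat 17 x 48 degC high / 4 x 47 degC low, cold
#' 4 x 0.5 degC high / 1 x 3 degC low, auditory 5 x 90 dB high / 2 x 80 dB low.
#'
#' @return tibble with columns `session`, `modality`, `stimulus_level`,
#'   `condition`, `n_reps`.
#' @export
default_trial_design <- function() {
  bind_rows(
    tibble(session = "QST", modality = "heat",
           stimulus_level = c(35, 43:49), condition = "familiarization", n_reps = 4L),
    tibble(session = "MRI", modality = "heat",
           stimulus_level = c(48, 47), condition = c("high", "low"), n_reps = c(17L, 4L)),
    tibble(session = "MRI", modality = "cold",
           stimulus_level = c(0.5, 3), condition = c("high", "low"), n_reps = c(4L, 1L)),
    tibble(session = "MRI", modality = "auditory",
           stimulus_level = c(90, 80), condition = c("high", "low"), n_reps = c(5L, 2L))
  )
}
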