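# shared fixture builders -- everything generated in code at test time

# small familiarization-only rating table with fully controlled ratings
make_familiarization <- function(participants, temps = c(35, 43:49), reps = 4,
                                 rating_fun) {
  grid <- expand.grid(participant_id = participants,
                      stimulus_level = temps,
                      repetition_index = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- rating_fun(grid)
  tibble::tibble(
    participant_id = grid$participant_id,
    session = "QST", modality = "heat",
    stimulus_level = grid$stimulus_level,
    condition = "familiarization",
    repetition_index = as.integer(grid$repetition_index),
    intensity_rating = r, unpleasantness_rating = r
  )
}

# beta_map_set built directly from matrices on a small grid
make_bms <- function(high, low = NULL, dim = c(8, 8, 8), mask = NULL,
                     subjects = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim)
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_len(nrow(high)))
  maps <- list(high = high)
  if (!is.null(low)) maps$low <- low
  beta_map_set(maps, mask, subjects)
}

# per-subject mean observed rating of the scanner task's high condition
mri_high_ratings <- function(ratings, mod = "heat") {
  ratings |>
    dplyr::filter(session == "MRI", modality == mod, condition == "high") |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(rating = mean(intensity_rating), .groups = "drop")
}

# subject maps of spatially smooth pure noise (for cluster-inference nulls)
smooth_noise_maps <- function(n_subj, mask, sigma = 1.5) {
  dm <- dim(mask)
  t(vapply(seq_len(n_subj), function(i) {
    v <- smooth_volume_3d(array(rnorm(prod(dm)), dm), sigma)
    v[mask]
  }, numeric(sum(mask))))
}

# adjusted Rand index between two labelings (closed form from the
# contingency table; independent of any clustering package)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  row_c <- sum_comb(rowSums(tab)); col_c <- sum_comb(colSums(tab))
  expected <- row_c * col_c / choose(n, 2)
  max_idx <- (row_c + col_c) / 2
  if (max_idx == expected) return(1)
  (idx - expected) / (max_idx - expected)
}
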