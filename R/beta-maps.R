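#' Beta-map container
#'
#' Holds per-subject voxelwise contrast amplitudes for the high- and
#' low-intensity conditions of one modality, as subjects x in-mask-voxel
#' matrices tied to a 3-D grid and binary mask.
#'
#' @param maps named list of numeric matrices (`high`, `low`), one row per
#'   subject, one column per in-mask voxel.
#' @param mask 3-D logical array; `sum(mask)` must equal the column count.
#' @param subjects character vector of subject ids (row order).
#' @param vox_mm voxel size metadata (mm).
#' @param truth optional list describing planted effects (ground truth).
#'
#' @return object of class `beta_map_set`.
#' @export
beta_map_set <- function(maps, mask, subjects, vox_mm = c(3, 3, 3), truth = NULL) {
  stopifnot(is.list(maps), is.array(mask), is.logical(mask))
  nvox <- sum(mask)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!is.matrix(m) || ncol(m) != nvox) {
      abort(sprintf("map '%s' must be a matrix with %d columns (in-mask voxels).",
                    nm, nvox), class = "painpsych_maps_error")
    }
    if (nrow(m) != length(subjects)) {
      abort(sprintf("map '%s' row count does not match subject count.", nm),
            class = "painpsych_maps_error")
    }
    if (any(!is.finite(m))) {
      abort(sprintf("map '%s' contains non-finite entries.", nm),
            class = "painpsych_maps_error")
    }
  }
  structure(list(maps = maps, mask = mask, dim = dim(mask),
                 subjects = subjects, vox_mm = vox_mm, truth = truth),
            class = "beta_map_set")
}

#' @export
print.beta_map_set <- function(x, ...) {
  cat(sprintf("<beta_map_set> %d subjects, grid %s, %d in-mask voxels, conditions: %s\n",
              length(x$subjects), paste(x$dim, collapse = "x"),
              sum(x$mask), paste(names(x$maps), collapse = ", ")))
  invisible(x)
}

#' Ellipsoidal analysis mask
#'
#' @param dim 3-D grid dimensions.
#' @param radius_frac semi-axes as a fraction of half the grid extent.
#' @return 3-D logical array.
#' @export
ellipsoid_mask <- function(dim = c(16, 16, 16), radius_frac = 0.8) {
  ctr <- (dim + 1) / 2
  semi <- radius_frac * (dim - 1) / 2
  idx <- expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]), k = seq_len(dim[3]))
  d2 <- ((idx$i - ctr[1]) / semi[1])^2 + ((idx$j - ctr[2]) / semi[2])^2 +
    ((idx$k - ctr[3]) / semi[3])^2
  array(d2 <= 1, dim)
}

# central cube of planted-effect voxels, returned as indices into in-mask voxels
effect_blob <- function(mask, size = 4) {
  dm <- dim(mask)
  ctr <- floor((dm + 1) / 2)
  half <- floor(size / 2)
  rng <- function(c, d) seq(max(1, c - half + 1), min(d, c - half + size))
  blob <- array(FALSE, dm)
  blob[rng(ctr[1], dm[1]), rng(ctr[2], dm[2]), rng(ctr[3], dm[3])] <- TRUE
  blob <- blob & mask
  which(blob[mask])
}

#' Generate synthetic voxelwise beta maps
#'
#' Plants a contiguous effect blob inside an ellipsoidal mask and adds
#' i.i.d. Gaussian voxel noise. Both conditions of a modality receive a
#' planted amplitude `gain * s_p` at the effect voxels, with
#' `gain_high > gain_low` so the high-intensity maps always carry the larger
#' signal. The participant scaling `s_p` encodes the regime:
#' * `"coupled"`: `s_p` is the participant's true mean high-intensity rating,
#'   so between-individual activation tracks perception;
#' * `"dissociated"`: `s_p` is a constant (`reference_rating`), so
#'   within-individual stimulus effects exist but between-individual
#'   activation is unrelated to ratings.
#'
#' @param truth `synthetic_truth` from [generate_cohort()].
#' @param modality which scanner task to simulate maps for.
#' @param regime `"dissociated"` or `"coupled"`.
#' @param noise_sd voxel noise sd (contrast units).
#' @param grid_dim 3-D grid dimensions.
#' @param seed integer seed.
#' @param gain_high,gain_low planted gain (contrast units per VAS unit) for the
#'   high/low condition.
#' @param reference_rating constant scaling used in the dissociated regime
#'   (VAS units; matches a typical cohort mean rating).
#' @param blob_size edge length of the cubic effect blob.
#'
#' @return a [beta_map_set()] with conditions `high` and `low`; its `truth`
#'   element records the planted voxel indices and per-subject amplitudes.
#' @export
generate_beta_maps <- function(truth, modality = "heat",
                               regime = c("dissociated", "coupled"),
                               noise_sd = 1, grid_dim = c(16, 16, 16),
                               seed = 1L, gain_high = 0.5, gain_low = 0.25,
                               reference_rating = 4, blob_size = 4) {
  stopifnot(inherits(truth, "synthetic_truth"))
  regime <- match.arg(regime)
  if (gain_high <= gain_low) {
    abort("`gain_high` must exceed `gain_low`.", class = "painpsych_maps_error")
  }
  mask <- ellipsoid_mask(grid_dim)
  if (!any(mask)) abort("empty mask.", class = "painpsych_maps_error")
  nvox <- sum(mask)
  effect <- effect_blob(mask, blob_size)

  has <- truth$participants[[paste0("has_", modality)]]
  if (is.null(has)) has <- rep(TRUE, nrow(truth$participants))
  subjects <- truth$participants$participant_id[has]

  ratings <- truth$true_means %>%
    filter(.data$session == "MRI", .data$modality == !!modality,
           .data$condition == "high",
           .data$participant_id %in% subjects) %>%
    arrange(match(.data$participant_id, subjects)) %>%
    pull("true_intensity")
  if (length(ratings) != length(subjects)) {
    abort("truth lacks scanner-task mean ratings for this modality.",
          class = "painpsych_maps_error")
  }

  s <- if (regime == "coupled") ratings else rep(reference_rating, length(subjects))
  set.seed(seed)
  n <- length(subjects)
  build <- function(gain) {
    m <- matrix(rnorm(n * nvox, 0, noise_sd), n, nvox)
    m[, effect] <- m[, effect] + outer(gain * s, rep(1, length(effect)))
    rownames(m) <- subjects
    m
  }
  maps <- list(high = build(gain_high), low = build(gain_low))
  beta_map_set(maps, mask, subjects,
               truth = list(regime = regime, effect_voxels = effect,
                            amplitude_high = gain_high * s,
                            amplitude_low = gain_low * s,
                            scaling = s, noise_sd = noise_sd))
}
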