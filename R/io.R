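#' Read and write rating datasets as CSV
#'
#' The on-disk format is the long trial table with exactly the columns
#' `participant_id, session, modality, stimulus_level, condition,
#' repetition_index, intensity_rating, unpleasantness_rating`.
#'
#' @param dataset rating tibble.
#' @param path CSV file path.
#' @return `read_ratings()` returns the tibble; `write_ratings()` its path,
#'   invisibly.
#' @export
write_ratings <- function(dataset, path) {
  req <- rating_columns()
  missing <- setdiff(req, names(dataset))
  if (length(missing)) {
    abort(paste0("dataset lacks column(s): ", paste(missing, collapse = ", ")),
          class = "painpsych_io_error")
  }
  readr::write_csv(dataset[req], path)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(rating_columns(), names(d))
  if (length(missing)) {
    abort(paste0("malformed ratings CSV; missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "painpsych_io_error")
  }
  d$repetition_index <- as.integer(d$repetition_index)
  bad <- d$intensity_rating < 0 | d$intensity_rating > 10 |
    d$unpleasantness_rating < 0 | d$unpleasantness_rating > 10
  if (any(bad, na.rm = TRUE)) {
    abort("ratings outside the VAS range [0, 10].", class = "painpsych_io_error")
  }
  d
}

rating_columns <- function() {
  c("participant_id", "session", "modality", "stimulus_level", "condition",
    "repetition_index", "intensity_rating", "unpleasantness_rating")
}

#' Read and write beta-map sets as NIfTI
#'
#' Each condition is one 4-D NIfTI volume with subjects along the 4th axis;
#' the binary mask is a 3-D volume beside them. Subject ids travel in a small
#' JSON sidecar.
#'
#' @param maps a [beta_map_set()].
#' @param prefix path prefix; files `<prefix>_<condition>.nii.gz`,
#'   `<prefix>_mask.nii.gz` and `<prefix>_subjects.json` are written.
#' @return `read_beta_maps()` returns the [beta_map_set()];
#'   `write_beta_maps()` the prefix, invisibly.
#' @export
write_beta_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "beta_map_set"))
  dm <- maps$dim
  for (cond in names(maps$maps)) {
    vol <- array(0, c(dm, length(maps$subjects)))
    flat <- array(0, dm)
    for (s in seq_along(maps$subjects)) {
      flat[maps$mask] <- maps$maps[[cond]][s, ]
      vol[, , , s] <- flat
    }
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(maps$vox_mm, 1)),
                       paste0(prefix, "_", cond, ".nii.gz"))
  }
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(maps$mask), dm),
                                     pixdim = maps$vox_mm),
                     paste0(prefix, "_mask.nii.gz"))
  jsonlite::write_json(list(subjects = maps$subjects,
                            conditions = names(maps$maps)),
                       paste0(prefix, "_subjects.json"))
  invisible(prefix)
}

#' @rdname write_beta_maps
#' @export
read_beta_maps <- function(prefix) {
  meta_path <- paste0(prefix, "_subjects.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("no sidecar '%s'.", meta_path), class = "painpsych_io_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  mask_img <- tryCatch(RNifti::readNifti(paste0(prefix, "_mask.nii.gz")),
                       error = function(e) {
                         abort(sprintf("cannot read mask NIfTI: %s", conditionMessage(e)),
                               class = "painpsych_io_error")
                       })
  mask <- array(as.vector(mask_img) > 0.5, dim(mask_img))
  vox_mm <- attr(mask_img, "pixdim")[1:3] %||% c(3, 3, 3)
  maps <- list()
  for (cond in meta$conditions) {
    img <- tryCatch(RNifti::readNifti(paste0(prefix, "_", cond, ".nii.gz")),
                    error = function(e) {
                      abort(sprintf("cannot read '%s' NIfTI: %s", cond,
                                    conditionMessage(e)),
                            class = "painpsych_io_error")
                    })
    arr <- as.array(img)
    n <- dim(arr)[4]
    m <- matrix(NA_real_, n, sum(mask))
    for (s in seq_len(n)) {
      frame <- arr[, , , s]
      m[s, ] <- frame[mask]
    }
    rownames(m) <- meta$subjects
    maps[[cond]] <- m
  }
  beta_map_set(maps, mask, meta$subjects, vox_mm = vox_mm)
}

#' Write a z map (in-mask values) as a 3-D NIfTI volume
#'
#' @param z numeric vector over in-mask voxels.
#' @param mask 3-D logical array.
#' @param path output NIfTI path.
#' @export
write_z_map <- function(z, mask, path) {
  vol <- array(0, dim(mask))
  vol[mask] <- z
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
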