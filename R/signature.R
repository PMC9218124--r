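#' Synthetic signature weight map
#'
#' Builds a signature aligned with the planted effect blob of a synthetic
#' [beta_map_set()]: unit weights at the planted voxels, zero elsewhere, with
#' the signature mask restricted to the blob. Stands in for an empirically
#' trained pain-signature pattern in simulations; it is synthetic and carries
#' no published weights.
#'
#' @param maps a synthetic [beta_map_set()] whose `truth` records the planted
#'   voxels.
#' @return object of class `signature_weights`: `weights` (numeric, one per
#'   in-mask voxel), `sig_mask` (logical, voxels belonging to the signature),
#'   `dim` (grid).
#' @export
synthetic_signature <- function(maps) {
  stopifnot(inherits(maps, "beta_map_set"))
  if (is.null(maps$truth$effect_voxels)) {
    abort("maps carry no planted-effect ground truth.", class = "painpsych_sig_error")
  }
  nvox <- sum(maps$mask)
  w <- numeric(nvox)
  w[maps$truth$effect_voxels] <- 1
  signature_weights(w, seq_len(nvox) %in% maps$truth$effect_voxels, dim(maps$mask))
}

#' @rdname synthetic_signature
#' @param weights numeric voxel weights (length = in-mask voxel count).
#' @param sig_mask logical vector marking the voxels included in the original
#'   signature definition.
#' @param dim grid dimensions the weights live on.
#' @export
signature_weights <- function(weights, sig_mask = rep(TRUE, length(weights)),
                              dim = NULL) {
  stopifnot(length(weights) == length(sig_mask), all(is.finite(weights)))
  structure(list(weights = as.numeric(weights), sig_mask = as.logical(sig_mask),
                 dim = dim),
            class = "signature_weights")
}

#' Signature expression: dot product of a beta map with a weight pattern
#'
#' For each subject, the scalar expression is the sum over signature-mask
#' voxels of `beta * weight`. Only voxels included in the signature definition
#' contribute.
#'
#' @param maps a [beta_map_set()].
#' @param weights a [signature_weights()] on the same grid.
#' @param condition which condition's maps to score.
#' @return tibble: `participant_id`, `condition`, `expression`.
#' @export
signature_expression <- function(maps, weights, condition = "high") {
  stopifnot(inherits(maps, "beta_map_set"), inherits(weights, "signature_weights"))
  if (length(weights$weights) != sum(maps$mask)) {
    abort("signature and maps are on different grids.", class = "painpsych_sig_error")
  }
  if (!is.null(weights$dim) && !identical(as.integer(weights$dim),
                                          as.integer(dim(maps$mask)))) {
    abort("signature and maps are on different grids.", class = "painpsych_sig_error")
  }
  Y <- maps$maps[[condition]]
  if (is.null(Y)) abort(sprintf("no '%s' condition in maps.", condition),
                        class = "painpsych_sig_error")
  w <- ifelse(weights$sig_mask, weights$weights, 0)
  tibble(participant_id = maps$subjects, condition = condition,
         expression = as.numeric(Y %*% w))
}

#' Within- and between-individual signature-expression tests
#'
#' Paired t test of the per-subject expression between the high- and
#' low-intensity conditions (df `n - 1`), and Pearson correlation of the
#' high-intensity expression with the per-subject mean rating (df `n - 2`).
#'
#' @param expr_high,expr_low expression tibbles from [signature_expression()]
#'   (matched subjects) or numeric vectors.
#' @param ratings per-subject mean ratings (vector aligned with the
#'   expression subjects, or data frame with `participant_id`, `rating`).
#' @return list with tibbles `paired` and `correlation`.
#' @export
expression_tests <- function(expr_high, expr_low, ratings) {
  if (is.data.frame(expr_high)) {
    if (is.data.frame(expr_low) &&
        !identical(expr_high$participant_id, expr_low$participant_id)) {
      abort("subject sets must match between conditions.",
            class = "painpsych_sig_error")
    }
    subjects <- expr_high$participant_id
    eh <- expr_high$expression
    el <- if (is.data.frame(expr_low)) expr_low$expression else expr_low
  } else {
    subjects <- NULL
    eh <- expr_high; el <- expr_low
  }
  if (length(eh) != length(el)) {
    abort("expression vectors must have equal length.", class = "painpsych_sig_error")
  }
  x <- if (is.null(subjects)) align_ratings(ratings, seq_along(eh))
       else align_ratings(ratings, subjects)
  list(paired = paired_t(eh, el), correlation = pearson_r(eh, x))
}
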