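#' Label connected components in a 3-D binary array
#'
#' Face (6-) connectivity flood fill; the most conservative standard
#' neighbourhood, so reported cluster sizes are reproducible.
#'
#' @param x 3-D logical array.
#' @return integer array of the same shape; 0 = background, 1..K = clusters.
#' @export
label_clusters_3d <- function(x) {
  dm <- dim(x)
  stopifnot(length(dm) == 3)
  lab <- array(0L, dm)
  idx <- which(x)
  if (length(idx) == 0) return(lab)
  coords <- arrayInd(idx, dm)
  in_set <- array(FALSE, dm); in_set[idx] <- TRUE
  cur <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_along(idx)) {
    start <- idx[s]
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- matrix(coords[s, ], 1, 3)
    lab[start] <- cur
    while (nrow(queue) > 0) {
      nb <- queue[rep(seq_len(nrow(queue)), each = 6), , drop = FALSE] +
        offs[rep(1:6, nrow(queue)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
        nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0) break
      lin <- nb[, 1] + dm[1] * (nb[, 2] - 1) + dm[1] * dm[2] * (nb[, 3] - 1)
      new <- in_set[lin] & lab[lin] == 0L
      if (!any(new)) break
      lin_new <- unique(lin[new])
      lab[lin_new] <- cur
      queue <- arrayInd(lin_new, dm)
    }
  }
  lab
}

# max cluster size of |z| >= thresh inside the mask (used for the permutation null)
max_cluster_size <- function(z_in_mask, mask, z_thresh) {
  supra <- array(FALSE, dim(mask))
  supra[mask] <- abs(z_in_mask) >= z_thresh
  if (!any(supra)) return(0L)
  lab <- label_clusters_3d(supra)
  max(tabulate(lab[lab > 0L]))
}

#' Permutation-based cluster-level inference on a z map
#'
#' Thresholds the z map at `|z| >= z_thresh`, labels 6-connected clusters
#' (positive and negative separately), and, when a permutation generator is
#' supplied, builds the null distribution of the maximum cluster size from
#' `n_perm` resampled z maps. The corrected p-value of each observed cluster
#' is `(1 + #(null max size >= observed size)) / (n_perm + 1)`, a family-wise
#' error rate that is exact under exchangeability.
#'
#' @param z numeric vector of z values for the in-mask voxels.
#' @param mask 3-D logical array defining the analysis volume.
#' @param z_thresh cluster-forming threshold (default 3.1).
#' @param alpha cluster-level significance threshold (default 0.05).
#' @param perm_fun optional function(i) returning a permuted in-mask z vector;
#'   when `NULL` no p-values are computed.
#' @param n_perm number of permutations (>= 100; smaller nulls are unstable).
#' @return object of class `cluster_result`: tibble `clusters` (id, sign,
#'   size, peak z, peak i/j/k, p_corrected, significant), the labelled array,
#'   and the null maximum-size distribution.
#' @export
cluster_inference <- function(z, mask, z_thresh = 3.1, alpha = 0.05,
                              perm_fun = NULL, n_perm = 1000) {
  if (length(z) != sum(mask)) {
    abort("`z` must have one value per in-mask voxel.", class = "painpsych_cluster_error")
  }
  if (any(!is.finite(z))) {
    abort("non-finite z values inside the mask.", class = "painpsych_cluster_error")
  }
  if (!is.null(perm_fun) && n_perm < 100) {
    abort("`n_perm` must be >= 100 for a stable null.", class = "painpsych_cluster_error")
  }
  dm <- dim(mask)
  zvol <- array(0, dm); zvol[mask] <- z
  supra <- array(FALSE, dm); supra[mask] <- abs(z) >= z_thresh
  lab <- label_clusters_3d(supra)
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  clusters <- map(ids, function(id) {
    vox <- which(lab == id)
    zv <- zvol[vox]
    peak <- vox[which.max(abs(zv))]
    pc <- arrayInd(peak, dm)
    tibble(cluster_id = id, sign = if (mean(zv) >= 0) "positive" else "negative",
           size = length(vox), peak_z = zv[which.max(abs(zv))],
           peak_i = pc[1], peak_j = pc[2], peak_k = pc[3])
  }) %>% list_rbind()
  if (is.null(clusters) || nrow(clusters) == 0) {
    clusters <- tibble(cluster_id = integer(), sign = character(),
                       size = integer(), peak_z = numeric(),
                       peak_i = integer(), peak_j = integer(),
                       peak_k = integer())
  }
  null_max <- NULL
  if (!is.null(perm_fun) && nrow(clusters) >= 0) {
    null_max <- vapply(seq_len(n_perm),
                       function(i) max_cluster_size(perm_fun(i), mask, z_thresh),
                       integer(1))
    if (nrow(clusters) > 0) {
      clusters$p_corrected <- vapply(clusters$size, function(s) {
        (1 + sum(null_max >= s)) / (n_perm + 1)
      }, numeric(1))
      clusters$significant <- clusters$p_corrected <= alpha
    } else {
      clusters$p_corrected <- numeric()
      clusters$significant <- logical()
    }
  }
  structure(list(clusters = clusters, labels = lab, z_thresh = z_thresh,
                 alpha = alpha, null_max_size = null_max,
                 n_perm = if (is.null(perm_fun)) 0L else n_perm),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s) at |z| >= %.2f", nrow(x$clusters), x$z_thresh))
  if (x$n_perm > 0) cat(sprintf(", %d permutations", x$n_perm))
  cat("\n")
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

# t -> z via the normal-quantile transform of the t CDF, numerically stable in
# both tails; |z| capped at 40 (p underflows far beyond any usable threshold)
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  pos <- t >= 0
  z[pos] <- -qnorm(pt(t[pos], df, lower.tail = FALSE, log.p = TRUE), log.p = TRUE)
  z[!pos] <- qnorm(pt(t[!pos], df, lower.tail = TRUE, log.p = TRUE), log.p = TRUE)
  pmin(pmax(z, -40), 40)
}

# F -> z (one-sided upper tail), same cap
f_to_z <- function(f, df1, df2) {
  z <- -qnorm(pf(f, df1, df2, lower.tail = FALSE, log.p = TRUE), log.p = TRUE)
  pmin(pmax(z, -40), 40)
}
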