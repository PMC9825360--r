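#' Uniform label flipping (noise model S-I)
#'
#' Flips exactly `round(rho1 * |true positives|)` of the truly positive
#' patches and `round(rho0 * |true negatives|)` of the truly negative
#' patches, each chosen uniformly without replacement, so realized noise
#' rates match the nominal ones up to rounding.
#'
#' @param pset a `patch_set` whose `true_label` column is populated.
#' @param rho0 fraction of true negatives to flip, in `[0, 1)`.
#' @param rho1 fraction of true positives to flip, in `[0, 1)`.
#' @param seed integer seed.
#' @return the `patch_set` with noisy `label`s (true labels untouched).
#' @export
simulate_uniform_flip <- function(pset, rho0, rho1, seed = 1) {
  if (anyNA(pset$true_label)) stop_config("true labels must be known")
  if (rho0 < 0 || rho0 >= 1 || rho1 < 0 || rho1 >= 1) {
    stop_config("rho0 and rho1 must be in [0, 1)")
  }
  lab <- pset$true_label
  pos <- which(lab == 1L)
  neg <- which(lab == 0L)
  with_stream(seed, "noise", {
    fp <- if (length(pos)) sample(pos, round(rho1 * length(pos))) else integer(0)
    fn <- if (length(neg)) sample(neg, round(rho0 * length(neg))) else integer(0)
    lab[fp] <- 0L
    lab[fn] <- 1L
  })
  pset$label <- lab
  pset
}

#' Coarse annotation by omitting small lesions (noise model S-II)
#'
#' Emulates a quick human annotation: with two or more lesions, only the
#' largest (by pixel area, 8-connected) is kept, dilated by a disc, and
#' replaced by its convex hull; with exactly one lesion, the lesion is
#' divided in half (split at its centroid perpendicular to its longest
#' principal axis; the larger half is kept, ties resolved toward the half
#' containing the first pixel in scan order).
#'
#' @param gt logical ground-truth mask with at least one lesion pixel.
#' @param dilation_radius disc radius in pixels; default 5% of the shorter
#'   mask side.
#' @return logical coarse mask.
#' @export
simulate_omit_small_lesions <- function(gt,
                                        dilation_radius = round(0.05 * min(dim(gt)))) {
  if (!any(gt)) stop_degenerate("ground-truth mask has no lesion")
  if (dilation_radius < 0) stop_config("dilation_radius must be >= 0")
  lab <- label_components(gt)
  n_comp <- max(lab)
  if (n_comp >= 2L) {
    sizes <- component_sizes(lab)
    largest <- which.max(sizes)  # ties: lowest label = first in scan order
    kept <- lab == largest
    convex_hull_mask(dilate_disk(kept, dilation_radius))
  } else {
    halve_component(gt)
  }
}

# Split a connected mask at its centroid, perpendicular to the longest
# principal axis; keep the larger half.
halve_component <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  v <- eigen(crossprod(centered) / nrow(pts), symmetric = TRUE)$vectors[, 1]
  proj <- centered %*% v
  half1 <- proj <= 0
  keep <- if (sum(half1) > sum(!half1)) half1
  else if (sum(half1) < sum(!half1)) !half1
  else {
    # tie: keep the half containing the first pixel in scan order
    first <- which.min((pts[, 2] - 1) * nrow(mask) + pts[, 1])
    if (half1[first]) half1 else !half1
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[pts[keep, , drop = FALSE]] <- TRUE
  out
}

#' Realized noise rates of a label vector
#'
#' @param true_labels binary vector of true labels.
#' @param noisy_labels binary vector of assigned labels, same length.
#' @return list with `rho0` (fraction of true negatives labeled 1) and
#'   `rho1` (fraction of true positives labeled 0); a rate is `NA` when its
#'   class is absent.
#' @export
noise_rates <- function(true_labels, noisy_labels) {
  stopifnot(length(true_labels) == length(noisy_labels))
  stopifnot(all(true_labels %in% 0:1), all(noisy_labels %in% 0:1))
  pos <- true_labels == 1
  neg <- true_labels == 0
  list(
    rho0 = if (any(neg)) mean(noisy_labels[neg] == 1) else NA_real_,
    rho1 = if (any(pos)) mean(noisy_labels[pos] == 0) else NA_real_
  )
}

#' Noise specification
#'
#' Bundles the parameters of the two synthetic coarse-annotation procedures
#' for serialization alongside generated fixtures.
#'
#' @param mode `"uniform_flip"` (S-I) or `"omit_small_lesions"` (S-II).
#' @param rho0,rho1 flip rates for S-I (fractions of true negatives /
#'   positives), in `[0, 1)`.
#' @param dilation_radius disc radius in pixels for S-II.
#' @param seed integer seed.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(mode = c("uniform_flip", "omit_small_lesions"),
                       rho0 = 0, rho1 = 0, dilation_radius = 0, seed = 1) {
  mode <- match.arg(mode)
  if (rho0 < 0 || rho0 >= 1 || rho1 < 0 || rho1 >= 1) {
    stop_config("rho0 and rho1 must be in [0, 1)")
  }
  if (dilation_radius < 0) stop_config("dilation_radius must be >= 0")
  structure(list(mode = mode, rho0 = rho0, rho1 = rho1,
                 dilation_radius = dilation_radius, seed = seed),
            class = "noise_spec")
}
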