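#' Construct a slide image object
#'
#' A slide is an 8-bit RGB raster stored as an `H x W x 3` numeric array with
#' values in `[0, 255]`, together with the downsample factor relative to the
#' native scan resolution and a source identifier.  Pyramidal whole-slide
#' formats can be plugged in by reading any level into such an array.
#'
#' @param pixels numeric array `H x W x 3` with values in `[0, 255]`, or an
#'   `H x W` matrix (replicated to three identical channels).
#' @param downsample downsample factor relative to native resolution.
#' @param source_id identifier string carried through to results.
#' @return an object of class `lcmil_slide` with elements `pixels`,
#'   `downsample`, `source_id`.
#' @export
slide_image <- function(pixels, downsample = 1, source_id = "slide") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop_config("`pixels` must be an H x W x 3 array")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop_config("pixel values must be finite and in [0, 255]")
  }
  structure(
    list(pixels = pixels, downsample = downsample, source_id = source_id),
    class = "lcmil_slide"
  )
}

#' @export
print.lcmil_slide <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<lcmil_slide '%s' %d x %d, downsample %g>\n",
              x$source_id, d[1], d[2], x$downsample))
  invisible(x)
}

slide_dim <- function(slide) dim(slide$pixels)[1:2]

#' Tissue detection via Otsu thresholding of HSV channels
#'
#' Converts the slide to HSV, applies Otsu's threshold independently to the
#' hue and saturation channels, and intersects the two foreground masks
#' (foreground being the high side of each threshold, which captures stained
#' tissue against a bright, unsaturated background).
#'
#' @param slide an [slide_image()].
#' @return logical `H x W` matrix, `TRUE` on tissue.
#' @seealso [compute_tissue_mask_rgb()] for the threshold-based alternative.
#' @export
compute_tissue_mask_hsv <- function(slide) {
  px <- slide$pixels
  hsv <- grDevices::rgb2hsv(
    r = as.vector(px[, , 1]), g = as.vector(px[, , 2]), b = as.vector(px[, , 3]),
    maxColorValue = 255
  )
  h <- hsv[1, ]
  s <- hsv[2, ]
  if (max(h) == min(h) || max(s) == min(s)) {
    stop_degenerate("constant H or S channel: Otsu threshold undefined")
  }
  d <- slide_dim(slide)
  mh <- matrix(h >= otsu_threshold(h), d[1], d[2])
  ms <- matrix(s >= otsu_threshold(s), d[1], d[2])
  mh & ms
}

#' Tissue detection via RGB thresholds
#'
#' A pixel is tissue iff its red, green and blue values are strictly below the
#' given thresholds, excluding near-white background.  Default thresholds
#' `(235, 210, 235)` follow the convention used for liver/colorectal
#' resection slides.
#'
#' @param slide an [slide_image()].
#' @param thresholds numeric length-3 `(r, g, b)` in `[0, 255]`.
#' @return logical `H x W` matrix, `TRUE` on tissue.
#' @export
compute_tissue_mask_rgb <- function(slide, thresholds = c(235, 210, 235)) {
  stopifnot(length(thresholds) == 3, all(thresholds >= 0), all(thresholds <= 255))
  px <- slide$pixels
  px[, , 1] < thresholds[1] & px[, , 2] < thresholds[2] & px[, , 3] < thresholds[3]
}

#' Lattice a slide into a grid of patches
#'
#' Generates the square-patch lattice with the given size and overlap,
#' top-left aligned at pixel `(0, 0)` (0-based coordinates, row-major).  A
#' patch occupies the half-open box `[row, row+P) x [col, col+P)`; its center
#' is `(row + P/2, col + P/2)`.  Patches extending past the slide edge are
#' never emitted, and patches whose center falls outside the tissue mask are
#' discarded.
#'
#' @param slide an [slide_image()].
#' @param tissue logical `H x W` tissue mask (default: everything is tissue).
#' @param patch_size patch side length in pixels.
#' @param overlap_fraction fraction of overlap between neighboring patches in
#'   `[0, 1)`; the stride is `patch_size * (1 - overlap_fraction)` and must be
#'   a positive integer.
#' @return a `patch_set`: a data frame with one row per retained patch
#'   (columns `row`, `col`, `center_row`, `center_col`, `label`, `true_label`,
#'   `score`, 0-based pixel coordinates) and attributes `patch_size`,
#'   `stride`, `slide_dim`, `grid_dim`, `source_id`.  Labels are unset (`NA`)
#'   until [assign_noisy_labels()].
#' @export
extract_patch_grid <- function(slide, tissue = NULL, patch_size = 256,
                               overlap_fraction = 0) {
  d <- slide_dim(slide)
  if (!is_count(patch_size) || patch_size > min(d)) {
    stop_config("patch_size must be a positive integer <= min(H, W)")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_config("overlap_fraction must be in [0, 1)")
  }
  stride <- patch_size * (1 - overlap_fraction)
  if (abs(stride - round(stride)) > 1e-9 || round(stride) < 1) {
    stop_config(sprintf(
      "stride patch_size * (1 - overlap) = %g is not a positive integer", stride))
  }
  stride <- as.integer(round(stride))
  if (is.null(tissue)) tissue <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(tissue), d)) stop_config("tissue mask must match slide shape")

  rows0 <- seq.int(0L, d[1] - patch_size, by = stride)
  cols0 <- seq.int(0L, d[2] - patch_size, by = stride)
  grid <- expand.grid(row = rows0, col = cols0, KEEP.OUT.ATTRS = FALSE)
  cr <- grid$row + patch_size %/% 2L
  cc <- grid$col + patch_size %/% 2L
  keep <- tissue[cbind(cr + 1L, cc + 1L)]
  ps <- data.frame(
    row = grid$row[keep], col = grid$col[keep],
    center_row = cr[keep], center_col = cc[keep],
    label = NA_integer_, true_label = NA_integer_, score = NA_real_
  )
  structure(ps,
    patch_size = patch_size, stride = stride, slide_dim = d,
    grid_dim = c(length(rows0), length(cols0)), source_id = slide$source_id,
    class = c("patch_set", "data.frame")
  )
}

patch_attr <- function(pset, what) attr(pset, what, exact = TRUE)

#' Assign noisy patch labels from a coarse annotation mask
#'
#' Each patch receives label 1 iff its center pixel lies inside the coarse
#' annotation mask (the center rule for boundary-straddling patches), giving
#' the positively/negatively labeled pools S_P and S_N.
#'
#' @param pset a `patch_set` from [extract_patch_grid()].
#' @param coarse logical `H x W` mask aligned to the slide frame.
#' @param as_truth if `TRUE`, also record the induced labels as the true
#'   labels (use when `coarse` is the ground-truth mask).
#' @return the `patch_set` with `label` (and optionally `true_label`) filled.
#' @export
assign_noisy_labels <- function(pset, coarse, as_truth = FALSE) {
  d <- patch_attr(pset, "slide_dim")
  if (!is.logical(coarse) || !identical(dim(coarse), d)) {
    stop_config("coarse mask must be a logical matrix aligned to the slide frame")
  }
  lab <- as.integer(coarse[cbind(pset$center_row + 1L, pset$center_col + 1L)])
  pset$label <- lab
  if (as_truth) pset$true_label <- lab
  pset
}

#' Positive / negative pool indices
#'
#' @param pset a labeled `patch_set`.
#' @return list with integer index vectors `positive` (S_P) and `negative`
#'   (S_N).
#' @export
patch_pools <- function(pset) {
  if (anyNA(pset$label)) stop_config("patch labels are unset")
  list(positive = which(pset$label == 1L), negative = which(pset$label == 0L))
}

#' Arrange per-patch scores on the heat-map grid
#'
#' Places every patch score at its lattice cell (`row/stride`, `col/stride`);
#' lattice positions with no retained patch (non-tissue) are `NA` and treated
#' as zero downstream.
#'
#' @param pset a `patch_set` whose `score` column is fully populated (see
#'   [score_all_patches()]), or with `values` supplying the per-patch values.
#' @param values optional numeric vector to place instead of `pset$score`
#'   (e.g. binary labels).
#' @return a `score_map`: numeric matrix on the patch grid with attributes
#'   `stride`, `patch_size`, `downscale` (stride, i.e. slide pixels per cell).
#' @export
assemble_score_map <- function(pset, values = NULL) {
  if (is.null(values)) values <- pset$score
  if (anyNA(values)) stop("every patch must carry a score before map assembly")
  gd <- patch_attr(pset, "grid_dim")
  stride <- patch_attr(pset, "stride")
  m <- matrix(NA_real_, gd[1], gd[2])
  m[cbind(pset$row %/% stride + 1L, pset$col %/% stride + 1L)] <- values
  structure(m,
    stride = stride, patch_size = patch_attr(pset, "patch_size"),
    downscale = stride, slide_dim = patch_attr(pset, "slide_dim"),
    class = c("score_map", "matrix")
  )
}

# Values of a slide-frame mask sampled at each patch center: the common
# evaluation frame on which coarse, refined and ground-truth masks are
# compared.
#' Sample a slide-frame mask at patch centers
#'
#' Rasterizes a mask to the patch grid by the same center rule used for label
#' assignment, so that masks of different provenance are compared on an
#' identical support.
#'
#' @param pset a `patch_set`.
#' @param mask logical `H x W` mask in the slide frame.
#' @return integer vector (0/1), one value per patch.
#' @export
mask_at_patch_centers <- function(pset, mask) {
  d <- patch_attr(pset, "slide_dim")
  if (!identical(dim(mask), d)) stop_config("mask must match the slide frame")
  as.integer(mask[cbind(pset$center_row + 1L, pset$center_col + 1L)])
}

# Per-patch values of a heat-map-frame mask (e.g. refined mask) back at
# patch positions.
grid_values_at_patches <- function(pset, grid) {
  stride <- patch_attr(pset, "stride")
  grid[cbind(pset$row %/% stride + 1L, pset$col %/% stride + 1L)]
}

# Extract the pixel block of one patch as a p x p x 3 array.
extract_patch_pixels <- function(slide, row0, col0, patch_size) {
  slide$pixels[(row0 + 1L):(row0 + patch_size),
               (col0 + 1L):(col0 + patch_size), , drop = FALSE]
}
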