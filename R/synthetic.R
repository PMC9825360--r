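#' Specification of a synthetic two-texture slide
#'
#' Describes a toy "slide": a textured background carrying one or more
#' lesions whose texture statistics differ, plus the exact ground-truth mask
#' of the lesion support.  Lesions are unions of random smooth star-shaped
#' blobs (a base radius modulated by a low-order random Fourier series), so
#' lesion geometry, area and boundary smoothness are controlled by a few
#' parameters.
#'
#' Textures are parameterized Gaussian noise fields: per pixel,
#' `base_gray + stripes + smoothed noise`, clipped to `[0, 255]`, then tinted
#' per RGB channel.  First-order (base gray, tint) and second-order (noise
#' sd, smoothing scale, stripes) statistics of patches therefore directly
#' control how hard the patch classification task is.
#'
#' @param height,width slide size in pixels.
#' @param n_lesions number of lesions (0 allowed: blank ground truth).
#' @param lesion_radius_range length-2 range of blob base radii in pixels.
#' @param background_texture,lesion_texture texture parameter lists as
#'   produced by [texture_params()].
#' @param lesion_fraction_bounds optional length-2 bounds; lesion geometry is
#'   rejection-sampled (re-drawn with derived seeds) until the lesion area
#'   fraction falls inside.  `NULL` disables the inclusion rule.
#' @param seed integer seed; the slide is fully determined by it.
#' @return a `synthetic_slide_spec` list.
#' @export
synthetic_slide_spec <- function(height = 2048, width = 2048, n_lesions = 3,
                                 lesion_radius_range = c(300, 500),
                                 background_texture = texture_params(
                                   base_gray = 200, noise_sd = 12,
                                   smooth_sigma = 1,
                                   tint = c(1, 0.86, 0.95)),
                                 lesion_texture = texture_params(
                                   base_gray = 150, noise_sd = 25,
                                   smooth_sigma = 2.5, stripe_freq = 0.12,
                                   stripe_amp = 12, tint = c(0.9, 0.78, 0.98)),
                                 lesion_fraction_bounds = NULL,
                                 seed = 1) {
  if (n_lesions > 0 && max(lesion_radius_range) * 2 > min(height, width)) {
    stop_config("lesion radius too large for the slide")
  }
  if (identical(background_texture, lesion_texture)) {
    stop_config("background and lesion textures must differ in at least one parameter")
  }
  structure(list(
    height = height, width = width, n_lesions = n_lesions,
    lesion_radius_range = lesion_radius_range,
    background_texture = background_texture, lesion_texture = lesion_texture,
    lesion_fraction_bounds = lesion_fraction_bounds, seed = seed
  ), class = "synthetic_slide_spec")
}

#' Texture parameters for the synthetic generator
#'
#' @param base_gray mean gray level in `[0, 255]`.
#' @param noise_sd standard deviation of the Gaussian noise field (gray
#'   levels).
#' @param smooth_sigma Gaussian smoothing scale of the noise in pixels
#'   (0 = white noise).
#' @param stripe_freq spatial frequency (cycles/pixel) of an optional
#'   sinusoidal stripe pattern; 0 disables stripes.
#' @param stripe_amp stripe amplitude in gray levels.
#' @param tint length-3 RGB channel multipliers in `(0, 1]`.
#' @return list of texture parameters.
#' @export
texture_params <- function(base_gray, noise_sd = 10, smooth_sigma = 0,
                           stripe_freq = 0, stripe_amp = 0,
                           tint = c(1, 1, 1)) {
  list(base_gray = base_gray, noise_sd = noise_sd, smooth_sigma = smooth_sigma,
       stripe_freq = stripe_freq, stripe_amp = stripe_amp, tint = tint)
}

# One gray texture field H x W for the given parameters (RNG: current stream).
render_texture_field <- function(h, w, tp) {
  field <- matrix(tp$base_gray, h, w)
  if (tp$stripe_freq > 0 && tp$stripe_amp > 0) {
    ang <- runif(1, 0, pi)
    phase <- runif(1, 0, 2 * pi)
    rowc <- matrix(seq_len(h), h, w)
    colc <- matrix(seq_len(w), h, w, byrow = TRUE)
    field <- field + tp$stripe_amp *
      sin(2 * pi * tp$stripe_freq * (rowc * cos(ang) + colc * sin(ang)) + phase)
  }
  if (tp$noise_sd > 0) {
    noise <- matrix(rnorm(h * w, sd = tp$noise_sd), h, w)
    if (tp$smooth_sigma > 0) {
      # smoothing shrinks the sd roughly by 2*sigma*sqrt(pi); rescale so
      # noise_sd keeps its meaning at the pixel level
      sm <- EBImage::gblur(noise, sigma = tp$smooth_sigma)
      sm <- sm * (tp$noise_sd / max(stats::sd(as.vector(sm)), 1e-12))
      noise <- sm
    }
    field <- field + noise
  }
  clamp(field, 0, 255)
}

# Union of star-shaped blobs (RNG: current stream).
render_lesion_mask <- function(h, w, n_lesions, radius_range) {
  gt <- matrix(FALSE, h, w)
  if (n_lesions == 0) return(gt)
  rowc <- matrix(seq_len(h), h, w)
  colc <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n_lesions)) {
    r0 <- runif(1, radius_range[1], radius_range[2])
    margin <- r0 * 1.35
    cy <- if (2 * margin >= h) h / 2 else runif(1, margin, h - margin)
    cx <- if (2 * margin >= w) w / 2 else runif(1, margin, w - margin)
    # smooth radial perturbation: 3 random Fourier harmonics, max +/-30%
    amp <- runif(3, 0, 0.3 / c(1, 2, 3))
    ph <- runif(3, 0, 2 * pi)
    theta <- atan2(rowc - cy, colc - cx)
    rad <- r0 * (1 + amp[1] * sin(theta + ph[1]) + amp[2] * sin(2 * theta + ph[2]) +
                   amp[3] * sin(3 * theta + ph[3]))
    dist <- sqrt((rowc - cy)^2 + (colc - cx)^2)
    gt <- gt | (dist <= rad)
  }
  gt
}

#' Generate a synthetic slide and its ground-truth mask
#'
#' Fully determined by `spec$seed`.  If `lesion_fraction_bounds` is set, the
#' lesion geometry is re-drawn (up to 100 attempts, each with a derived seed)
#' until the lesion area fraction lies inside the bounds.
#'
#' @param spec a [synthetic_slide_spec()].
#' @return list with `slide` (an [slide_image()]) and `ground_truth` (logical
#'   mask).
#' @export
generate_synthetic_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  h <- spec$height; w <- spec$width

  gt <- with_stream(spec$seed, "slide", {
    m <- render_lesion_mask(h, w, spec$n_lesions, spec$lesion_radius_range)
    if (!is.null(spec$lesion_fraction_bounds) && spec$n_lesions > 0) {
      b <- spec$lesion_fraction_bounds
      attempt <- 0
      while ({f <- mean(m); f < b[1] || f > b[2]}) {
        attempt <- attempt + 1
        if (attempt > 100) stop_config(
          "could not meet lesion_fraction_bounds in 100 attempts")
        m <- render_lesion_mask(h, w, spec$n_lesions, spec$lesion_radius_range)
      }
    }
    m
  })

  img <- with_stream(spec$seed, "misc", {
    bg <- render_texture_field(h, w, spec$background_texture)
    le <- render_texture_field(h, w, spec$lesion_texture)
    gray <- bg
    gray[gt] <- le[gt]
    tint_bg <- spec$background_texture$tint
    tint_le <- spec$lesion_texture$tint
    px <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      tm <- matrix(tint_bg[ch], h, w)
      tm[gt] <- tint_le[ch]
      px[, , ch] <- clamp(gray * tm, 0, 255)
    }
    px
  })

  list(
    slide = slide_image(img, source_id = sprintf("synthetic-seed%d", spec$seed)),
    ground_truth = gt
  )
}

#' Lesion area fraction of a mask
#'
#' Fraction of tissue pixels covered by the lesion mask; used to enforce the
#' inclusion rule that slides keep their lesion ratio within `[0.10, 0.90]`.
#'
#' @param mask logical lesion mask.
#' @param tissue optional logical tissue mask of the same shape; default is
#'   the full raster.
#' @return fraction in `[0, 1]`.
#' @export
lesion_area_fraction <- function(mask, tissue = NULL) {
  if (is.null(tissue)) tissue <- matrix(TRUE, nrow(mask), ncol(mask))
  stopifnot(identical(dim(mask), dim(tissue)))
  nt <- sum(tissue)
  if (nt == 0) stop_degenerate("empty tissue mask")
  sum(mask & tissue) / nt
}

#' Check a lesion fraction against inclusion bounds
#'
#' @param fraction lesion area fraction.
#' @param bounds inclusion bounds, default `c(0.10, 0.90)`.
#' @return `TRUE` if inside the bounds.
#' @export
within_inclusion_bounds <- function(fraction, bounds = c(0.10, 0.90)) {
  fraction >= bounds[1] & fraction <= bounds[2]
}

#' Default synthetic benchmark slide specification
#'
#' The package's standard desk-scale test bed: a 2048 x 2048 slide with
#' three lesions (radius 300-500 px), lesion fraction forced into
#' `[0.10, 0.90]` by rejection sampling, and the default texture contrast.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_slide_spec()].
#' @return a `synthetic_slide_spec`.
#' @export
default_slide_spec <- function(seed = 1, ...) {
  args <- list(seed = seed, lesion_fraction_bounds = c(0.10, 0.90), ...)
  do.call(synthetic_slide_spec, args)
}
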