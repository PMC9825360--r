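# Frozen small-CNN patch feature extractor.
#
# The MIL predictors see patches only through an embedding f_psi.  The
# package default keeps the convolutional stage frozen (as the training
# contract requires) and makes it cheap and fully seeded: four convolution
# layers with fixed random (He-initialized) filters over a 32 x 32 grayscale
# rendition of the patch, plus first-order color statistics.  A pretrained
# deep backbone can be plugged in by supplying any function that maps a
# p x p x 3 patch to a numeric vector.

#' Create the default frozen convolutional feature extractor
#'
#' Four 3x3 convolution layers (8, 8, 16, 16 filters, ReLU, 2x2 mean pooling
#' after the first two) with fixed random filters applied to the patch
#' downsampled to 32 x 32 grayscale; global mean and max pooling of the last
#' layer plus per-channel mean/sd and grayscale mean/sd give a 40-dimensional
#' descriptor.  Filters are drawn once from the extractor seed, so the
#' embedding is deterministic and identical across runs and platforms.
#'
#' @param seed seed for the frozen filters (part of the extractor identity).
#' @return an object of class `cnn_extractor`; call it via
#'   [extract_features()].
#' @export
cnn_feature_extractor <- function(seed = 42) {
  he <- function(k, cin, cout) {
    array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
          c(k, k, cin, cout))
  }
  filters <- with_stream(seed, "init", list(
    he(3, 1, 8), he(3, 8, 8), he(3, 8, 16), he(3, 16, 16)
  ))
  structure(list(filters = filters, n_features = 40L, seed = seed),
            class = "cnn_extractor")
}

# 3x3 valid convolution of an H x W x Cin array with a 3 x 3 x Cin x Cout
# filter bank, via im2col + one matrix product.
conv3x3 <- function(x, filt) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
  Ho <- H - 2L; Wo <- W - 2L
  cols <- matrix(0, Ho * Wo, 9L * cin)
  k <- 0L
  for (ch in seq_len(cin)) {
    for (dc in 0:2) {
      for (dr in 0:2) {
        k <- k + 1L
        cols[, k] <- x[(1L + dr):(Ho + dr), (1L + dc):(Wo + dc), ch]
      }
    }
  }
  fm <- matrix(filt, 9L * cin, dim(filt)[4])
  # filter array is k x k x cin x cout; reorder rows to (dr, dc, ch)
  y <- cols %*% fm
  array(y, c(Ho, Wo, dim(filt)[4]))
}

relu <- function(x) pmax(x, 0)

# 2x2 mean pooling (odd trailing row/col cropped).
pool2 <- function(x) {
  H <- 2L * (dim(x)[1] %/% 2L); W <- 2L * (dim(x)[2] %/% 2L)
  x <- x[seq_len(H), seq_len(W), , drop = FALSE]
  (x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE] +
     x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE] +
     x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE] +
     x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]) / 4
}

# Block-mean downsample a matrix by integer factor f.
block_mean <- function(m, f) {
  if (f == 1L) return(m)
  H <- f * (nrow(m) %/% f); W <- f * (ncol(m) %/% f)
  m <- m[seq_len(H), seq_len(W)]
  # average rows then columns via rowsum on group indices
  rg <- (seq_len(H) - 1L) %/% f + 1L
  cg <- (seq_len(W) - 1L) %/% f + 1L
  t(rowsum(t(rowsum(m, rg)), cg)) / (f * f)
}

# Embed one patch (p x p x 3, values 0..255) -> length-40 descriptor.
embed_patch <- function(extractor, patch) {
  p <- dim(patch)[1]
  gray <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / (3 * 255)
  f <- max(1L, p %/% 32L)
  g32 <- block_mean(gray, f)
  x <- array(g32, c(dim(g32), 1L))
  x <- pool2(relu(conv3x3(x, extractor$filters[[1]])))
  x <- pool2(relu(conv3x3(x, extractor$filters[[2]])))
  x <- relu(conv3x3(x, extractor$filters[[3]]))
  x <- relu(conv3x3(x, extractor$filters[[4]]))
  fm <- apply(x, 3, mean)
  fx <- apply(x, 3, max)
  ch_mean <- c(mean(patch[, , 1]), mean(patch[, , 2]), mean(patch[, , 3])) / 255
  ch_sd <- c(stats::sd(patch[, , 1]), stats::sd(patch[, , 2]),
             stats::sd(patch[, , 3])) / 255
  c(fm, fx, ch_mean, ch_sd, mean(gray), stats::sd(gray))
}

#' Compute patch embeddings for a whole patch set
#'
#' @param slide an [slide_image()].
#' @param pset a `patch_set`.
#' @param extractor a [cnn_feature_extractor()] or any function mapping a
#'   `p x p x 3` array to a numeric vector.
#' @return numeric matrix, one row per patch.
#' @export
extract_features <- function(slide, pset, extractor = cnn_feature_extractor()) {
  p <- patch_attr(pset, "patch_size")
  n <- nrow(pset)
  fun <- if (inherits(extractor, "cnn_extractor")) {
    function(px) embed_patch(extractor, px)
  } else {
    stopifnot(is.function(extractor))
    extractor
  }
  first <- fun(extract_patch_pixels(slide, pset$row[1], pset$col[1], p))
  out <- matrix(0, n, length(first))
  out[1, ] <- first
  if (n > 1) {
    for (i in 2:n) {
      out[i, ] <- fun(extract_patch_pixels(slide, pset$row[i], pset$col[i], p))
    }
  }
  out
}

# Column standardization; statistics are estimated once on the training
# patch set and frozen into the model.
feature_scaler <- function(features) {
  mu <- colMeans(features)
  sg <- apply(features, 2, stats::sd)
  sg[!is.finite(sg) | sg < 1e-8] <- 1
  list(center = mu, scale = sg)
}

apply_scaler <- function(features, scaler) {
  sweep(sweep(features, 2, scaler$center), 2, scaler$scale, "/")
}
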