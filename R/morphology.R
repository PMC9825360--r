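# Binary-mask morphology: 8-connected components (run-based union-find),
# small-object removal, small-hole filling, disc dilation, convex hulls.

#' Label 8-connected components of a binary mask
#'
#' Two foreground pixels are connected if they touch edge- or corner-wise.
#' Labeling merges row runs with a union-find, so large masks with few
#' components stay cheap.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 for background, components
#'   numbered 1.. in first-pixel scan order (column-major, as R stores
#'   matrices).
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  if (!any(mask)) return(out)

  # runs of TRUE per row
  run_row <- list(); run_c1 <- list(); run_c2 <- list()
  for (r in seq_len(H)) {
    x <- mask[r, ]
    if (!any(x)) { run_row[[r]] <- integer(0); run_c1[[r]] <- integer(0); run_c2[[r]] <- integer(0); next }
    rl <- rle(x)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    run_row[[r]] <- rep.int(r, sum(keep))
    run_c1[[r]] <- starts[keep]
    run_c2[[r]] <- ends[keep]
  }
  rr <- unlist(run_row); c1 <- unlist(run_c1); c2 <- unlist(run_c2)
  nrun <- length(rr)
  parent <- seq_len(nrun)
  # union-find with path halving
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx_by_row <- split(seq_len(nrun), rr)
  for (r in 2:H) {
    a <- idx_by_row[[as.character(r)]]
    b <- idx_by_row[[as.character(r - 1L)]]
    if (is.null(a) || is.null(b)) next
    for (i in a) {
      # 8-connectivity: column ranges overlapping or diagonally adjacent
      j <- b[c2[b] >= c1[i] - 1L & c1[b] <= c2[i] + 1L]
      for (k in j) {
        ri <- uf_find(i); rk <- uf_find(k)
        if (ri != rk) parent[max(ri, rk)] <- min(ri, rk)
      }
    }
  }
  root <- vapply(seq_len(nrun), uf_find, integer(1))

  # order components by first pixel in column-major scan order
  first_pix <- (c1 - 1L) * H + rr  # linear index of run start
  comp_first <- tapply(first_pix, root, min)
  ord <- order(comp_first)
  relabel <- integer(max(root))
  relabel[as.integer(names(comp_first))[ord]] <- seq_along(ord)
  for (i in seq_len(nrun)) {
    out[rr[i], c1[i]:c2[i]] <- relabel[root[i]]
  }
  out
}

component_sizes <- function(labels) {
  tab <- tabulate(labels[labels > 0L])
  tab
}

#' Remove small connected foreground objects
#'
#' @param mask logical matrix.
#' @param min_px objects (8-connected) with fewer than `min_px` pixels are
#'   removed.
#' @return logical matrix.
#' @export
remove_small_objects <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- component_sizes(lab)
  keep <- which(sizes >= min_px)
  lab > 0L & lab %in% keep
}

#' Fill small background holes
#'
#' A hole is an 8-connected background component that does not touch the
#' raster border.
#'
#' @param mask logical matrix.
#' @param min_px holes with fewer than `min_px` pixels are filled.
#' @return logical matrix.
#' @export
fill_small_holes <- function(mask, min_px) {
  if (min_px <= 1 || all(mask)) return(mask)
  lab <- label_components(!mask)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- component_sizes(lab)
  fill <- setdiff(which(sizes < min_px), border)
  mask | (lab %in% fill & lab > 0L)
}

#' Dilate a binary mask with a disc structuring element
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels (rounded to integer); 0 returns the
#'   mask unchanged.
#' @return logical matrix.
#' @export
dilate_disk <- function(mask, radius) {
  radius <- as.integer(round(radius))
  if (radius <= 0L) return(mask)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  EBImage::dilate(mask * 1, brush) > 0.5
}

#' Filled convex hull of a binary mask
#'
#' Computes the convex hull of the foreground pixel centers and rasterizes it
#' by horizontal scanlines; a pixel is set iff its center lies inside or on
#' the hull.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return logical matrix.
#' @export
convex_hull_mask <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) stop_degenerate("empty mask has no convex hull")
  if (nrow(unique(pts)) < 3) return(mask)
  hull <- grDevices::chull(pts[, 2], pts[, 1])  # x = col, y = row
  vr <- pts[hull, 1]; vc <- pts[hull, 2]
  n <- length(hull)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq.int(min(vr), max(vr))) {
    xs <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      r1 <- vr[i]; r2 <- vr[j]; cc1 <- vc[i]; cc2 <- vc[j]
      if (r1 == r2) {
        if (r1 == r) xs <- c(xs, cc1, cc2)
      } else if (r >= min(r1, r2) && r <= max(r1, r2)) {
        xs <- c(xs, cc1 + (r - r1) * (cc2 - cc1) / (r2 - r1))
      }
    }
    if (length(xs)) {
      lo <- ceiling(min(xs) - 1e-9); hi <- floor(max(xs) + 1e-9)
      if (hi >= lo) out[r, lo:hi] <- TRUE
    }
  }
  out
}
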