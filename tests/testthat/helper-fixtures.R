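# Shared fixtures (built in code, cached for the test run) and independent
# brute-force oracles.

.fixture_env <- new.env()

# A desk-scale slide: 1024^2, two lesions, default texture contrast; the
# labeled patch lattice (64-px patches, 50% overlap -> 31x31 grid) and its
# frozen-CNN descriptors.
small_fixture <- function(seed = 1) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_env[[key]])) {
    spec <- default_slide_spec(seed = seed, height = 1024, width = 1024,
                               n_lesions = 2,
                               lesion_radius_range = c(150, 260))
    sim <- generate_synthetic_slide(spec)
    pset <- extract_patch_grid(sim$slide, patch_size = 64,
                               overlap_fraction = 0.5)
    pset <- assign_noisy_labels(pset, sim$ground_truth, as_truth = TRUE)
    feats <- extract_features(sim$slide, pset)
    .fixture_env[[key]] <- list(sim = sim, pset = pset, feats = feats)
  }
  .fixture_env[[key]]
}

# Post-processing sizes suited to the 31x31 grid of the small fixture.
small_refine_cfg <- function() refine_config(min_object_px = 25, min_hole_px = 25)

small_train_cfg <- function(seed = 3, M = 400) {
  train_config(M = M, n_j = 10, seed = seed)
}

# --- oracles ---------------------------------------------------------------

# Exhaustive Otsu: try every candidate cut, split the raw values, maximize
# between-class variance. Deliberately naive (double loop).
bf_otsu <- function(values, n_bins = 256) {
  cand <- (seq_len(n_bins) - 0.5) / n_bins
  best <- -Inf; best_t <- NA
  n <- length(values)
  for (t in cand) {
    lo <- values[values < t]; hi <- values[values >= t]
    if (!length(lo) || !length(hi)) next
    bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-15) { best <- bcv; best_t <- t }
  }
  best_t
}

# Flood-fill 8-connected labeling (queue-based), for checking the
# union-find implementation.
bf_label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {   # column-major scan order
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j)); lab[i, j] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          r <- p[1] + di; c <- p[2] + dj
          if (r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c] &&
              lab[r, c] == 0L) {
            lab[r, c] <- nxt
            queue[[length(queue) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# Point-in-convex-hull via cross products against every hull edge.
bf_in_hull <- function(r, c, vr, vc) {
  n <- length(vr)
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (vc[j] - vc[i]) * (r - vr[i]) - (vr[j] - vr[i]) * (c - vc[i])
    if (abs(cr) < 1e-9) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
  }
  TRUE
}

# Naive k-NN label editing identical in rule to dknn_refine.
bf_dknn <- function(X, lab, k) {
  n <- nrow(X)
  D <- as.matrix(dist(scale(X)))
  diag(D) <- Inf
  maj <- function(l, own) {
    n1 <- sum(l == 1); n0 <- length(l) - n1
    if (n1 > n0) 1L else if (n0 > n1) 0L else own
  }
  flagged <- logical(n)
  for (i in 1:n) {
    nb <- order(D[i, ])[1:k]
    flagged[i] <- maj(lab[nb], lab[i]) != lab[i]
  }
  pool <- which(!flagged)
  if (length(pool) < k) pool <- 1:n
  out <- lab
  for (i in which(flagged)) {
    cand <- setdiff(pool, i)
    nb <- cand[order(D[i, cand])[1:min(k, length(cand))]]
    out[i] <- maj(lab[nb], lab[i])
  }
  out
}

# 2-D Gaussian toy pools with planted flips, embedded in a patch set.
make_toy_noisy <- function(n, flip, seed) {
  set.seed(seed)
  n_pos <- n %/% 2
  X <- rbind(
    cbind(rnorm(n_pos, 3, 0.5), rnorm(n_pos, 3, 0.5)),
    cbind(rnorm(n - n_pos, -3, 0.5), rnorm(n - n_pos, -3, 0.5))
  )
  truth <- rep(c(1L, 0L), c(n_pos, n - n_pos))
  lab <- truth
  idx <- sample(n, flip)
  lab[idx] <- 1L - lab[idx]
  side <- ceiling(sqrt(n))
  ps <- toy_pset(rep(0L, side^2), side, side)
  ps <- ps[1:n, ]
  attr(ps, "grid_dim") <- c(side, side)
  ps$label <- lab
  ps$true_label <- truth
  list(ps = ps, X = X, lab = lab, truth = truth)
}

# Minimal patch set on a full rectangular grid with given labels, for tests
# that need label pools but no pixels.
toy_pset <- function(labels, nr, nc, patch_size = 2L, stride = 2L) {
  stopifnot(length(labels) == nr * nc)
  grid <- expand.grid(row = (seq_len(nr) - 1L) * stride,
                      col = (seq_len(nc) - 1L) * stride)
  ps <- data.frame(
    row = grid$row, col = grid$col,
    center_row = grid$row + patch_size %/% 2L,
    center_col = grid$col + patch_size %/% 2L,
    label = as.integer(labels), true_label = as.integer(labels),
    score = NA_real_
  )
  structure(ps, patch_size = patch_size, stride = stride,
            slide_dim = c(nr * stride + patch_size, nc * stride + patch_size),
            grid_dim = c(nr, nc), source_id = "toy",
            class = c("patch_set", "data.frame"))
}
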