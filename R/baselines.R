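# Baseline label-cleaning methods operating on the same patch pools:
# deep-feature k-NN label editing and two-round rank pruning.

#' DkNN configuration
#'
#' @param k neighbour count (default 10).
#' @return a `dknn_config` list.
#' @export
dknn_config <- function(k = 10) {
  if (!is_count(k)) stop_config("k must be a positive integer")
  structure(list(k = k), class = "dknn_config")
}

#' Rank-pruning configuration
#'
#' @param n_folds cross-validation folds for the first-round scores.
#' @param lambda ridge penalty of the logistic head.
#' @param seed seed for the fold assignment.
#' @return a `rank_prune_config` list.
#' @export
rank_prune_config <- function(n_folds = 3, lambda = 1e-2, seed = 1) {
  if (!is_count(n_folds, min = 2)) stop_config("n_folds must be >= 2")
  structure(list(n_folds = n_folds, lambda = lambda, seed = seed),
            class = "rank_prune_config")
}

# Majority label of a label vector with a tie sentinel.
vote <- function(labels, tie = NA_integer_) {
  n1 <- sum(labels == 1L)
  n0 <- length(labels) - n1
  if (n1 > n0) 1L else if (n0 > n1) 0L else tie
}

#' k-NN label editing in the frozen feature space (DkNN)
#'
#' Embeds every patch, flags those whose noisy label disagrees with the
#' majority label of their `k` nearest neighbours (Euclidean distance on the
#' standardized descriptors), then relabels the flagged patches by a k-NN
#' majority vote among the remaining trusted patches.  Ties (even `k`)
#' resolve toward keeping the original label, making the editor
#' conservative.
#'
#' @param pset labeled `patch_set`.
#' @param features raw descriptor matrix from [extract_features()].
#' @param cfg a [dknn_config()].
#' @return integer vector of edited labels (one per patch).
#' @export
dknn_refine <- function(pset, features, cfg = dknn_config()) {
  n <- nrow(pset)
  if (cfg$k >= n) stop_config("k must be smaller than the number of patches")
  lab <- pset$label
  if (anyNA(lab)) stop_config("patch labels are unset")
  std <- apply_scaler(features, feature_scaler(features))
  D <- as.matrix(stats::dist(std))
  diag(D) <- Inf
  nn_idx <- t(apply(D, 1, order))[, seq_len(cfg$k), drop = FALSE]
  flagged <- logical(n)
  for (i in seq_len(n)) {
    maj <- vote(lab[nn_idx[i, ]], tie = lab[i])
    flagged[i] <- maj != lab[i]
  }
  trusted <- which(!flagged)
  pool <- trusted
  if (length(trusted) < cfg$k) {
    warning("fewer trusted patches than k; voting over all patches")
    pool <- seq_len(n)
  }
  out <- lab
  for (i in which(flagged)) {
    cand <- setdiff(pool, i)
    nb <- cand[order(D[i, cand])[seq_len(min(cfg$k, length(cand)))]]
    out[i] <- vote(lab[nb], tie = lab[i])
  }
  out
}

# Ridge logistic head on frozen descriptors.
fit_ridge_head <- function(x, y, lambda) {
  glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                 standardize = TRUE)
}

predict_ridge_head <- function(fit, x, lambda) {
  as.vector(predict(fit, newx = x, s = lambda, type = "response"))
}

#' Two-round rank pruning of noisy patch labels
#'
#' Round one fits a binary patch classifier by stratified n-fold
#' cross-validation, giving every patch an out-of-fold probability score.
#' Untrusted patches are pruned by the confident-example rule:
#' labeled-negative patches scoring above the mean score of the
#' labeled-positive pool, and labeled-positive patches scoring below the
#' mean score of the labeled-negative pool.  Round two retrains on the
#' remaining patches and emits that classifier's scores for all patches.
#'
#' @param pset labeled `patch_set`.
#' @param features raw descriptor matrix.
#' @param cfg a [rank_prune_config()].
#' @return the `patch_set` with `score` filled by the second-round
#'   classifier; diagnostics (out-of-fold scores, pruning thresholds and the
#'   pruned index set) are attached as attribute `"rank_prune"`.
#' @export
rank_prune_refine <- function(pset, features, cfg = rank_prune_config()) {
  lab <- pset$label
  if (anyNA(lab)) stop_config("patch labels are unset")
  pos <- which(lab == 1L); neg <- which(lab == 0L)
  if (!length(pos) || !length(neg)) stop_config("both classes must be present")
  n <- nrow(pset)

  folds <- integer(n)
  with_stream(cfg$seed, "folds", {
    folds[pos] <- sample(rep_len(seq_len(cfg$n_folds), length(pos)))
    folds[neg] <- sample(rep_len(seq_len(cfg$n_folds), length(neg)))
  })
  oof <- numeric(n)
  for (f in seq_len(cfg$n_folds)) {
    tr <- folds != f
    if (length(unique(lab[tr])) < 2) {
      stop("a cross-validation fold lost one class; use fewer folds")
    }
    fit <- fit_ridge_head(features[tr, , drop = FALSE], lab[tr], cfg$lambda)
    oof[!tr] <- predict_ridge_head(fit, features[!tr, , drop = FALSE], cfg$lambda)
  }

  thr_pos <- mean(oof[pos])  # negatives above this are untrusted
  thr_neg <- mean(oof[neg])  # positives below this are untrusted
  pruned <- c(neg[oof[neg] > thr_pos], pos[oof[pos] < thr_neg])
  keep <- setdiff(seq_len(n), pruned)
  if (!any(lab[keep] == 1L) || !any(lab[keep] == 0L)) {
    stop(sprintf(
      "rank pruning removed an entire class (pruned %d of %d patches; thresholds %.3f/%.3f)",
      length(pruned), n, thr_pos, thr_neg))
  }
  fit2 <- fit_ridge_head(features[keep, , drop = FALSE], lab[keep], cfg$lambda)
  pset$score <- predict_ridge_head(fit2, features, cfg$lambda)
  attr(pset, "rank_prune") <- list(oof = oof, pruned = sort(pruned),
                                   thr_pos = thr_pos, thr_neg = thr_neg)
  pset
}
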