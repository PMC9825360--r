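# Multiple-instance predictors over noisy patch pools.
#
# Two bag-level predictors share a trainable embedding head
# h = relu(W1 phi + b1) on top of the frozen patch descriptor phi:
#   * attention: z = sum_i w_i h_i with w = softmax(w_a' tanh(V h_i)),
#     P = logistic(<g, z> + c)      (attention-based MIL pooling)
#   * minet:     P = mean_i logistic(<g, h_i> + c)   (mean instance pooling)
# Both are trained with the focal loss, one Adam step per bag.

#' Training configuration for the MIL predictors
#'
#' @param M number of bags.
#' @param n_j bag size (instances per bag, constant across bags).
#' @param pos_fraction fraction of positive bags (default 0.5, i.e. M/2
#'   positive and M/2 negative).
#' @param lr0 initial Adam learning rate.  The decay schedule halves it every
#'   `decay_interval` bags by default.
#' @param decay_factor,decay_interval step-decay: the learning rate at bag
#'   `j` is `lr0 * decay_factor^((j-1) %/% decay_interval)`.
#' @param d_h embedding dimension of the trainable head.
#' @param d_a attention dimension.
#' @param eps_clamp probability clamp inside logs.
#' @param seed integer seed controlling bag sampling and parameter init.
#' @return a `train_config` list.
#' @export
train_config <- function(M = 1000, n_j = 10, pos_fraction = 0.5,
                         lr0 = 2e-3, decay_factor = 0.5, decay_interval = 100,
                         d_h = 128, d_a = 64, eps_clamp = 1e-7, seed = 1) {
  if (!is_count(M) || !is_count(n_j)) stop_config("M and n_j must be positive integers")
  if (lr0 <= 0) stop_config("lr0 must be positive")
  structure(list(M = M, n_j = n_j, pos_fraction = pos_fraction, lr0 = lr0,
                 decay_factor = decay_factor, decay_interval = decay_interval,
                 d_h = d_h, d_a = d_a, eps_clamp = eps_clamp, seed = seed),
            class = "train_config")
}

#' Learning rate after a number of bags
#'
#' @param cfg a [train_config()].
#' @param bags_done number of bags already processed.
#' @return the learning rate used for the next bag.
#' @export
lr_at <- function(cfg, bags_done) {
  cfg$lr0 * cfg$decay_factor^(bags_done %/% cfg$decay_interval)
}

#' Construct MIL bags from the labeled patch pools
#'
#' Positive bags draw their instances i.i.d. uniformly with replacement from
#' S_P, negative bags from S_N; a bag's label is therefore shared by
#' construction with all its instances' noisy labels.  Bag order is shuffled.
#'
#' @param pset a labeled `patch_set`.
#' @param M number of bags.
#' @param n_j instances per bag.
#' @param pos_fraction fraction of positive bags.
#' @param seed integer seed.
#' @return list of bags; each bag is `list(ids, label, slide)` with `ids`
#'   indexing rows of `pset`.
#' @export
build_bags <- function(pset, M, n_j, pos_fraction = 0.5, seed = 1) {
  pools <- patch_pools(pset)
  if (!length(pools$positive) || !length(pools$negative)) {
    stop_config("both S_P and S_N must be non-empty to build bags")
  }
  n_pos <- round(pos_fraction * M)
  with_stream(seed, "bags", {
    bags <- vector("list", M)
    for (j in seq_len(M)) {
      if (j <= n_pos) {
        bags[[j]] <- list(ids = sample(pools$positive, n_j, replace = TRUE),
                          label = 1L, slide = 1L)
      } else {
        bags[[j]] <- list(ids = sample(pools$negative, n_j, replace = TRUE),
                          label = 0L, slide = 1L)
      }
    }
    bags <- bags[sample.int(M)]
  })
  bags
}

#' Focal-loss modulation exponent schedule
#'
#' `gamma = 5` while the predicted positive-class probability lies in
#' `[0, 0.2)` and `gamma = 3` on `[0.2, 1]`.
#'
#' @param p predicted probability of the positive class.
#' @return gamma, vectorized over `p`.
#' @export
focal_gamma <- function(p) ifelse(p < 0.2, 5, 3)

#' Focal loss for a bag prediction
#'
#' `L = -( Y (1-P)^gamma log P + (1-Y) P^gamma log(1-P) )`, with `P` clamped
#' away from 0 and 1 inside the logs.  With `gamma = 0` this is the binary
#' cross-entropy.
#'
#' @param Y bag label, 0 or 1 (vectorized).
#' @param P predicted bag score in `(0, 1)` (vectorized).
#' @param gamma modulation exponent; default selects it from the schedule
#'   [focal_gamma()] evaluated at `P` (treated as a constant, i.e. detached).
#' @param eps probability clamp.
#' @return non-negative loss value(s).
#' @export
focal_loss <- function(Y, P, gamma = NULL, eps = 1e-7) {
  if (is.null(gamma)) gamma <- focal_gamma(P)
  Pc <- clamp(P, eps, 1 - eps)
  -(Y * (1 - Pc)^gamma * log(Pc) + (1 - Y) * Pc^gamma * log(1 - Pc))
}

# d focal_loss / d logit at clamped P (gamma detached).
focal_loss_dlogit <- function(Y, P, gamma, eps = 1e-7) {
  Pc <- clamp(P, eps, 1 - eps)
  dLdP <- ifelse(Y == 1,
    gamma * (1 - Pc)^(gamma - 1) * log(Pc) - (1 - Pc)^gamma / Pc,
    -gamma * Pc^(gamma - 1) * log(1 - Pc) + Pc^gamma / (1 - Pc))
  dLdP * Pc * (1 - Pc)
}

#' Attention-based MIL pooling
#'
#' Computes instance weights `w_i = softmax(w_a' tanh(V h_i))` and the bag
#' representation `z = sum_i w_i h_i`.  Weights are non-negative and sum to
#' one; a single instance always receives weight exactly 1.
#'
#' @param h numeric matrix of instance embeddings, one row per instance.
#' @param V attention parameter matrix (`d_a x d_h`).
#' @param w_a attention projection vector (length `d_a`).
#' @return list with `z` (length `d_h`) and `weights` (length `n`).
#' @export
attention_pool <- function(h, V, w_a) {
  if (!is.matrix(h) || nrow(h) < 1) stop_config("h must be a matrix with >= 1 row")
  e <- as.vector(tanh(h %*% t(V)) %*% w_a)
  e <- e - max(e)
  w <- exp(e) / sum(exp(e))
  list(z = as.vector(crossprod(h, w)), weights = w)
}

# --- model -----------------------------------------------------------------

init_mil_params <- function(variant, d_f, cfg) {
  with_stream(cfg$seed, "init", {
    p <- list(
      W1 = matrix(rnorm(cfg$d_h * d_f, sd = sqrt(2 / d_f)), cfg$d_h, d_f),
      b1 = numeric(cfg$d_h),
      g = rnorm(cfg$d_h, sd = sqrt(1 / cfg$d_h)),
      c = 0
    )
    if (variant == "attention") {
      p$V <- matrix(rnorm(cfg$d_a * cfg$d_h, sd = sqrt(1 / cfg$d_h)), cfg$d_a, cfg$d_h)
      p$w_a <- rnorm(cfg$d_a, sd = sqrt(1 / cfg$d_a))
    }
    p
  })
}

# Embedding head on standardized descriptors.
head_embed <- function(params, phi) {
  n <- nrow(phi)
  a1 <- phi %*% t(params$W1) + matrix(params$b1, n, length(params$b1), byrow = TRUE)
  list(a1 = a1, h = pmax(a1, 0))
}

# Forward pass on one bag of standardized descriptors; returns P and the
# intermediates needed for the backward pass.
mil_forward <- function(params, variant, phi) {
  emb <- head_embed(params, phi)
  if (variant == "attention") {
    pool <- attention_pool(emb$h, params$V, params$w_a)
    logit <- sum(params$g * pool$z) + params$c
    P <- logistic(logit)
    list(P = P, h = emb$h, a1 = emb$a1, pool = pool, logit = logit)
  } else {
    s_logit <- as.vector(emb$h %*% params$g) + params$c
    s <- logistic(s_logit)
    P <- mean(s)
    list(P = P, h = emb$h, a1 = emb$a1, s = s, s_logit = s_logit)
  }
}

mil_backward <- function(params, variant, phi, fw, Y, eps) {
  gamma <- focal_gamma(fw$P)
  gr <- list()
  if (variant == "attention") {
    dlogit <- focal_loss_dlogit(Y, fw$P, gamma, eps)
    z <- fw$pool$z; w <- fw$pool$weights; h <- fw$h
    gr$g <- dlogit * z
    gr$c <- dlogit
    dz <- dlogit * params$g                       # d_h
    dh <- outer(w, dz)                            # n x d_h (direct term)
    dw <- as.vector(h %*% dz)                     # n
    de <- w * (dw - sum(w * dw))                  # softmax backprop
    Tn <- tanh(h %*% t(params$V))                 # n x d_a
    gr$w_a <- as.vector(crossprod(Tn, de))
    dT <- outer(de, params$w_a) * (1 - Tn^2)      # n x d_a
    gr$V <- crossprod(dT, h)                      # d_a x d_h
    dh <- dh + dT %*% params$V
  } else {
    dP <- {
      Pc <- clamp(fw$P, eps, 1 - eps)
      ifelse(Y == 1,
        gamma * (1 - Pc)^(gamma - 1) * log(Pc) - (1 - Pc)^gamma / Pc,
        -gamma * Pc^(gamma - 1) * log(1 - Pc) + Pc^gamma / (1 - Pc))
    }
    n <- nrow(phi)
    ds_logit <- dP / n * fw$s * (1 - fw$s)        # n
    gr$g <- as.vector(crossprod(fw$h, ds_logit))
    gr$c <- sum(ds_logit)
    dh <- outer(ds_logit, params$g)
  }
  da1 <- dh * (fw$a1 > 0)
  gr$W1 <- crossprod(da1, phi)
  gr$b1 <- colSums(da1)
  gr
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a MIL predictor on noisily labeled patches
#'
#' Iterates the bags one at a time, taking one Adam optimizer step per bag
#' with the step-decayed learning rate of the configuration.  The
#' convolutional feature extractor stays frozen throughout; only the
#' embedding head, pooling and classifier parameters are trained.  Fully
#' deterministic given `cfg$seed`.
#'
#' @param pset a labeled `patch_set` (or list of them for multi-slide
#'   training, together with `bags` from [build_multislide_bags()]).
#' @param features raw descriptor matrix from [extract_features()] (or list
#'   of matrices, matching `pset`).
#' @param cfg a [train_config()].
#' @param variant `"attention"` or `"minet"`.
#' @param bags optional pre-built bag list; default [build_bags()] with the
#'   configuration's `M`, `n_j`, `pos_fraction` and `seed`.
#' @return an object of class `mil_model` carrying the trained parameters,
#'   the feature scaler (frozen training-set statistics), the variant, and a
#'   training log (`data.frame` of bag index, loss, learning rate).
#' @export
train_mil <- function(pset, features, cfg = train_config(),
                      variant = c("attention", "minet"), bags = NULL) {
  variant <- match.arg(variant)
  if (cfg$M < 1) stop_config("M must be >= 1")
  single <- !is.null(dim(features))
  feat_list <- if (single) list(features) else features
  pset_list <- if (single) list(pset) else pset
  scaler <- feature_scaler(do.call(rbind, feat_list))
  std <- lapply(feat_list, apply_scaler, scaler = scaler)
  if (is.null(bags)) {
    if (!single) stop_config("multi-slide training requires pre-built bags")
    bags <- build_bags(pset_list[[1]], cfg$M, cfg$n_j, cfg$pos_fraction, cfg$seed)
  }
  d_f <- ncol(std[[1]])
  params <- init_mil_params(variant, d_f, cfg)
  state <- adam_init(params)
  log <- data.frame(bag = seq_along(bags), loss = NA_real_, lr = NA_real_)
  for (j in seq_along(bags)) {
    bag <- bags[[j]]
    phi <- std[[bag$slide]][bag$ids, , drop = FALSE]
    fw <- mil_forward(params, variant, phi)
    loss <- focal_loss(bag$label, fw$P, eps = cfg$eps_clamp)
    if (!is.finite(loss)) {
      stop(sprintf("non-finite loss at bag %d (P = %g, label = %d)",
                   j, fw$P, bag$label))
    }
    gr <- mil_backward(params, variant, phi, fw, bag$label, cfg$eps_clamp)
    lr <- lr_at(cfg, j - 1)
    upd <- adam_step(params, gr, state, lr)
    params <- upd$params
    state <- upd$state
    log$loss[j] <- loss
    log$lr[j] <- lr
  }
  structure(list(variant = variant, params = params, scaler = scaler,
                 d_f = d_f, cfg = cfg, log = log),
            class = "mil_model")
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model variant='%s', d_f=%d, d_h=%d, trained on %d bags>\n",
              x$variant, x$d_f, length(x$params$g), nrow(x$log)))
  invisible(x)
}

#' Bag-level score of the attention predictor
#'
#' `P = logistic(<g, z> + c)` with `z` the attention-pooled embedding of the
#' bag's instances.
#'
#' @param model a trained `mil_model` with `variant = "attention"`.
#' @param features raw descriptor rows of the bag's instances.
#' @return score in `(0, 1)`.
#' @export
bag_score_attention <- function(model, features) {
  stopifnot(model$variant == "attention")
  phi <- apply_scaler(rbind(features), model$scaler)
  mil_forward(model$params, "attention", phi)$P
}

#' Bag-level score of the mean-pooling (mi-Net style) predictor
#'
#' The arithmetic mean of the instance-level classifier outputs.
#'
#' @param model a trained `mil_model` with `variant = "minet"`.
#' @param features raw descriptor rows of the bag's instances.
#' @return score in `(0, 1)`.
#' @export
bag_score_minet <- function(model, features) {
  stopifnot(model$variant == "minet")
  phi <- apply_scaler(rbind(features), model$scaler)
  mil_forward(model$params, "minet", phi)$P
}

#' Bag-level score (variant dispatched)
#'
#' @param model a trained `mil_model`.
#' @param features raw descriptor rows of the bag's instances.
#' @return score in `(0, 1)`.
#' @export
bag_score <- function(model, features) {
  if (model$variant == "attention") bag_score_attention(model, features)
  else bag_score_minet(model, features)
}
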