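# A tiny trained model on the shared fixture, reused across blocks.
tiny_models <- local({
  env <- new.env()
  function(variant) {
    if (is.null(env[[variant]])) {
      fx <- small_fixture()
      ps <- simulate_uniform_flip(fx$pset, 0.2, 0.2, seed = 5)
      env[[variant]] <- list(
        model = train_mil(ps, fx$feats, small_train_cfg(M = 120),
                          variant = variant),
        pset = ps, feats = fx$feats
      )
    }
    env[[variant]]
  }
})

test_that("bag construction respects pools, counts and replacement", {
  labels <- rep(c(1L, 0L), c(30, 70))
  ps <- toy_pset(labels, 10, 10)
  bags <- build_bags(ps, M = 1000, n_j = 10, pos_fraction = 0.5, seed = 1)
  expect_length(bags, 1000)
  y <- vapply(bags, `[[`, integer(1), "label")
  expect_equal(sum(y == 1), 500)
  for (b in bags[seq(1, 1000, 97)]) {
    expect_true(all(labels[b$ids] == b$label))   # Y_j = 1 iff X_j subset S_P
    expect_length(b$ids, 10)
  }
  # singleton bags carry their instance's noisy label
  b1 <- build_bags(ps, M = 50, n_j = 1, seed = 2)
  for (b in b1) expect_equal(labels[b$ids], b$label)
  # with replacement: a pool of 2 must repeat inside a 10-instance bag
  ps2 <- toy_pset(rep(c(1L, 0L), c(2, 98)), 10, 10)
  b2 <- build_bags(ps2, M = 20, n_j = 10, pos_fraction = 0.5, seed = 3)
  pos_bags <- Filter(function(b) b$label == 1, b2)
  expect_true(all(vapply(pos_bags, function(b) anyDuplicated(b$ids) > 0,
                         logical(1))))
  # both pools must be non-empty
  expect_error(build_bags(toy_pset(rep(1L, 100), 10, 10), 10, 5),
               class = "lcmil_config_error")
})

test_that("attention pooling weights are a proper softmax average", {
  set.seed(31)
  V <- matrix(rnorm(8 * 5), 8, 5); w_a <- rnorm(8)
  # single instance: weight exactly 1, z = h
  h1 <- matrix(rnorm(5), 1)
  p1 <- attention_pool(h1, V, w_a)
  expect_identical(p1$weights, 1)
  expect_equal(p1$z, as.vector(h1))
  # identical embeddings: uniform weights
  h <- matrix(rep(rnorm(5), each = 6), 6, 5)
  p <- attention_pool(h, V, w_a)
  expect_equal(p$weights, rep(1 / 6, 6))
  expect_equal(p$z, h[1, ])
  # arbitrary bag: matches the direct formula
  h3 <- matrix(rnorm(15), 3, 5)
  p3 <- attention_pool(h3, V, w_a)
  e <- as.vector(w_a %*% tanh(V %*% t(h3)))
  w_direct <- exp(e) / sum(exp(e))
  expect_equal(p3$weights, w_direct)
  expect_equal(p3$z, colSums(h3 * w_direct))
  expect_equal(sum(p3$weights), 1, tolerance = 1e-12)
})

test_that("focal loss matches direct evaluation, reduces to BCE at gamma 0", {
  expect_equal(focal_loss(1, 0.5, gamma = 3), 0.5^3 * log(2))
  expect_equal(focal_loss(1, 0.5, gamma = 3), 0.0866, tolerance = 1e-3)
  for (P in seq(0.05, 0.95, by = 0.1)) {
    for (Y in 0:1) {
      expect_equal(focal_loss(Y, P, gamma = 0),
                   -(Y * log(P) + (1 - Y) * log(1 - P)))
      for (g in c(1, 3, 5)) {
        direct <- -(Y * (1 - P)^g * log(P) + (1 - Y) * P^g * log(1 - P))
        expect_equal(focal_loss(Y, P, gamma = g), direct)
      }
    }
  }
  # schedule
  expect_equal(focal_gamma(c(0, 0.1, 0.1999, 0.2, 0.7, 1)), c(5, 5, 5, 3, 3, 3))
  expect_equal(focal_loss(1, 0.1), focal_loss(1, 0.1, gamma = 5))
  # limits and monotonicity in P for Y = 1
  Ps <- seq(0.01, 0.99, by = 0.01)
  L <- focal_loss(1, Ps, gamma = 3)
  expect_true(all(diff(L) < 0))
  expect_lt(focal_loss(1, 1 - 1e-9), 1e-6)
})

test_that("analytic loss gradients match numeric differentiation", {
  set.seed(7)
  fx <- small_fixture()
  cfg <- train_config(M = 1, n_j = 4, d_h = 16, d_a = 8, seed = 2)
  phi <- lcmil:::apply_scaler(fx$feats[1:4, ], lcmil:::feature_scaler(fx$feats))
  for (variant in c("attention", "minet")) {
    params <- lcmil:::init_mil_params(variant, ncol(phi), cfg)
    for (Y in 0:1) {
      fw <- lcmil:::mil_forward(params, variant, phi)
      gr <- lcmil:::mil_backward(params, variant, phi, fw, Y, 1e-7)
      gamma <- focal_gamma(fw$P)   # gradients hold gamma fixed (detached)
      loss_at <- function(p) {
        focal_loss(Y, lcmil:::mil_forward(p, variant, phi)$P, gamma = gamma)
      }
      eps <- 1e-6
      for (nm in names(gr)) {
        idx <- if (length(params[[nm]]) > 3) c(1, 3) else 1
        for (i in idx) {
          pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
          pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
          num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
          expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
        }
      }
    }
  }
})

test_that("learning-rate decay halves every interval", {
  cfg <- train_config(lr0 = 5e-5, decay_factor = 0.5, decay_interval = 100)
  expect_equal(lr_at(cfg, 0), 5e-5)
  expect_equal(lr_at(cfg, 99), 5e-5)
  expect_equal(lr_at(cfg, 100), 2.5e-5)
  expect_equal(lr_at(cfg, 200), 1.25e-5)
})

test_that("training is deterministic and rejects degenerate configs", {
  fx <- small_fixture()
  ps <- simulate_uniform_flip(fx$pset, 0.2, 0.2, seed = 5)
  cfg <- small_train_cfg(M = 60)
  m1 <- train_mil(ps, fx$feats, cfg, "attention")
  m2 <- train_mil(ps, fx$feats, cfg, "attention")
  probe <- fx$feats[c(1, 17, 200), , drop = FALSE]
  for (i in 1:3) {
    expect_identical(bag_score(m1, probe[i, , drop = FALSE]),
                     bag_score(m2, probe[i, , drop = FALSE]))
  }
  expect_true(all(is.finite(m1$log$loss)))
  expect_error(train_config(M = 0), class = "lcmil_config_error")
})

test_that("bag scores behave: logistic midpoint, mi-Net mean oracle, monotone logit", {
  tm <- tiny_models("minet")
  # mi-Net bag score equals the mean of independently computed instance scores
  ids <- c(3, 40, 117)
  bagP <- bag_score_minet(tm$model, tm$feats[ids, ])
  inst <- vapply(ids, function(i) {
    bag_score_minet(tm$model, tm$feats[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(bagP, mean(inst), tolerance = 1e-12)

  # attention: zero logit gives exactly 0.5 and the logit is monotone
  ta <- tiny_models("attention")
  md <- ta$model
  phi <- lcmil:::apply_scaler(ta$feats[5, , drop = FALSE], md$scaler)
  h <- lcmil:::head_embed(md$params, phi)$h
  z <- as.vector(h)
  p0 <- md$params; p0$g <- z * 0; p0$c <- 0
  expect_identical(lcmil:::mil_forward(p0, "attention", phi)$P, 0.5)
  pbig <- md$params; pbig$g <- z * 50 / max(sum(z^2), 1e-9); pbig$c <- 0
  expect_gt(lcmil:::mil_forward(pbig, "attention", phi)$P, 0.99)
})

test_that("a trained attention model separates lesion from background patches", {
  aucs <- vapply(1:3, function(s) {
    fx <- small_fixture()
    ps <- simulate_uniform_flip(fx$pset, 0.3, 0.3, seed = s)
    model <- train_mil(ps, fx$feats, train_config(M = 400, n_j = 10, seed = s),
                       "attention")
    scored <- score_all_patches(model, ps, fx$feats)
    score_auc(scored$score, ps$true_label)
  }, numeric(1))
  expect_gt(median(aucs), 0.8)
})
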