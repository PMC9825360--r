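test_that("singleton-bag scores are valid, deterministic, and shared by duplicates", {
  fx <- small_fixture()
  ps <- simulate_uniform_flip(fx$pset, 0.2, 0.2, seed = 4)
  model <- train_mil(ps, fx$feats, small_train_cfg(M = 100), "attention")
  scored <- score_all_patches(model, ps, fx$feats)
  expect_true(all(scored$score >= 0 & scored$score <= 1))
  # duplicate descriptor rows get bit-identical scores
  expect_identical(bag_score(model, fx$feats[7, , drop = FALSE]),
                   scored$score[7])
})

test_that("the Otsu threshold is computed on originally-positive scores only", {
  fx <- small_fixture()
  ps <- simulate_uniform_flip(fx$pset, 0.2, 0.2, seed = 4)
  set.seed(8)
  ps$score <- ifelse(ps$label == 1, rbeta(nrow(ps), 5, 2), rbeta(nrow(ps), 2, 5))
  v0 <- otsu_threshold(ps$score[ps$label == 1])
  map <- assemble_score_map(ps)
  ref1 <- lcmil:::threshold_map(ps, map, small_refine_cfg())
  # perturbing S_N scores must not move the threshold
  ps2 <- ps
  ps2$score[ps2$label == 0] <- runif(sum(ps2$label == 0))
  ref2 <- lcmil:::threshold_map(ps2, assemble_score_map(ps2), small_refine_cfg())
  expect_identical(attr(ref1, "v0"), v0)
  expect_identical(attr(ref2, "v0"), v0)
})

test_that("binarize_and_clean thresholds at >= v0 and applies morphology", {
  ps <- toy_pset(rep(0L, 36), 6, 6)
  ps$score <- rep(0, 36)
  map <- assemble_score_map(ps)
  expect_false(any(binarize_and_clean(map, 0.5, refine_config())))
  ps$score <- c(rep(0.7, 18), rep(0.2, 18))
  map2 <- assemble_score_map(ps)
  out <- binarize_and_clean(map2, 0.7, refine_config(min_object_px = 0,
                                                     min_hole_px = 0))
  expect_equal(sum(out), 18)   # score == v0 is foreground
})

test_that("refinement improves the coarse annotation across noise levels", {
  seeds <- 1:5
  for (rho in c(0.1, 0.2, 0.3)) {
    gain <- vapply(seeds, function(s) {
      fx <- small_fixture(s)
      ps <- simulate_uniform_flip(fx$pset, rho, rho, seed = s + 10)
      res <- refine_pset(ps, fx$feats, method = "lc_mil_atten",
                         train_cfg = train_config(M = 400, n_j = 10, seed = s),
                         cfg = small_refine_cfg(),
                         ground_truth_labels = ps$true_label)
      m <- res$metrics
      m$f1[m$mask == "refined"] - m$f1[m$mask == "coarse"]
    }, numeric(1))
    expect_gt(median(gain), 0)
  }
})

test_that("an easy noise-free fixture is recovered almost exactly", {
  fx <- small_fixture()
  ps <- fx$pset   # labels equal the truth
  res <- refine_pset(ps, fx$feats, method = "lc_mil_atten",
                     train_cfg = small_train_cfg(),
                     cfg = refine_config(min_object_px = 25, min_hole_px = 25,
                                         threshold_mode = "fixed",
                                         fixed_threshold = 0.5),
                     ground_truth_labels = ps$true_label)
  expect_gt(res$metrics$f1[res$metrics$mask == "refined"], 0.9)
})

test_that("refinement results are reproducible for a fixed seed", {
  fx <- small_fixture()
  ps <- simulate_uniform_flip(fx$pset, 0.25, 0.25, seed = 6)
  run <- function() {
    refine_pset(ps, fx$feats, method = "lc_mil_minet",
                train_cfg = small_train_cfg(M = 120), cfg = small_refine_cfg(),
                ground_truth_labels = ps$true_label)
  }
  a <- run(); b <- run()
  expect_identical(a$pset$score, b$pset$score)
  expect_identical(a$refined, b$refined)
  expect_identical(a$v0, b$v0)
})

test_that("multi-slide bags never mix slides and support held-out scoring", {
  fx1 <- small_fixture(1)
  fx2 <- small_fixture(2)
  ps1 <- simulate_uniform_flip(fx1$pset, 0.2, 0.2, seed = 1)
  ps2 <- simulate_uniform_flip(fx2$pset, 0.2, 0.2, seed = 2)
  bags <- build_multislide_bags(list(ps1, ps2), M = 500, n_j = 5, seed = 3)
  expect_length(bags, 1000)
  prov <- vapply(bags, `[[`, integer(1), "slide")
  expect_setequal(unique(prov), c(1L, 2L))
  expect_equal(sum(prov == 1), 500)

  # training on two slides, scoring a third without using its labels
  cfg <- train_config(M = 1000, n_j = 5, seed = 3)
  model <- train_mil(list(ps1, ps2), list(fx1$feats, fx2$feats), cfg,
                     "attention", bags = bags)
  fx3 <- small_fixture(3)
  scored <- score_all_patches(model, fx3$pset, fx3$feats)
  expect_gt(score_auc(scored$score, fx3$pset$true_label), 0.8)

  # an unusable slide is skipped with a warning
  ps_bad <- ps1; ps_bad$label <- 0L
  expect_warning(b2 <- build_multislide_bags(list(ps1, ps_bad), M = 10, n_j = 3),
                 "skipped")
  expect_length(b2, 10)
})
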