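#' Post-processing configuration for refined masks
#'
#' @param min_object_px remove 8-connected foreground objects smaller than
#'   this many heat-map-grid pixels (default 100).
#' @param min_hole_px fill background holes smaller than this (default 100).
#' @param threshold_mode `"otsu_on_positives"` (Otsu's threshold computed on
#'   the scores of originally-positive patches only) or `"fixed"`.
#' @param fixed_threshold threshold in `[0, 1]` when `threshold_mode` is
#'   `"fixed"`.
#' @return a `refine_config` list.
#' @export
refine_config <- function(min_object_px = 100, min_hole_px = 100,
                          threshold_mode = c("otsu_on_positives", "fixed"),
                          fixed_threshold = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (min_object_px < 0 || min_hole_px < 0) stop_config("sizes must be >= 0")
  if (threshold_mode == "fixed" &&
      (is.null(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 1)) {
    stop_config("fixed threshold must be in [0, 1]")
  }
  structure(list(min_object_px = min_object_px, min_hole_px = min_hole_px,
                 threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold),
            class = "refine_config")
}

#' Score every patch as a singleton bag
#'
#' At inference each patch is its own one-instance bag, so the bag-level
#' prediction equals the instance-level prediction (for the attention
#' variant the weight of the lone instance is exactly 1 and the score is
#' `logistic(<g, f_psi(x)> + c)`).
#'
#' @param model a trained `mil_model`.
#' @param pset the `patch_set` to score.
#' @param features raw descriptor matrix for `pset`.
#' @return the `patch_set` with its `score` column filled.
#' @export
score_all_patches <- function(model, pset, features) {
  n <- nrow(pset)
  stopifnot(nrow(features) == n)
  sc <- numeric(n)
  for (i in seq_len(n)) {
    sc[i] <- bag_score(model, features[i, , drop = FALSE])
  }
  pset$score <- sc
  pset
}

#' Threshold a score map and clean it with morphology
#'
#' Binarizes at `score >= v0` (lattice cells without a patch count as
#' background), removes small objects, then fills small holes; sizes are in
#' heat-map-grid pixels.
#'
#' @param map a `score_map` from [assemble_score_map()].
#' @param v0 threshold in `[0, 1]`.
#' @param cfg a [refine_config()].
#' @return logical matrix in the heat-map frame.
#' @export
binarize_and_clean <- function(map, v0, cfg = refine_config()) {
  m <- unclass(map)
  m[is.na(m)] <- 0
  mask <- m >= v0
  mask <- remove_small_objects(mask, cfg$min_object_px)
  fill_small_holes(mask, cfg$min_hole_px)
}

#' Build MIL bags from several slides
#'
#' Bags are built per slide exactly as in [build_bags()] (instances of one
#' bag never mix slides), then concatenated and shuffled.  Slides whose
#' positive or negative pool is empty are skipped with a warning.
#'
#' @param psets list of labeled `patch_set`s.
#' @param M bags per slide.
#' @param n_j instances per bag.
#' @param pos_fraction fraction of positive bags per slide.
#' @param seed integer seed.
#' @return list of bags with `slide` recording each bag's slide of origin.
#' @export
build_multislide_bags <- function(psets, M, n_j, pos_fraction = 0.5, seed = 1) {
  stopifnot(length(psets) >= 1)
  all_bags <- list()
  for (s in seq_along(psets)) {
    pools <- patch_pools(psets[[s]])
    if (!length(pools$positive) || !length(pools$negative)) {
      warning(sprintf("slide %d skipped: empty positive or negative pool", s))
      next
    }
    bags <- build_bags(psets[[s]], M, n_j, pos_fraction,
                       seed = derive_seed(seed, "bags") + s)
    bags <- lapply(bags, function(b) { b$slide <- s; b })
    all_bags <- c(all_bags, bags)
  }
  if (!length(all_bags)) stop_config("no slide yielded usable bags")
  with_stream(seed, "order", all_bags <- all_bags[sample.int(length(all_bags))])
  all_bags
}

#' Refine a coarse annotation on one slide
#'
#' The end-to-end label-cleaning pipeline: tissue mask, patch lattice, noisy
#' label assignment from the coarse mask, MIL bag construction and training,
#' singleton-bag re-scoring of every patch, Otsu thresholding on the scores
#' of the originally-positive pool, and morphological cleanup.  The
#' `"dknn"` and `"rank_pruning"` baselines run through the same patching and
#' post-processing; DkNN produces a binary map and therefore skips the Otsu
#' step.
#'
#' @param slide an [slide_image()].
#' @param coarse logical coarse-annotation mask in the slide frame.
#' @param method `"lc_mil_atten"`, `"lc_mil_minet"`, `"dknn"` or
#'   `"rank_pruning"`.
#' @param train_cfg a [train_config()] (MIL methods).
#' @param cfg a [refine_config()].
#' @param patch_size,overlap_fraction patch lattice parameters.
#' @param tissue optional tissue mask; default [compute_tissue_mask_rgb()].
#' @param extractor feature extractor (see [extract_features()]).
#' @param features optional precomputed descriptor matrix for the lattice
#'   (saves recomputation across noise conditions).
#' @param ground_truth optional ground-truth mask; when supplied the result
#'   carries metrics for the coarse and refined masks, both evaluated on the
#'   heat-map grid via the patch-center rule.
#' @param dknn_cfg,rank_cfg baseline configurations ([dknn_config()],
#'   [rank_prune_config()]).
#' @return a `refinement_result`: list with the scored `patch_set`, the
#'   `score_map`, threshold `v0` (NA for DkNN), `refined` mask (heat-map
#'   frame), the fitted model (MIL methods), configuration provenance, and
#'   `metrics` when ground truth was given.
#' @export
refine <- function(slide, coarse,
                   method = c("lc_mil_atten", "lc_mil_minet", "dknn",
                              "rank_pruning"),
                   train_cfg = train_config(), cfg = refine_config(),
                   patch_size = 256, overlap_fraction = 0, tissue = NULL,
                   extractor = cnn_feature_extractor(), features = NULL,
                   ground_truth = NULL,
                   dknn_cfg = dknn_config(), rank_cfg = rank_prune_config()) {
  method <- match.arg(method)
  if (is.null(tissue)) tissue <- compute_tissue_mask_rgb(slide)
  pset <- extract_patch_grid(slide, tissue, patch_size, overlap_fraction)
  pset <- assign_noisy_labels(pset, coarse)
  if (is.null(features)) features <- extract_features(slide, pset, extractor)
  refine_pset(pset, features, method = method, train_cfg = train_cfg,
              cfg = cfg, ground_truth_labels =
                if (is.null(ground_truth)) NULL
                else mask_at_patch_centers(pset, ground_truth),
              dknn_cfg = dknn_cfg, rank_cfg = rank_cfg,
              source_id = slide$source_id)
}

# Core refinement on an already-labeled patch set with precomputed features.
#' Refine an already-labeled patch set
#'
#' Same as [refine()] but starting from a labeled `patch_set` and its
#' descriptor matrix; useful when the noisy labels come from a synthetic
#' noise model rather than a mask, or when features are shared across runs.
#'
#' @param pset labeled `patch_set`.
#' @param features raw descriptor matrix.
#' @param ground_truth_labels optional 0/1 vector of true patch labels.
#' @inheritParams refine
#' @param source_id slide identifier recorded in the result.
#' @return a `refinement_result` (see [refine()]).
#' @export
refine_pset <- function(pset, features,
                        method = c("lc_mil_atten", "lc_mil_minet", "dknn",
                                   "rank_pruning"),
                        train_cfg = train_config(), cfg = refine_config(),
                        ground_truth_labels = NULL,
                        dknn_cfg = dknn_config(), rank_cfg = rank_prune_config(),
                        source_id = "slide") {
  method <- match.arg(method)
  model <- NULL
  v0 <- NA_real_
  if (method %in% c("lc_mil_atten", "lc_mil_minet")) {
    variant <- if (method == "lc_mil_atten") "attention" else "minet"
    model <- train_mil(pset, features, train_cfg, variant)
    pset <- score_all_patches(model, pset, features)
    map <- assemble_score_map(pset)
    refined <- threshold_map(pset, map, cfg)
    v0 <- attr(refined, "v0")
  } else if (method == "rank_pruning") {
    pset <- rank_prune_refine(pset, features, rank_cfg)
    map <- assemble_score_map(pset)
    refined <- threshold_map(pset, map, cfg)
    v0 <- attr(refined, "v0")
  } else {
    new_labels <- dknn_refine(pset, features, dknn_cfg)
    pset$score <- as.numeric(new_labels)
    map <- assemble_score_map(pset)
    # binary map: no Otsu, straight to morphology
    refined <- binarize_and_clean(map, 0.5, cfg)
  }
  attr(refined, "v0") <- NULL
  metrics <- NULL
  if (!is.null(ground_truth_labels)) {
    truth <- ground_truth_labels
    refined_labels <- as.integer(grid_values_at_patches(pset, refined))
    metrics <- rbind(
      cbind(mask = "coarse", metrics_report(pset$label, truth)),
      cbind(mask = "refined", metrics_report(refined_labels, truth))
    )
  }
  structure(list(
    pset = pset, score_map = map, v0 = v0, refined = refined, model = model,
    method = method, config = list(train = train_cfg, refine = cfg),
    source_id = source_id, metrics = metrics
  ), class = "refinement_result")
}

# Otsu (on originally-positive patches' scores) or fixed threshold, then
# morphology.
threshold_map <- function(pset, map, cfg) {
  v0 <- if (cfg$threshold_mode == "fixed") cfg$fixed_threshold
  else otsu_threshold(pset$score[pset$label == 1L])
  out <- binarize_and_clean(map, v0, cfg)
  attr(out, "v0") <- v0
  out
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("<refinement_result '%s' method=%s, %d patches, v0=%s>\n",
              x$source_id, x$method, nrow(x$pset),
              ifelse(is.na(x$v0), "-", sprintf("%.4f", x$v0))))
  if (!is.null(x$metrics)) {
    print(x$metrics[, c("mask", "ppv", "tpr", "f1", "iou")], digits = 3)
  }
  invisible(x)
}
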