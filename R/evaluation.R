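#' Confusion counts of a binary prediction
#'
#' @param pred 0/1 vector of predicted patch labels (positive = lesion).
#' @param truth 0/1 vector of true patch labels, same length.
#' @return named list `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth)) stop_config("length mismatch")
  stopifnot(all(pred %in% 0:1), all(truth %in% 0:1))
  list(
    tp = sum(pred == 1 & truth == 1),
    fp = sum(pred == 1 & truth == 0),
    fn = sum(pred == 0 & truth == 1),
    tn = sum(pred == 0 & truth == 0)
  )
}

#' Segmentation metrics from confusion counts
#'
#' Precision (PPV), recall (TPR), specificity (TNR), negative predictive
#' value (NPV), F1 (harmonic mean of PPV and TPR) and intersection over
#' union.  Ratios with a zero denominator are reported as `NA`.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return one-row `data.frame` with the counts and metrics.
#' @export
metrics_from_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  ppv <- safe(tp, tp + fp)
  tpr <- safe(tp, tp + fn)
  f1 <- if (!is.na(ppv) && !is.na(tpr) && (ppv + tpr) > 0) {
    2 * ppv * tpr / (ppv + tpr)
  } else NA_real_
  data.frame(
    tp = tp, fp = fp, fn = fn, tn = tn,
    ppv = ppv, tpr = tpr,
    tnr = safe(tn, tn + fp), npv = safe(tn, tn + fn),
    f1 = f1, iou = safe(tp, tp + fp + fn)
  )
}

#' Metrics of a prediction against the truth
#'
#' @param pred,truth 0/1 vectors.
#' @return one-row `data.frame` as [metrics_from_counts()].
#' @export
metrics_report <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  metrics_from_counts(cc$tp, cc$fp, cc$fn, cc$tn)
}

#' Summarize per-slide metric reports
#'
#' Metrics are always computed per slide and then aggregated (never from
#' pooled counts): reports are grouped by `(method, condition)` and the mean
#' and sample standard deviation of each metric are returned.  The standard
#' deviation of a single-report group is `NA`.
#'
#' @param reports `data.frame` with columns `method`, `condition` and metric
#'   columns (any of `ppv`, `tpr`, `tnr`, `npv`, `f1`, `iou`).
#' @return `data.frame` with one row per `(method, condition)` and
#'   `<metric>_mean` / `<metric>_sd` columns plus `n_slides`.
#' @export
summarize_reports <- function(reports) {
  stopifnot(nrow(reports) >= 1)
  if (is.null(reports$method)) reports$method <- "method"
  if (is.null(reports$condition)) reports$condition <- "all"
  metric_cols <- intersect(c("ppv", "tpr", "tnr", "npv", "f1", "iou"),
                           names(reports))
  groups <- split(reports, list(reports$method, reports$condition), drop = TRUE)
  rows <- lapply(groups, function(g) {
    out <- data.frame(method = g$method[1], condition = g$condition[1],
                      n_slides = nrow(g))
    for (m in metric_cols) {
      out[[paste0(m, "_mean")]] <- mean(g[[m]], na.rm = TRUE)
      out[[paste0(m, "_sd")]] <- if (nrow(g) > 1) stats::sd(g[[m]], na.rm = TRUE)
      else NA_real_
    }
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$method, res$condition), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Moving average over slides sorted by coarse-annotation quality
#'
#' Sorts the reports by the F1 of the coarse annotation and returns the
#' centered moving average (window `k`) of a chosen metric — the standard
#' view of refinement performance as a function of input noise.
#'
#' @param x numeric vector (already in the desired order), or use
#'   `sort_by` to order first.
#' @param k window size (default 15).
#' @param sort_by optional numeric vector to sort `x` by (ascending).
#' @return numeric vector of the same length; positions where the centered
#'   window is truncated use the available values.
#' @export
moving_average <- function(x, k = 15, sort_by = NULL) {
  if (!is.null(sort_by)) x <- x[order(sort_by)]
  n <- length(x)
  half <- (k - 1) %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + (k - 1 - half))
    mean(x[lo:hi])
  }, numeric(1))
}

#' Area under the ROC curve
#'
#' Rank-based AUC (equivalent to the Wilcoxon statistic) of scores against
#' binary truth; used to judge patch-score quality against ground truth.
#'
#' @param scores numeric vector.
#' @param truth 0/1 vector.
#' @return AUC in `[0, 1]`, `NA` if a class is absent.
#' @export
score_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
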