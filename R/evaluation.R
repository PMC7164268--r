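# Evaluation of support scores against a reference alignment: confusion
# counts, ROC and PR curves, and their AUCs.
#
# Scope rule: only homologies present in the estimated alignment are scored,
# so true-alignment homologies missing from the estimate are not considered.
# A "positive call" is support >= threshold.

#' Score-and-label table for an estimated alignment
#'
#' Joins the estimated alignment's homologies with their support scores and
#' labels each pair by presence in the reference alignment.
#'
#' @param truth Reference alignment (`msa`), homology data frame, or key
#'   vector.
#' @param est Estimated alignment (`msa`), homology data frame, or key
#'   vector.
#' @param scores A `support_annotation` covering all estimated homologies.
#' @return Data frame with columns `key`, `support`, `is_true`.
#' @export
score_labels <- function(truth, est, scores) {
  tk <- as_homology_keys(truth)
  ek <- as_homology_keys(est)
  sk <- homology_keys(scores)
  idx <- match(ek, sk)
  if (anyNA(idx) || anyNA(scores$support[idx]))
    stop("support score missing for some estimated homologies", call. = FALSE)
  data.frame(key = ek, support = scores$support[idx], is_true = ek %in% tk,
             stringsAsFactors = FALSE)
}

#' Confusion counts at a support threshold
#'
#' Over the homologies of the estimated alignment: TP are pairs present in
#' the reference with support >= threshold, FP pairs absent from the
#' reference with support >= threshold, FN reference pairs below threshold,
#' TN non-reference pairs below threshold.
#'
#' @inheritParams score_labels
#' @param threshold Support threshold in `[0, 1]`.
#' @return Named list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(truth, est, scores, threshold) {
  sl <- score_labels(truth, est, scores)
  pos <- sl$support >= threshold
  list(tp = sum(sl$is_true & pos), fp = sum(!sl$is_true & pos),
       fn = sum(sl$is_true & !pos), tn = sum(!sl$is_true & !pos))
}

#' ROC and PR curves from scores and labels
#'
#' One point per distinct score value, plus the empty-call endpoint
#' (threshold above every score). For the PR curve, precision at
#' `tp + fp = 0` is defined as 1. If the negative class is empty the ROC
#' curve is degenerate and a warning is issued.
#'
#' @param scores Numeric support scores.
#' @param labels Logical (or 0/1) reference-membership labels.
#' @return Data frame of curve points: `threshold`, `fpr`, `tpr` for
#'   [roc_curve()]; `threshold`, `recall`, `precision` for [pr_curve()].
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  P <- sum(labels); N <- sum(!labels)
  if (P == 0) stop("ROC requires at least one positive pair", call. = FALSE)
  if (N == 0) warning("no negative pairs; ROC curve is degenerate")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tp <- vapply(thr, function(t) sum(labels & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!labels & scores >= t), numeric(1))
  data.frame(threshold = thr,
             fpr = if (N > 0) fp / N else rep(0, length(thr)),
             tpr = tp / P)
}

#' @rdname roc_curve
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  P <- sum(labels)
  if (P == 0) stop("PR requires at least one positive pair", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tp <- vapply(thr, function(t) sum(labels & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!labels & scores >= t), numeric(1))
  prec <- ifelse(tp + fp == 0, 1, tp / (tp + fp))
  data.frame(threshold = thr, recall = tp / P, precision = prec)
}

#' Area under a curve
#'
#' `method = "trapezoid"` integrates by the trapezoid rule (ROC convention);
#' `method = "step"` uses right-step summation,
#' `sum((x_i - x_{i-1}) * y_i)`, the average-precision-consistent
#' convention for PR curves.
#'
#' @param x,y Curve coordinates in increasing `x` order (e.g. `fpr`/`tpr`
#'   or `recall`/`precision`).
#' @param method `"trapezoid"` or `"step"`.
#' @return Area, in `[0, 1]` for ROC/PR inputs.
#' @export
auc <- function(x, y, method = c("trapezoid", "step")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 2)
  dx <- diff(x)
  switch(method,
         trapezoid = sum(dx * (head(y, -1) + tail(y, -1)) / 2),
         step = sum(dx * tail(y, -1)))
}

#' @rdname auc
#' @param scores,labels Scores and labels, as in [roc_curve()].
#' @export
roc_auc <- function(scores, labels) {
  r <- roc_curve(scores, labels)
  auc(r$fpr, r$tpr, "trapezoid")
}

#' @rdname auc
#' @export
pr_auc <- function(scores, labels) {
  p <- pr_curve(scores, labels)
  auc(p$recall, p$precision, "step")
}

#' Evaluate a support annotation against a reference alignment
#'
#' Applies the scope rule, builds both curves and both AUCs.
#'
#' @inheritParams score_labels
#' @return List with `roc` and `pr` point data frames, `roc_auc`, `pr_auc`,
#'   and `n_pairs`.
#' @export
evaluate_support <- function(truth, est, scores) {
  sl <- score_labels(truth, est, scores)
  list(roc = roc_curve(sl$support, sl$is_true),
       pr = pr_curve(sl$support, sl$is_true),
       roc_auc = roc_auc(sl$support, sl$is_true),
       pr_auc = pr_auc(sl$support, sl$is_true),
       n_pairs = nrow(sl))
}

#' Aggregate AUC over several datasets
#'
#' Either pools all scored pairs into one curve (`"pooled"`) or averages the
#' per-dataset AUCs (`"averaged"`). Both conventions are reasonable for
#' multi-dataset summaries; the choice is exposed because they can differ.
#'
#' @param runs List of lists with elements `scores` and `labels`.
#' @param mode `"pooled"` or `"averaged"`.
#' @param metric `"roc"` or `"pr"`.
#' @return A single AUC value.
#' @export
aggregate_auc <- function(runs, mode = c("pooled", "averaged"),
                          metric = c("roc", "pr")) {
  mode <- match.arg(mode); metric <- match.arg(metric)
  f <- if (metric == "roc") roc_auc else pr_auc
  if (mode == "pooled") {
    s <- unlist(lapply(runs, `[[`, "scores"))
    l <- unlist(lapply(runs, `[[`, "labels"))
    f(s, l)
  } else {
    mean(vapply(runs, function(r) f(r$scores, r$labels), numeric(1)))
  }
}
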