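#' Area under the ROC curve by the Mann-Whitney formulation
#'
#' Computes AUC as the rank statistic
#' `(sum of case ranks - n1 (n1 + 1) / 2) / (n1 n0)`, which counts
#' concordant case/control score pairs with ties weighted 0.5. Equivalent
#' to the trapezoidal integral of the ROC curve produced by
#' [roc_points()].
#'
#' @param scores numeric decision values; higher means more case-like.
#' @param labels factor/character with levels `control` and `case`; both
#'   classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = c("control", "case"))
  n1 <- sum(labels == "case"); n0 <- sum(labels == "control")
  if (n1 == 0 || n0 == 0) stop("both classes are required to compute AUC")
  r <- rank(scores)
  (sum(r[labels == "case"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points over decision-value thresholds
#'
#' One operating point per distinct decision value (threshold rule
#' `score >= t` predicts case), anchored at (0, 0) and (1, 1). Both
#' coordinates are non-decreasing, and the trapezoidal area under the
#' curve equals [auc_mw()] including its tie handling.
#'
#' @inheritParams auc_mw
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = c("control", "case"))
  n1 <- sum(labels == "case"); n0 <- sum(labels == "control")
  if (n1 == 0 || n0 == 0) stop("both classes are required")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == "case") / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == "control") / n0, 0)
  data.frame(threshold = c(Inf, thr, -Inf),
             fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}
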