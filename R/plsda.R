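#' Fit a two-class PLS-DA model
#'
#' Partial least squares discriminant analysis by the NIPALS algorithm:
#' predictors are column-centred and unit-variance scaled, the class is
#' coded +1 (case) / -1 (control) and centred, and components are
#' extracted sequentially with X-deflation. Convergence of each
#' component's score vector is iterated to `tol` (with a single-response
#' Y the iteration converges immediately; non-convergence is flagged with
#' the iteration count rather than silently accepted).
#'
#' Per component `a` the model stores the weight vector `w_a` (unit
#' norm), scores `t_a`, X-loadings `p_a`, the y-loading `b_a`, and the
#' explained Y sum of squares `SSY_a = b_a^2 t_a' t_a` used for VIP
#' weighting.
#'
#' @param X numeric matrix, samples x predictors (no constant columns).
#' @param y factor/character with levels `control` and `case`, both
#'   present.
#' @param A number of components, default 2; must not exceed
#'   `min(n - 1, p)`.
#' @param tol NIPALS convergence tolerance, default 1e-10.
#' @param max_iter NIPALS iteration cap per component, default 500.
#' @return An object of class `plsda_fit` with `weights`, `scores`,
#'   `loadings`, `y_loadings`, `ssy`, `center`, `scale`, `y_mean`,
#'   `iterations`, `converged`, `A`.
#' @export
fit_plsda <- function(X, y, A = 2, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = c("control", "case"))
  if (anyNA(y)) stop("labels must be 'control' or 'case'")
  if (nlevels(droplevels(y)) < 2) stop("both classes are required")
  n <- nrow(X); p <- ncol(X)
  if (A > min(n - 1, p)) stop("A cannot exceed min(n - 1, p)")
  st <- standardize_fit(X)
  if (any(st$scale == 1 & apply(X, 2, stats::sd) == 0))
    stop("constant predictor column(s)")
  Xa <- standardize_apply(X, st)
  y0 <- ifelse(y == "case", 1, -1)
  y_mean <- mean(y0)
  ya <- y0 - y_mean
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  b <- numeric(A); ssy <- numeric(A)
  iterations <- integer(A); converged <- logical(A)
  for (a in seq_len(A)) {
    u <- ya
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xa, u)
      w <- w / sqrt(sum(w^2))
      t_a <- drop(Xa %*% w)
      # single-response Y: q is scalar 1, u stays proportional to ya
      if (sqrt(sum((t_a - t_old)^2)) < tol) break
      t_old <- t_a
    }
    iterations[a] <- it
    converged[a] <- it < max_iter
    p_a <- drop(crossprod(Xa, t_a)) / sum(t_a^2)
    b[a] <- sum(ya * t_a) / sum(t_a^2)
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    ssy[a] <- b[a]^2 * sum(t_a^2)
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - b[a] * t_a
  }
  rownames(W) <- rownames(P) <- colnames(X)
  structure(
    list(weights = W, scores = Tm, loadings = P, y_loadings = b, ssy = ssy,
         center = st$center, scale = st$scale, y_mean = y_mean,
         iterations = iterations, converged = converged, A = A,
         residual_X = Xa),
    class = "plsda_fit")
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat(sprintf("<plsda_fit> %d components over %d predictors; SSY %s\n",
              x$A, nrow(x$weights),
              paste(sprintf("%.2f", x$ssy), collapse = " / ")))
  invisible(x)
}

#' Predict from a PLS-DA model
#'
#' @param object a [fit_plsda()] model.
#' @param newdata samples x predictors matrix on the original scale.
#' @param type `"class"` (default) for labels by the sign of the
#'   predicted centred response, or `"response"` for the numeric
#'   prediction.
#' @param ... unused.
#' @return Factor of predicted labels, or numeric vector.
#' @export
predict.plsda_fit <- function(object, newdata, type = c("class", "response"),
                              ...) {
  type <- match.arg(type)
  Xa <- standardize_apply(as.matrix(newdata),
                          list(center = object$center, scale = object$scale))
  yhat <- rep(object$y_mean, nrow(Xa))
  for (a in seq_len(object$A)) {
    t_a <- drop(Xa %*% object$weights[, a])
    yhat <- yhat + object$y_loadings[a] * t_a
    Xa <- Xa - tcrossprod(t_a, object$loadings[, a])
  }
  if (type == "response") return(yhat)
  factor(ifelse(yhat > 0, "case", "control"), levels = c("control", "case"))
}

#' Variable importance in projection (VIP) scores
#'
#' Cumulative VIP over the model's components:
#' \deqn{VIP_j = \sqrt{ p \sum_a SSY_a (w_{aj} / \|w_a\|)^2 / \sum_a SSY_a }}
#' with `p` the number of predictors and `SSY_a = b_a^2 t_a' t_a` the Y
#' sum of squares explained by component `a`. By construction
#' `sum(VIP^2) = p` exactly. Per-component VIPs (the same formula
#' restricted to one component) are exposed alongside the cumulative
#' score, and predictors at or above the importance threshold are
#' flagged.
#'
#' @param model a [fit_plsda()] model.
#' @param threshold importance threshold, default 0.8.
#' @return A data frame with `predictor`, `vip`, per-component columns
#'   `vip_comp1..A`, and `important` (`vip >= threshold`).
#' @export
vip_scores <- function(model, threshold = 0.8) {
  stopifnot(inherits(model, "plsda_fit"))
  if (sum(model$ssy) <= 0)
    stop("model explains no Y variance; VIP is undefined")
  p <- nrow(model$weights)
  W2 <- model$weights^2  # columns already unit norm
  vip <- sqrt(p * drop(W2 %*% model$ssy) / sum(model$ssy))
  out <- data.frame(predictor = rownames(model$weights) %||%
                      paste0("X", seq_len(p)),
                    vip = vip, stringsAsFactors = FALSE, row.names = NULL)
  for (a in seq_len(model$A))
    out[[paste0("vip_comp", a)]] <- sqrt(p * W2[, a])
  out$important <- out$vip >= threshold
  out
}

#' Cross-validated PLS-DA classification accuracy
#'
#' Stratified k-fold cross-validation of the PLS-DA classifier, with
#' standardisation and model fitting redone inside every fold from the
#' fold-training statistics (the same leakage discipline as the SVM arm).
#'
#' @param X samples x predictors matrix.
#' @param y labels (`control` / `case`).
#' @param A number of components, default 2.
#' @param k number of folds, default 10.
#' @param seed integer seed for fold assignment.
#' @return A list with `accuracy` (pooled over held-out subjects),
#'   `fold_accuracy`, `predictions`.
#' @export
plsda_cv_performance <- function(X, y, A = 2, k = 10, seed = 1) {
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = c("control", "case"))
  folds <- make_stratified_folds(y, k, derive_seed(seed, "plsdacv"))
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_plsda(X[tr, , drop = FALSE], y[tr],
                     A = min(A, sum(tr) - 1, ncol(X)))
    pr <- predict(fit, X[!tr, , drop = FALSE])
    pred[!tr] <- pr
    fold_acc[f] <- mean(pr == y[!tr])
  }
  list(accuracy = mean(pred == y), fold_accuracy = fold_acc,
       predictions = pred)
}
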