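standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$center), 2, st$scale, `/`)
}

# Case-oriented decision values: higher = more case-like, regardless of
# which class libsvm happened to treat as positive.
svm_scores <- function(model, Xs) {
  pr <- stats::predict(model, Xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  s <- dv[, 1]
  if (first == "case") s else -s
}

# k-fold CV accuracy of an RBF-SVM at fixed hyperparameters, with
# per-fold standardisation from the fold-training statistics.
svm_cv_accuracy <- function(X, y, folds, cost, gamma) {
  k <- max(folds)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    st <- standardize_fit(X[tr, , drop = FALSE])
    m <- e1071::svm(standardize_apply(X[tr, , drop = FALSE], st),
                    droplevels(y[tr]), kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
    pred <- stats::predict(m, standardize_apply(X[!tr, , drop = FALSE], st))
    acc[f] <- mean(as.character(pred) == as.character(y[!tr]))
  }
  acc
}

#' Train the final SVM on the consensus edges
#'
#' Fits the band's final classifier: an RBF-kernel SVM on the consensus
#' edge set, with per-feature z-standardisation from training statistics
#' and hyperparameters chosen by a small grid search (`cost_grid` x
#' `gamma_grid`) scored by stratified k-fold CV accuracy on the training
#' set. The reported internal CV accuracy (mean and SD over folds) and
#' the support-vector count describe the chosen configuration; the model
#' itself is refit on the full training set.
#'
#' An empty consensus yields an explicit no-signal result (class
#' `final_svm` with `no_signal = TRUE`) rather than an error, so the
#' pipeline can continue and report chance-level evaluation.
#'
#' @param dataset the training [connectome_dataset()].
#' @param edges consensus edge ids (positions in the full edge index).
#' @param control a [pipeline_control()].
#' @param seed integer seed for fold assignment.
#' @return An object of class `final_svm`: `model`, standardisation
#'   (`center`, `scale`), `edges`, `cost`, `gamma`, `cv_fold_accuracy`,
#'   `cv_mean`, `cv_sd`, `n_support_vectors`, `grid` (all configurations
#'   with their CV means), `no_signal`.
#' @export
train_final_svm <- function(dataset, edges, control = pipeline_control(),
                            seed = 1) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  if (length(edges) == 0) {
    return(structure(list(no_signal = TRUE, edges = integer(0),
                          cv_fold_accuracy = numeric(0), cv_mean = NA_real_,
                          cv_sd = NA_real_, n_support_vectors = 0L),
                     class = "final_svm"))
  }
  ds <- subset_edges(dataset, edges)
  X <- ds$X; y <- ds$labels
  p <- ncol(X)
  gamma_grid <- control$gamma_grid %||% unique(c(1 / p, 0.01, 0.1))
  grid <- expand.grid(cost = control$cost_grid, gamma = gamma_grid)
  folds <- make_stratified_folds(y, control$k_folds, derive_seed(seed, "svmcv"))
  grid$cv_mean <- NA_real_
  accs <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    accs[[g]] <- svm_cv_accuracy(X, y, folds, grid$cost[g], grid$gamma[g])
    grid$cv_mean[g] <- mean(accs[[g]])
  }
  best <- which.max(grid$cv_mean) # ties: first configuration in grid order
  st <- standardize_fit(X)
  model <- e1071::svm(standardize_apply(X, st), y, kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best],
                      scale = FALSE)
  structure(
    list(no_signal = FALSE, model = model, center = st$center,
         scale = st$scale, edges = ds$edge_ids,
         cost = grid$cost[best], gamma = grid$gamma[best],
         cv_fold_accuracy = accs[[best]],
         cv_mean = mean(accs[[best]]), cv_sd = stats::sd(accs[[best]]),
         n_support_vectors = sum(model$nSV), grid = grid, folds = folds),
    class = "final_svm")
}

#' @export
print.final_svm <- function(x, ...) {
  if (x$no_signal) {
    cat("<final_svm> no-signal (empty consensus)\n")
  } else {
    cat(sprintf("<final_svm> %d edges, C = %g, gamma = %g, internal CV accuracy %.2f +/- %.2f, %d support vectors\n",
                length(x$edges), x$cost, x$gamma, x$cv_mean, x$cv_sd,
                x$n_support_vectors))
  }
  invisible(x)
}

#' Label-permutation significance test of the final model
#'
#' Refits the final model configuration (same consensus edges, same
#' hyperparameters, same internal CV protocol) on `B` datasets with
#' labels permuted within the training set, and compares the observed
#' internal CV accuracy against the null distribution with the add-one
#' convention `p = (1 + #\{null >= observed\}) / (B + 1)`. With the
#' default `B = 99`, a model beating every permutation attains the floor
#' p = 0.01.
#'
#' @param dataset the training [connectome_dataset()].
#' @param edges consensus edge ids.
#' @param fit the [train_final_svm()] result whose configuration is
#'   tested.
#' @param control a [pipeline_control()] (supplies `B` and `k_folds`).
#' @param seed integer seed for the permutation draws.
#' @return A list of class `permutation_test` with `observed`,
#'   `null_accuracy` (length `B`), `p`, `B`.
#' @export
permutation_test <- function(dataset, edges, fit,
                             control = pipeline_control(), seed = 1) {
  stopifnot(inherits(dataset, "connectome_dataset"),
            inherits(fit, "final_svm"))
  if (control$B < 1) stop("B must be >= 1")
  if (fit$no_signal) stop("cannot permutation-test a no-signal model")
  ds <- subset_edges(dataset, edges)
  X <- ds$X
  observed <- fit$cv_mean
  null_acc <- numeric(control$B)
  for (b in seq_len(control$B)) {
    set.seed(derive_seed(seed, "perm", b))
    yb <- sample(ds$labels)
    folds <- make_stratified_folds(yb, control$k_folds,
                                   derive_seed(seed, "permfolds", b))
    null_acc[b] <- mean(svm_cv_accuracy(X, yb, folds, fit$cost, fit$gamma))
  }
  structure(
    list(observed = observed, null_accuracy = null_acc,
         p = (1 + sum(null_acc >= observed)) / (control$B + 1),
         B = control$B),
    class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> observed %.3f vs %d permutations, p = %.4g\n",
              x$observed, x$B, x$p))
  invisible(x)
}

#' Evaluate the final model on the external test set
#'
#' Applies the training standardisation and the final SVM to the held-out
#' participants and summarises performance as a ROC curve over
#' decision-value thresholds and the Mann-Whitney AUC (ties counted 0.5).
#' A no-signal model emits constant decision values, i.e. a diagonal ROC
#' and AUC 0.5.
#'
#' @param fit a [train_final_svm()] result.
#' @param dataset the test [connectome_dataset()] (participants disjoint
#'   from training; both classes present).
#' @return An object of class `classifier_evaluation`: `roc` (data frame
#'   `threshold`, `fpr`, `tpr`), `auc`, `scores`, `labels`, `no_signal`.
#' @export
evaluate_test <- function(fit, dataset) {
  stopifnot(inherits(fit, "final_svm"), inherits(dataset, "connectome_dataset"))
  y <- dataset$labels
  if (nlevels(droplevels(y)) < 2) stop("test set must contain both classes")
  if (fit$no_signal) {
    scores <- rep(0, nrow(dataset$X))
  } else {
    ds <- subset_edges(dataset, fit$edges)
    Xs <- standardize_apply(ds$X, list(center = fit$center, scale = fit$scale))
    scores <- svm_scores(fit$model, Xs)
  }
  names(scores) <- dataset$subject_ids
  structure(
    list(roc = roc_points(scores, y), auc = auc_mw(scores, y),
         scores = scores, labels = y, no_signal = fit$no_signal),
    class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("<classifier_evaluation> AUC %.3f on %d test subjects%s\n",
              x$auc, length(x$scores),
              if (x$no_signal) " (no-signal model)" else ""))
  invisible(x)
}
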