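#' Cross-validated recursive random-forest feature selection (CV-SVM-rRF-FS)
#'
#' The core nested feature-selection procedure. The training set is
#' partitioned into `k_folds` stratified folds; within each fold's
#' training portion the univariate screen is recomputed (by default -
#' `filter_scope = "train"` - so held-out fold subjects never influence
#' the candidate set) and [rrf_fs()] prunes the candidates to the
#' OOB-optimal subset. Each fold also fits an RBF-SVM on its selected
#' edges and records its accuracy on the held-out fold. The final
#' selection is the consensus of the `k_folds` fold-level selections:
#' edges selected in at least `consensus_min` folds.
#'
#' @param dataset the training [connectome_dataset()] (must never contain
#'   test subjects).
#' @param control a [pipeline_control()].
#' @param seed integer seed.
#' @return An object of class `feature_selection_result`: `fold_selected`
#'   (list of global edge-id vectors), `fold_paths` (OOB trajectories),
#'   `fold_accuracy`, `frequency` (data frame `edge`, `n_folds` for every
#'   edge ever selected), `consensus` (edge ids), `k`, `input_space`.
#' @export
cv_svm_rrf_fs <- function(dataset, control = pipeline_control(), seed = 1) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  y <- dataset$labels
  k <- control$k_folds
  folds <- make_stratified_folds(y, k, derive_seed(seed, "cvfs"))
  cand_full <- NULL
  if (control$filter_scope == "full") {
    uni <- edge_ttest(dataset, alpha = control$alpha, adjust = control$adjust)
    cand_full <- uni$edge[uni$significant]
  }
  fold_selected <- vector("list", k)
  fold_paths <- vector("list", k)
  fold_accuracy <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr_rows <- which(folds != f)
    ds_tr <- subset_subjects(dataset, dataset$subject_ids[tr_rows])
    cand <- if (control$filter_scope == "train") {
      uni_f <- edge_ttest(ds_tr, alpha = control$alpha, adjust = control$adjust)
      uni_f$edge[uni_f$significant]
    } else cand_full
    if (length(cand) == 0) {
      fold_selected[[f]] <- integer(0)
      next
    }
    if (length(cand) == 1) {
      fold_selected[[f]] <- cand
    } else {
      cols <- match(cand, ds_tr$edge_ids)
      fs <- rrf_fs(ds_tr$X[, cols, drop = FALSE], ds_tr$labels, control,
                   seed = derive_seed(seed, "rrf", f))
      fold_selected[[f]] <- cand[fs$selected]
      fold_paths[[f]] <- fs$path
    }
    # fold-level SVM accuracy on the held-out fold
    sel_cols <- match(fold_selected[[f]], dataset$edge_ids)
    st <- standardize_fit(dataset$X[tr_rows, sel_cols, drop = FALSE])
    m <- e1071::svm(
      standardize_apply(dataset$X[tr_rows, sel_cols, drop = FALSE], st),
      droplevels(y[tr_rows]), kernel = "radial",
      cost = control$fold_svm_cost, gamma = 1 / length(sel_cols),
      scale = FALSE)
    held <- which(folds == f)
    pred <- stats::predict(
      m, standardize_apply(dataset$X[held, sel_cols, drop = FALSE], st))
    fold_accuracy[f] <- mean(as.character(pred) == as.character(y[held]))
  }
  all_sel <- unlist(fold_selected)
  freq <- if (length(all_sel)) {
    tb <- table(all_sel)
    data.frame(edge = as.integer(names(tb)), n_folds = as.integer(tb))
  } else data.frame(edge = integer(0), n_folds = integer(0))
  consensus <- freq$edge[freq$n_folds >= control$consensus_min]
  structure(
    list(fold_selected = fold_selected, fold_paths = fold_paths,
         fold_accuracy = fold_accuracy, frequency = freq,
         consensus = sort(consensus), k = k,
         input_space = if (control$filter_scope == "train")
           "significant_edges" else "significant_edges_full_sample",
         folds = folds),
    class = "feature_selection_result")
}

#' @export
print.feature_selection_result <- function(x, ...) {
  cat(sprintf("<feature_selection_result> %d folds, consensus %d edges (>= %s folds), mean fold accuracy %.2f\n",
              x$k, length(x$consensus),
              if (nrow(x$frequency)) max(x$frequency$n_folds) else "-",
              mean(x$fold_accuracy, na.rm = TRUE)))
  invisible(x)
}

#' End-to-end classification pipeline for one band
#'
#' The supervised arm of the framework, run on one band's dataset:
#' stratified 80/20 participant split, [cv_svm_rrf_fs()] on the training
#' set, [train_final_svm()] on the consensus edges, the label-permutation
#' significance test (when `control$B > 0`), and external ROC/AUC
#' evaluation on the held-out participants. All randomness derives from
#' `seed`; a given seed and control always reproduce the identical
#' result.
#'
#' @param dataset a [connectome_dataset()].
#' @param control a [pipeline_control()].
#' @param seed integer seed.
#' @param permute run the permutation test (default `TRUE`; it is also
#'   skipped when the consensus is empty or `control$B == 0`).
#' @return An object of class `pipeline_result`: `split`, `fs`, `fit`,
#'   `permutation` (or `NULL`), `evaluation`, `band`, `seed`.
#' @export
run_pipeline <- function(dataset, control = pipeline_control(), seed = 1,
                         permute = TRUE) {
  split <- stratified_split(dataset, control$test_fraction, seed)
  train <- subset_subjects(dataset, split$train_ids)
  test <- subset_subjects(dataset, split$test_ids)
  fs <- cv_svm_rrf_fs(train, control, seed)
  fit <- train_final_svm(train, fs$consensus, control, seed)
  perm <- NULL
  if (permute && control$B > 0 && !fit$no_signal) {
    perm <- permutation_test(train, fs$consensus, fit, control, seed)
  }
  structure(
    list(split = split, fs = fs, fit = fit, permutation = perm,
         evaluation = evaluate_test(fit, test),
         band = dataset$band, seed = as.integer(seed)),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> band %s: consensus %d edges, internal CV %.2f +/- %.2f, %s, external AUC %.2f\n",
              x$band, length(x$fs$consensus),
              x$fit$cv_mean, x$fit$cv_sd,
              if (is.null(x$permutation)) "no permutation test"
              else sprintf("permutation p = %.3g", x$permutation$p),
              x$evaluation$auc))
  invisible(x)
}
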