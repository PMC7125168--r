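#' Pipeline configuration
#'
#' Every tunable knob of the analysis pipeline in one place, with
#' defaults matching the emulated study design: raw-p screening at
#' alpha = 0.01, 80/20 participant split, 10-fold cross-validation,
#' recursive random-forest elimination (1000 trees, drop the
#' lowest-importance 20% per round, floor of 2 features, minimal-OOB
#' selection), consensus at >= 5 of 10 folds, RBF-SVM with a small
#' C/gamma grid, 99 label permutations, 2 PLS components and a VIP
#' threshold of 0.8.
#'
#' @param alpha univariate screening threshold on the raw p-value.
#' @param adjust multiplicity handling for the screen: `"none"` (default)
#'   or `"BH"`.
#' @param test_fraction held-out participant fraction for the external
#'   test set.
#' @param k_folds number of cross-validation folds.
#' @param filter_scope `"train"` (default): the univariate screen feeding
#'   feature selection is recomputed inside each fold's training portion
#'   (leakage-safe); `"full"`: screen once on the whole training set.
#' @param ntree random-forest size per elimination round.
#' @param drop_fraction fraction of lowest-importance features dropped
#'   per elimination round.
#' @param floor_features smallest feature-set size on the elimination
#'   path.
#' @param consensus_min minimum number of folds (out of `k_folds`) an
#'   edge must be selected in to enter the consensus list.
#' @param fold_svm_cost SVM cost used for the per-fold accuracy models
#'   inside CV-SVM-rRF-FS.
#' @param cost_grid,gamma_grid final-model hyperparameter grids;
#'   `gamma_grid = NULL` means `c(1/p, 0.01, 0.1)` with `p` the number
#'   of consensus edges.
#' @param B number of label permutations for the significance test
#'   (`0` disables it).
#' @param plsda_components number of PLS-DA components.
#' @param vip_threshold VIP importance threshold.
#' @param n_components number of principal components reported per stage.
#' @return A list of class `pipeline_control`.
#' @export
pipeline_control <- function(alpha = 0.01, adjust = "none",
                             test_fraction = 0.2, k_folds = 10,
                             filter_scope = c("train", "full"),
                             ntree = 1000, drop_fraction = 0.2,
                             floor_features = 2, consensus_min = 5,
                             fold_svm_cost = 1,
                             cost_grid = c(0.1, 1, 10), gamma_grid = NULL,
                             B = 99, plsda_components = 2,
                             vip_threshold = 0.8, n_components = 2) {
  filter_scope <- match.arg(filter_scope)
  stopifnot(alpha > 0, alpha <= 1, test_fraction > 0, test_fraction < 1,
            k_folds >= 2, ntree >= 1, drop_fraction > 0, drop_fraction < 1,
            floor_features >= 1, consensus_min >= 1, B >= 0)
  structure(
    list(alpha = alpha, adjust = adjust, test_fraction = test_fraction,
         k_folds = as.integer(k_folds), filter_scope = filter_scope,
         ntree = as.integer(ntree), drop_fraction = drop_fraction,
         floor_features = as.integer(floor_features),
         consensus_min = as.integer(consensus_min),
         fold_svm_cost = fold_svm_cost, cost_grid = cost_grid,
         gamma_grid = gamma_grid, B = as.integer(B),
         plsda_components = as.integer(plsda_components),
         vip_threshold = vip_threshold,
         n_components = as.integer(n_components)),
    class = "pipeline_control")
}

#' Write / read a pipeline configuration
#'
#' Plain-JSON serialisation of a [pipeline_control()] with a schema
#' version tag, so a run's configuration can be archived next to its
#' outputs and replayed exactly.
#'
#' @param control a [pipeline_control()].
#' @param path JSON file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_control`.
#' @export
write_pipeline_config <- function(control, path) {
  stopifnot(inherits(control, "pipeline_control"))
  jsonlite::write_json(c(list(schema = "megml-config-1"),
                         unclass(control)),
                       path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$schema <- NULL
  if (length(raw$gamma_grid) == 0) raw$gamma_grid <- NULL
  do.call(pipeline_control, raw)
}
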