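#' Recursive random-forest feature selection
#'
#' Iterative backward elimination guided by out-of-bag (OOB) error: fit a
#' random forest with permutation importance, record the OOB error of the
#' current feature set, drop the `drop_fraction` lowest-importance
#' features, and repeat down to `floor_features`. The selected set is the
#' point on the elimination path with minimal OOB error; ties are broken
#' in favour of the smaller set.
#'
#' @param X numeric matrix (samples x features, >= 2 features).
#' @param y factor with both classes present.
#' @param control a [pipeline_control()] supplying `ntree`,
#'   `drop_fraction` and `floor_features`.
#' @param seed integer seed; forests are seeded per elimination round so
#'   the whole path is reproducible.
#' @return A list of class `rrf_fs` with `selected` (column indices into
#'   `X`), `path` (data frame: round, n_features, oob_error) and
#'   `features_by_round`.
#' @export
rrf_fs <- function(X, y, control = pipeline_control(), seed = 1) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  if (ncol(X) < 2) stop("at least 2 features are required")
  if (nlevels(y) < 2 || min(table(y)) < 2)
    stop("both classes with >= 2 samples are required")
  current <- seq_len(ncol(X))
  rounds <- list(); feats <- list()
  r <- 0
  repeat {
    r <- r + 1
    set.seed(derive_seed(seed, "rrf", r))
    rf <- randomForest::randomForest(
      x = X[, current, drop = FALSE], y = y,
      ntree = control$ntree, importance = TRUE)
    oob <- rf$err.rate[control$ntree, "OOB"]
    rounds[[r]] <- data.frame(round = r, n_features = length(current),
                              oob_error = unname(oob))
    feats[[r]] <- current
    if (length(current) <= control$floor_features) break
    imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
    n_drop <- max(1L, floor(control$drop_fraction * length(current)))
    n_keep <- max(control$floor_features, length(current) - n_drop)
    keep <- order(imp, decreasing = TRUE)[seq_len(n_keep)]
    current <- sort(current[keep])
  }
  path <- do.call(rbind, rounds)
  # minimal OOB error; ties resolved toward the smallest feature set
  best <- which(path$oob_error == min(path$oob_error))
  best <- best[which.min(path$n_features[best])]
  structure(
    list(selected = feats[[best]], path = path, features_by_round = feats),
    class = "rrf_fs")
}

#' @export
print.rrf_fs <- function(x, ...) {
  cat(sprintf("<rrf_fs> %d rounds, selected %d features (OOB %.3f)\n",
              nrow(x$path), length(x$selected),
              min(x$path$oob_error)))
  invisible(x)
}
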