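#' Z-score edge columns
#'
#' Standardises each edge column to mean 0 and sample SD 1. Zero-variance
#' columns become all zeros and are flagged in the `zero_variance`
#' attribute. The `center` and `scale` attributes allow exact
#' de-standardisation.
#'
#' @param x a [connectome_dataset()] or a subjects x edges matrix with at
#'   least 2 rows.
#' @return A numeric matrix with attributes `center`, `scale`,
#'   `zero_variance` (integer column positions).
#' @export
zscore_edges <- function(x) {
  X <- if (inherits(x, "connectome_dataset")) x$X else as.matrix(x)
  if (nrow(X) < 2) stop("at least 2 subjects are required")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  zv <- which(scl == 0)
  scl_use <- ifelse(scl == 0, 1, scl)
  Z <- sweep(sweep(X, 2, ctr), 2, scl_use, `/`)
  Z[, zv] <- 0
  attr(Z, "center") <- ctr
  attr(Z, "scale") <- scl
  attr(Z, "zero_variance") <- zv
  Z
}

#' Two-way hierarchical clustering with label agreement
#'
#' Euclidean distance with Ward linkage (`ward.D2`) on z-scored data, for
#' subjects (and optionally edges). The subject dendrogram is cut at `k`
#' clusters, and cluster-vs-label agreement is reported both as a
#' confusion table and as the narrative metric used in connectome
#' heatmap figures: the number of subjects of each label that fall
#' outside their majority-matched cluster. The adjusted Rand index is
#' included for quantitative tests.
#'
#' @param z z-scored subjects x edges matrix (see [zscore_edges()]).
#' @param labels factor of group labels, one per subject.
#' @param k number of participant clusters to cut (default 2; must not
#'   exceed the number of subjects).
#' @param cluster_edges also build the edge dendrogram (default `TRUE`;
#'   disable for very wide matrices where only the subject structure is
#'   needed).
#' @return An object of class `clustering_report`: list with
#'   `subject_hclust`, `edge_hclust` (or `NULL`), `assignments`,
#'   `confusion` (cluster x label table), `misplaced` (named per-label
#'   counts), `ari`.
#' @export
hierarchical_clusters <- function(z, labels, k = 2, cluster_edges = TRUE) {
  z <- as.matrix(z)
  labels <- factor(labels)
  if (k > nrow(z)) stop("k cannot exceed the number of subjects")
  sh <- stats::hclust(stats::dist(z), method = "ward.D2")
  eh <- if (cluster_edges && ncol(z) >= 2)
    stats::hclust(stats::dist(t(z)), method = "ward.D2") else NULL
  assign <- stats::cutree(sh, k = k)
  confusion <- table(cluster = assign, label = labels)
  # match clusters to labels maximizing diagonal agreement (k = 2: best of
  # the two mappings; general k: greedy by cluster size)
  misplaced <- misplaced_counts(confusion)
  structure(
    list(subject_hclust = sh, edge_hclust = eh, assignments = assign,
         confusion = confusion, misplaced = misplaced,
         ari = mclust::adjustedRandIndex(assign, labels)),
    class = "clustering_report")
}

misplaced_counts <- function(confusion) {
  lab_names <- colnames(confusion)
  k <- nrow(confusion)
  if (k == 1 || length(lab_names) < 2) {
    out <- rep(0L, length(lab_names)); names(out) <- lab_names
    return(out)
  }
  if (k == 2 && length(lab_names) == 2) {
    direct <- confusion[1, 1] + confusion[2, 2]
    crossed <- confusion[1, 2] + confusion[2, 1]
    map <- if (direct >= crossed) c(1L, 2L) else c(2L, 1L)
  } else {
    map <- apply(confusion, 2, which.max)
  }
  out <- integer(length(lab_names)); names(out) <- lab_names
  for (l in seq_along(lab_names))
    out[l] <- sum(confusion[-map[l], l])
  out
}

#' @export
print.clustering_report <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("misplaced: %s; ARI %.3f\n",
              paste(sprintf("%s %d", names(x$misplaced), x$misplaced),
                    collapse = ", "), x$ari))
  invisible(x)
}

#' Principal component summary of a connectome stage
#'
#' PCA (via [stats::prcomp()]) on centred, unscaled input - intended to be
#' run on z-scored data, where scaling is already equalised. Component
#' signs follow a fixed convention (the largest-magnitude loading of each
#' component is positive) so results are reproducible across platforms.
#'
#' @param z subjects x edges matrix (typically from [zscore_edges()]).
#' @param n_components number of components to retain in the score table
#'   (default `min(2, n - 1)`); must not exceed `min(n - 1, n_edges)`.
#' @param stage stage tag, one of `"all_edges"`, `"significant"`,
#'   `"selected"` (or any label).
#' @return An object of class `pca_report`: list with `scores` (n x
#'   n_components), `loadings`, `pct_variance` (all components,
#'   non-increasing, summing to <= 100), `n_components`, `stage`.
#' @export
pca_report <- function(z, n_components = NULL, stage = "all_edges") {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2) stop("at least 2 subjects are required")
  maxc <- min(n - 1, ncol(z))
  if (is.null(n_components)) n_components <- min(2, maxc)
  if (n_components > maxc)
    stop("n_components cannot exceed min(n - 1, n_edges)")
  pr <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  pct <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(a) {
    l <- pr$rotation[, a]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, `*`)[, seq_len(n_components), drop = FALSE]
  loadings <- sweep(pr$rotation, 2, flip, `*`)[, seq_len(n_components), drop = FALSE]
  structure(
    list(scores = scores, loadings = loadings, pct_variance = pct,
         n_components = n_components, stage = stage),
    class = "pca_report")
}

#' @export
print.pca_report <- function(x, ...) {
  cat(sprintf("<pca_report> stage %s: PC1..PC%d explain %s%% of variance\n",
              x$stage, x$n_components,
              paste(sprintf("%.1f", x$pct_variance[seq_len(x$n_components)]),
                    collapse = " / ")))
  invisible(x)
}
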