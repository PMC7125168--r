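#' Per-edge two-sample comparison between case and control
#'
#' Welch two-sample t-test (two-sided, unequal variances) on every edge
#' column, vectorised over the full connectome. Following the screening
#' design this package implements, the significance flag is applied to the
#' raw p-value - no multiple-testing correction by default - to preserve
#' the maximum amount of variance for the downstream feature-selection
#' machinery; Benjamini-Hochberg adjustment is available as an option for
#' reuse.
#'
#' Degenerate edges with zero variance in both groups and zero mean
#' difference report `t = 0, p = 1` (never `NaN`); zero pooled variance
#' with a non-zero difference reports an infinite `t` and `p = 0`. Exact
#' zero mean differences are labelled `"increase"` with `tie = TRUE` so
#' output is deterministic.
#'
#' @param dataset a [connectome_dataset()] with at least 2 subjects per
#'   group.
#' @param alpha raw-p significance threshold, default 0.01.
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjusted p-values (the flag is then applied to the adjusted p).
#' @return An object of class `univariate_result`: a data frame with one
#'   row per edge (`edge`, `region_a`, `region_b`, `mean_case`,
#'   `mean_control`, `t`, `df`, `p`, `direction`, `tie`, `significant`)
#'   and attributes `alpha`, `band`, `adjust`.
#' @export
edge_ttest <- function(dataset, alpha = 0.01, adjust = c("none", "BH")) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  adjust <- match.arg(adjust)
  y <- dataset$labels
  if (min(table(y)) < 2) stop("at least 2 subjects per group are required")
  X1 <- dataset$X[y == "case", , drop = FALSE]
  X0 <- dataset$X[y == "control", , drop = FALSE]
  n1 <- nrow(X1); n0 <- nrow(X0)
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- colSums(sweep(X1, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(X0, 2, m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  diff <- m1 - m0
  tstat <- ifelse(se2 > 0, diff / sqrt(se2), ifelse(diff == 0, 0, Inf * sign(diff)))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)),
               n1 + n0 - 2)
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df),
              ifelse(tstat == 0, 1, 0))
  p[se2 == 0 & diff == 0] <- 1
  p_used <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  idx <- dataset$index
  res <- data.frame(
    edge = dataset$edge_ids,
    region_a = idx$region_names[idx$pairs$i[dataset$edge_ids]],
    region_b = idx$region_names[idx$pairs$j[dataset$edge_ids]],
    mean_case = m1, mean_control = m0,
    t = tstat, df = df, p = p,
    direction = ifelse(diff >= 0, "increase", "decrease"),
    tie = diff == 0,
    significant = p_used < alpha,
    stringsAsFactors = FALSE, row.names = NULL)
  if (adjust == "BH") res$p_adjusted <- p_used
  structure(res, class = c("univariate_result", "data.frame"),
            alpha = alpha, band = dataset$band, adjust = adjust)
}

#' Per-band summary of significant edges
#'
#' The per-band counts of significant edges split by direction, plus the
#' across-band mean and sample SD (denominator `n - 1`) of the significant
#' counts. A single-band input reports SD 0 with `sd_defined = FALSE`.
#'
#' @param results a list of [edge_ttest()] results, one per band.
#' @return A list of class `band_summary` with `table` (data frame: band,
#'   n_significant, n_increase, n_decrease), `mean_significant`,
#'   `sd_significant` and `sd_defined`.
#' @export
summarize_bands <- function(results) {
  if (inherits(results, "univariate_result")) results <- list(results)
  if (length(results) == 0) stop("at least one band result is required")
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "univariate_result"))
    sig <- r[r$significant, , drop = FALSE]
    data.frame(band = attr(r, "band"),
               n_significant = nrow(sig),
               n_increase = sum(sig$direction == "increase"),
               n_decrease = sum(sig$direction == "decrease"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sd_defined <- nrow(tab) > 1
  structure(
    list(table = tab,
         mean_significant = mean(tab$n_significant),
         sd_significant = if (sd_defined) stats::sd(tab$n_significant) else 0,
         sd_defined = sd_defined),
    class = "band_summary")
}

#' @export
print.band_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("significant edges across bands: %.1f +/- %.1f (mean +/- SD%s)\n",
              x$mean_significant, x$sd_significant,
              if (x$sd_defined) "" else "; single band, SD undefined"))
  invisible(x)
}

#' Restrict a dataset to its significant edges
#'
#' @param dataset the [connectome_dataset()] the test was computed on.
#' @param result the matching [edge_ttest()] result.
#' @return A [connectome_dataset()] holding only the significant edges in
#'   their original order. If no edge is significant, a zero-column
#'   object of class `empty_selection` is returned (with the band and the
#'   alpha recorded) so callers can branch explicitly instead of crashing.
#' @export
filter_significant <- function(dataset, result) {
  stopifnot(inherits(dataset, "connectome_dataset"),
            inherits(result, "univariate_result"))
  if (!identical(result$edge, dataset$edge_ids))
    stop("result was not computed on this dataset's edges")
  keep <- result$edge[result$significant]
  if (length(keep) == 0) {
    return(structure(list(band = dataset$band, alpha = attr(result, "alpha"),
                          n_selected = 0L),
                     class = "empty_selection"))
  }
  subset_edges(dataset, keep)
}

#' @export
print.empty_selection <- function(x, ...) {
  cat(sprintf("<empty_selection> band %s: no edges significant at alpha = %g\n",
              x$band, x$alpha))
  invisible(x)
}
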