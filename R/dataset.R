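#' Construct a connectome dataset
#'
#' The universal currency of the pipeline: a subjects-by-edges matrix of
#' wPLI values for one frequency band, with binary group labels, stable
#' subject ids and the edge identities of every column.
#'
#' @param X numeric matrix, subjects in rows, edges in columns, all values
#'   in `[0, 1]`, no missing values.
#' @param labels factor (or character) of group labels with levels
#'   `control` and `case`; both classes must be present.
#' @param band frequency-band name the edges were computed in.
#' @param index the [edge_index()] the columns refer to.
#' @param subject_ids unique subject identifiers (default: rownames of
#'   `X`, or `sub01..`).
#' @param edge_ids integer positions into `index` identifying each column
#'   (default: all edges in canonical order). Subsetting a dataset keeps
#'   the original edge ids so selected-edge lists always refer back to
#'   the full connectome.
#' @return An object of class `connectome_dataset`.
#' @export
connectome_dataset <- function(X, labels, band, index,
                               subject_ids = NULL, edge_ids = NULL) {
  stopifnot(is.matrix(X), inherits(index, "edge_index"))
  if (is.null(edge_ids)) edge_ids <- seq_len(length(index))
  edge_ids <- as.integer(edge_ids)
  if (ncol(X) != length(edge_ids))
    stop("column count must equal the number of edge ids")
  if (any(edge_ids < 1L) || any(edge_ids > length(index)))
    stop("edge ids out of range for the edge index")
  if (anyNA(X)) stop("missing values in X")
  if (min(X) < -1e-9 || max(X) > 1 + 1e-9)
    stop("wPLI values must lie in [0, 1]")
  labels <- factor(as.character(labels), levels = c("control", "case"))
  if (anyNA(labels)) stop("labels must be 'control' or 'case'")
  if (length(labels) != nrow(X)) stop("one label per subject required")
  if (nlevels(droplevels(labels)) < 2L) stop("both label classes must be present")
  if (is.null(subject_ids)) {
    subject_ids <- rownames(X) %||% sprintf("sub%02d", seq_len(nrow(X)))
  }
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (length(subject_ids) != nrow(X)) stop("one id per subject required")
  rownames(X) <- subject_ids
  colnames(X) <- edge_label(edge_ids, index)
  structure(
    list(X = X, labels = labels, band = as.character(band),
         index = index, subject_ids = subject_ids, edge_ids = edge_ids),
    class = "connectome_dataset")
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cat(sprintf("<connectome_dataset> band %s: %d subjects (%d case / %d control) x %d edges\n",
              x$band, nrow(x$X), sum(x$labels == "case"),
              sum(x$labels == "control"), ncol(x$X)))
  invisible(x)
}

#' @export
dim.connectome_dataset <- function(x) dim(x$X)

#' Restrict a dataset to a subset of edges
#'
#' @param dataset a [connectome_dataset()].
#' @param edge_ids edge ids (positions in the full edge index) to keep;
#'   they must be among the dataset's current columns. Original edge order
#'   is preserved.
#' @return A `connectome_dataset` with the selected columns.
#' @export
subset_edges <- function(dataset, edge_ids) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  edge_ids <- as.integer(edge_ids)
  keep <- which(dataset$edge_ids %in% edge_ids)
  if (length(keep) != length(unique(edge_ids)))
    stop("some requested edges are not columns of this dataset")
  connectome_dataset(dataset$X[, keep, drop = FALSE], dataset$labels,
                     dataset$band, dataset$index,
                     subject_ids = dataset$subject_ids,
                     edge_ids = dataset$edge_ids[keep])
}

#' Restrict a dataset to a subset of subjects
#'
#' @param dataset a [connectome_dataset()].
#' @param subject_ids subject identifiers to keep (order preserved as given).
#' @return A `connectome_dataset` with the selected rows.
#' @export
subset_subjects <- function(dataset, subject_ids) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  rows <- match(subject_ids, dataset$subject_ids)
  if (anyNA(rows)) stop("unknown subject id(s)")
  connectome_dataset(dataset$X[rows, , drop = FALSE], dataset$labels[rows],
                     dataset$band, dataset$index,
                     subject_ids = dataset$subject_ids[rows],
                     edge_ids = dataset$edge_ids)
}
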