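#' Number of edges in a full undirected connectome
#'
#' @param n_regions number of atlas regions (>= 2).
#' @return `n_regions * (n_regions - 1) / 2`, the number of unordered
#'   region pairs. For the AAL-90 parcellation this is 4005.
#' @examples
#' edge_count(90) # 4005
#' @export
edge_count <- function(n_regions) {
  if (length(n_regions) != 1L || is.na(n_regions) || n_regions < 2)
    stop("n_regions must be a single value >= 2")
  n_regions <- as.integer(n_regions)
  (n_regions * (n_regions - 1L)) %/% 2L
}

#' Canonical edge index for a region set
#'
#' Builds the canonical bijection between unordered region pairs and edge
#' columns: pairs `(i, j)` with `i < j` (1-based) in lexicographic order,
#' i.e. `(1,2), (1,3), ..., (1,R), (2,3), ...` — the row-wise reading order
#' of the upper triangle. Every matrix vectorisation, edge id and consensus
#' list in the package refers to this order, so edge identities are stable
#' across runs and platforms.
#'
#' @param n_regions number of regions.
#' @param region_names optional character vector of unique, non-empty
#'   region names (defaults to `R1..Rn`; use [aal90_regions()] for the
#'   packaged AAL-90 label set).
#' @return An object of class `edge_index`: a list with `n_regions`,
#'   `pairs` (data.frame with integer columns `i`, `j`), and
#'   `region_names`.
#' @examples
#' idx <- edge_index(4)
#' idx$pairs
#' @export
edge_index <- function(n_regions, region_names = NULL) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (is.null(region_names)) region_names <- paste0("R", seq_len(n_regions))
  region_names <- as.character(region_names)
  if (length(region_names) != n_regions)
    stop("region_names must have length n_regions")
  if (anyDuplicated(region_names) || any(!nzchar(region_names)))
    stop("region_names must be unique and non-empty")
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- sequence((n_regions - 1L):1L) + i
  structure(
    list(n_regions = n_regions,
         pairs = data.frame(i = i, j = j),
         region_names = region_names),
    class = "edge_index")
}

#' @export
length.edge_index <- function(x) nrow(x$pairs)

#' @export
print.edge_index <- function(x, ...) {
  cat(sprintf("<edge_index> %d regions, %d edges\n", x$n_regions, length(x)))
  invisible(x)
}

#' Packaged AAL-90 region labels
#'
#' The 90 cortical and subcortical region labels of the Automated
#' Anatomical Labelling atlas in its standard numerical order
#' (left/right interleaved), using the dotted laterality convention
#' (`"Frontal.Mid.R"`, `"Hippocampus.L"`, ...).
#'
#' @return Character vector of length 90.
#' @export
aal90_regions <- function() {
  path <- system.file("extdata", "aal90_labels.txt", package = "megml",
                      mustWork = TRUE)
  readLines(path)
}

#' Human-readable label for an edge
#'
#' @param edge_id integer vector of edge ids (1-based positions in the
#'   canonical edge order).
#' @param index an [edge_index()].
#' @param sep separator between the two region names.
#' @return Character vector like `"Lingual.L-Temporal.Sup.R"`.
#' @export
edge_label <- function(edge_id, index, sep = "-") {
  stopifnot(inherits(index, "edge_index"))
  edge_id <- as.integer(edge_id)
  if (any(is.na(edge_id)) || any(edge_id < 1L) || any(edge_id > length(index)))
    stop("edge id out of range")
  paste(index$region_names[index$pairs$i[edge_id]],
        index$region_names[index$pairs$j[edge_id]], sep = sep)
}

#' Find the edge id of a region pair
#'
#' @param region_a,region_b region names (order irrelevant).
#' @param index an [edge_index()].
#' @return Integer edge id.
#' @export
edge_id_of <- function(region_a, region_b, index) {
  ia <- match(region_a, index$region_names)
  ib <- match(region_b, index$region_names)
  if (anyNA(ia) || anyNA(ib))
    stop("unknown region name(s): ",
         paste(unique(c(region_a[is.na(ia)], region_b[is.na(ib)])), collapse = ", "))
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  if (any(lo == hi)) stop("a region cannot pair with itself")
  out <- integer(length(lo))
  for (k in seq_along(lo)) {
    out[k] <- which(index$pairs$i == lo[k] & index$pairs$j == hi[k])
  }
  out
}

#' Vectorise a symmetric connectivity matrix into canonical edge order
#'
#' @param M square symmetric numeric matrix with zero diagonal (symmetry
#'   tolerance 1e-9; values outside `[0, 1]` by more than 1e-9 are
#'   rejected rather than clipped).
#' @param index an [edge_index()] whose size matches `M`.
#' @return Numeric vector of length `length(index)` following the
#'   canonical edge order; round-trips with [devectorize_edges()].
#' @export
vectorize_matrix <- function(M, index) {
  stopifnot(inherits(index, "edge_index"))
  if (!is.matrix(M) || nrow(M) != ncol(M) || nrow(M) != index$n_regions)
    stop("M must be a square matrix of size n_regions")
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at cell (%d, %d)", bad[1], bad[2]))
  }
  asym <- abs(M - t(M))
  if (max(asym) > 1e-9) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("matrix asymmetric beyond 1e-9 at cell (%d, %d)", bad[1], bad[2]))
  }
  if (max(abs(diag(M))) > 1e-9)
    stop(sprintf("nonzero diagonal at region %d", which.max(abs(diag(M)))))
  if (min(M) < -1e-9 || max(M) > 1 + 1e-9)
    stop("edge values outside [0, 1]")
  M[cbind(index$pairs$i, index$pairs$j)]
}

#' Rebuild the symmetric matrix from a canonical edge vector
#'
#' @param v numeric edge vector in canonical order.
#' @param index an [edge_index()].
#' @return Symmetric matrix with zero diagonal and region-name dimnames.
#' @export
devectorize_edges <- function(v, index) {
  stopifnot(inherits(index, "edge_index"))
  if (length(v) != length(index)) stop("edge vector length mismatch")
  M <- matrix(0, index$n_regions, index$n_regions,
              dimnames = list(index$region_names, index$region_names))
  M[cbind(index$pairs$i, index$pairs$j)] <- v
  M[cbind(index$pairs$j, index$pairs$i)] <- v
  M
}
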