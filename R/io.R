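#' Write a connectome dataset to disk
#'
#' Two plain-text layouts are supported:
#' \describe{
#'   \item{`edge_table_csv`}{one long CSV with columns `subject_id`,
#'     `group`, `band`, `region_a`, `region_b`, `wpli`; `path` names the
#'     file.}
#'   \item{`square_csv`}{one 90x90 (or RxR) symmetric CSV per subject with
#'     region-name header, plus a `labels.json` sidecar mapping
#'     `subject_id` to group; `path` names a directory. Only full-edge
#'     datasets can be written this way.}
#' }
#' Values are written with 15 significant digits so a write/read
#' round-trip is lossless to well below 1e-12.
#'
#' @param dataset a [connectome_dataset()].
#' @param path output file (`edge_table_csv`) or directory (`square_csv`).
#' @param format `"edge_table_csv"` or `"square_csv"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path,
                          format = c("edge_table_csv", "square_csv")) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  format <- match.arg(format)
  idx <- dataset$index
  if (format == "edge_table_csv") {
    pa <- idx$region_names[idx$pairs$i[dataset$edge_ids]]
    pb <- idx$region_names[idx$pairs$j[dataset$edge_ids]]
    n <- nrow(dataset$X); e <- ncol(dataset$X)
    tab <- data.frame(
      subject_id = rep(dataset$subject_ids, each = e),
      group = rep(as.character(dataset$labels), each = e),
      band = dataset$band,
      region_a = rep(pa, times = n),
      region_b = rep(pb, times = n),
      wpli = format(as.vector(t(dataset$X)), digits = 15, scientific = FALSE,
                    trim = TRUE),
      stringsAsFactors = FALSE)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    if (length(dataset$edge_ids) != length(idx))
      stop("square_csv requires the full edge set")
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (r in seq_len(nrow(dataset$X))) {
      M <- devectorize_edges(dataset$X[r, ], idx)
      Mc <- matrix(format(M, digits = 15, scientific = FALSE, trim = TRUE),
                   nrow(M), dimnames = dimnames(M))
      utils::write.csv(as.data.frame(Mc),
                       file.path(path, paste0(dataset$subject_ids[r], ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    labels <- as.list(stats::setNames(as.character(dataset$labels),
                                      dataset$subject_ids))
    jsonlite::write_json(labels, file.path(path, "labels.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a connectome dataset from disk
#'
#' Inverse of [write_dataset()]. Schema violations fail loudly: unknown
#' region names, subjects missing edges, labels not covering all
#' subjects, and values outside `[0, 1]` are all errors.
#'
#' @param path file (`edge_table_csv`) or directory (`square_csv`).
#' @param format `"edge_table_csv"` or `"square_csv"`.
#' @param region_names region label set defining the edge index; defaults
#'   to [aal90_regions()] for 90-region data. Must cover every region
#'   name in the file.
#' @param band band name for `square_csv` input (the edge table carries
#'   its own `band` column).
#' @param labels optional named vector/list `subject_id -> group`
#'   overriding the `group` column or `labels.json` sidecar.
#' @return A [connectome_dataset()].
#' @export
read_dataset <- function(path, format = c("edge_table_csv", "square_csv"),
                         region_names = aal90_regions(), band = NULL,
                         labels = NULL) {
  format <- match.arg(format)
  idx <- edge_index(length(region_names), region_names)
  if (format == "edge_table_csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("subject_id", "group", "band", "region_a", "region_b", "wpli")
    if (!all(need %in% names(tab))) stop("edge table missing columns")
    ids <- unique(tab$subject_id)
    eid <- edge_id_of(tab$region_a, tab$region_b, idx)
    all_eids <- sort(unique(eid))
    X <- matrix(NA_real_, length(ids), length(all_eids),
                dimnames = list(ids, NULL))
    row <- match(tab$subject_id, ids)
    col <- match(eid, all_eids)
    if (anyDuplicated(cbind(row, col))) stop("duplicate subject/edge rows")
    X[cbind(row, col)] <- as.numeric(tab$wpli)
    if (anyNA(X)) stop("incomplete edge table: some subjects lack edges")
    if (is.null(labels)) {
      labels <- tapply(tab$group, tab$subject_id, function(g) unique(g)[1])
      if (any(tapply(tab$group, tab$subject_id,
                     function(g) length(unique(g))) > 1))
        stop("inconsistent group labels within a subject")
    }
    band <- unique(tab$band)
    if (length(band) != 1) stop("edge table must hold a single band")
    connectome_dataset(X, unlist(labels)[ids], band, idx,
                       subject_ids = ids, edge_ids = all_eids)
  } else {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0) stop("no subject matrices found in ", path)
    if (is.null(labels)) {
      lp <- file.path(path, "labels.json")
      if (!file.exists(lp)) stop("labels.json sidecar not found")
      labels <- jsonlite::read_json(lp, simplifyVector = TRUE)
    }
    ids <- sub("\\.csv$", "", basename(files))
    if (!all(ids %in% names(labels)))
      stop("labels missing for subject(s): ",
           paste(setdiff(ids, names(labels)), collapse = ", "))
    X <- matrix(NA_real_, length(ids), length(idx),
                dimnames = list(ids, NULL))
    for (r in seq_along(files)) {
      M <- as.matrix(utils::read.csv(files[r], check.names = FALSE))
      if (!identical(colnames(M), idx$region_names))
        stop("region header mismatch in ", basename(files[r]))
      storage.mode(M) <- "double"
      rownames(M) <- colnames(M)
      X[r, ] <- vectorize_matrix(M, idx)
    }
    if (is.null(band)) band <- "unknown"
    connectome_dataset(X, unlist(labels)[ids], band, idx, subject_ids = ids)
  }
}
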