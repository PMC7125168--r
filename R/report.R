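#' Run the full per-band analysis
#'
#' Orchestrates every stage of the framework on one band's dataset:
#' full-sample univariate screening (the descriptive arm), unsupervised
#' structure checks (two-way clustering and PCA) on all edges and on the
#' significant edges, the supervised pipeline ([run_pipeline()]:
#' stratified split, CV-SVM-rRF-FS, final SVM, permutation test,
#' external ROC/AUC), PLS-DA verification with VIP scoring on the
#' consensus edges, and the unsupervised checks once more on the
#' selected edges. All randomness derives from `seed`.
#'
#' @param dataset a [connectome_dataset()].
#' @param control a [pipeline_control()].
#' @param seed integer seed.
#' @return An object of class `band_report`: `band`, `univariate`,
#'   `cluster_all`/`pca_all`, `cluster_significant`/`pca_significant`
#'   (or `NULL` when no edge passes the screen), `pipeline`,
#'   `cluster_selected`/`pca_selected` (or `NULL` for an empty
#'   consensus), `plsda` (`fit`, `vip`, `cv`, or `NULL`), `control`,
#'   `seed`.
#' @export
run_band <- function(dataset, control = pipeline_control(), seed = 1) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  rep <- list(band = dataset$band, control = control, seed = as.integer(seed))

  rep$univariate <- edge_ttest(dataset, alpha = control$alpha,
                               adjust = control$adjust)
  z_all <- zscore_edges(dataset)
  rep$cluster_all <- hierarchical_clusters(z_all, dataset$labels,
                                           cluster_edges = FALSE)
  rep$pca_all <- pca_report(z_all, control$n_components, stage = "all_edges")

  sig <- filter_significant(dataset, rep$univariate)
  if (inherits(sig, "connectome_dataset")) {
    z_sig <- zscore_edges(sig)
    rep$cluster_significant <- hierarchical_clusters(z_sig, sig$labels)
    rep$pca_significant <- pca_report(z_sig,
                                      min(control$n_components, ncol(z_sig)),
                                      stage = "significant")
  }

  rep$pipeline <- run_pipeline(dataset, control, seed)
  consensus <- rep$pipeline$fs$consensus

  if (length(consensus) > 0) {
    sel <- subset_edges(dataset, consensus)
    z_sel <- zscore_edges(sel)
    rep$cluster_selected <- hierarchical_clusters(z_sel, sel$labels)
    rep$pca_selected <- pca_report(z_sel,
                                   min(control$n_components, ncol(z_sel)),
                                   stage = "selected")
    train <- subset_subjects(dataset, rep$pipeline$split$train_ids)
    tr_sel <- subset_edges(train, consensus)
    A <- min(control$plsda_components, nrow(tr_sel$X) - 1, ncol(tr_sel$X))
    fit <- fit_plsda(tr_sel$X, tr_sel$labels, A = A)
    rep$plsda <- list(
      fit = fit,
      vip = vip_scores(fit, control$vip_threshold),
      cv = plsda_cv_performance(tr_sel$X, tr_sel$labels, A = A,
                                k = min(control$k_folds, nrow(tr_sel$X)),
                                seed = derive_seed(seed, "plsda")))
  }
  structure(rep, class = "band_report")
}

#' @export
print.band_report <- function(x, ...) {
  n_sig <- sum(x$univariate$significant)
  cons <- length(x$pipeline$fs$consensus)
  cat(sprintf("<band_report> %s: %d significant edges, %d consensus edges, external AUC %.2f\n",
              x$band, n_sig, cons, x$pipeline$evaluation$auc))
  invisible(x)
}

#' Aggregate band reports into summary tables
#'
#' Builds the two study-level summary tables and the evaluation summary
#' from a set of per-band reports:
#' \describe{
#'   \item{`table1`}{one row per band: significant-edge count with
#'     increase/decrease split, and consensus-selected edge count with
#'     its increase/decrease split. Selected-edge directionality is taken
#'     from the corresponding full-sample univariate result.}
#'   \item{`table2`}{the consensus edge lists, one row per edge with
#'     columns `band`, `region_1`, `region_2`.}
#'   \item{`evaluation`}{per band: internal CV mean/SD, support-vector
#'     count, permutation p, external AUC.}
#'   \item{`summary`}{the across-band mean/SD of significant counts
#'     (from [summarize_bands()]).}
#' }
#'
#' @param reports list of [run_band()] reports (one per band).
#' @return A list of class `study_tables` with elements `table1`,
#'   `table2`, `evaluation`, `summary`.
#' @export
aggregate_tables <- function(reports) {
  if (inherits(reports, "band_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  t1 <- list(); t2 <- list(); ev <- list()
  for (r in reports) {
    stopifnot(inherits(r, "band_report"))
    uni <- r$univariate
    sig <- uni[uni$significant, , drop = FALSE]
    cons <- r$pipeline$fs$consensus
    cons_dir <- uni$direction[match(cons, uni$edge)]
    t1[[r$band]] <- data.frame(
      band = r$band,
      n_significant = nrow(sig),
      increase = sum(sig$direction == "increase"),
      decrease = sum(sig$direction == "decrease"),
      n_selected = length(cons),
      selected_increase = sum(cons_dir == "increase"),
      selected_decrease = sum(cons_dir == "decrease"),
      stringsAsFactors = FALSE)
    if (length(cons) > 0) {
      ei <- r$univariate[match(cons, r$univariate$edge), ]
      t2[[r$band]] <- data.frame(band = r$band, region_1 = ei$region_a,
                                 region_2 = ei$region_b,
                                 stringsAsFactors = FALSE)
    }
    ev[[r$band]] <- data.frame(
      band = r$band,
      cv_mean = r$pipeline$fit$cv_mean,
      cv_sd = r$pipeline$fit$cv_sd,
      n_support_vectors = r$pipeline$fit$n_support_vectors,
      permutation_p = if (is.null(r$pipeline$permutation)) NA_real_
                      else r$pipeline$permutation$p,
      auc = r$pipeline$evaluation$auc,
      no_signal = r$pipeline$fit$no_signal,
      stringsAsFactors = FALSE)
  }
  structure(
    list(table1 = do.call(rbind, c(t1, list(make.row.names = FALSE))),
         table2 = if (length(t2))
           do.call(rbind, c(t2, list(make.row.names = FALSE)))
           else data.frame(band = character(0), region_1 = character(0),
                           region_2 = character(0)),
         evaluation = do.call(rbind, c(ev, list(make.row.names = FALSE))),
         summary = summarize_bands(lapply(reports, `[[`, "univariate"))),
    class = "study_tables")
}

#' @export
print.study_tables <- function(x, ...) {
  print(x$table1, row.names = FALSE)
  cat(sprintf("across bands: %.1f +/- %.1f significant edges (mean +/- SD)\n",
              x$summary$mean_significant, x$summary$sd_significant))
  invisible(x)
}

#' Write a band report (and its manifest) to a directory
#'
#' Emits plain CSV/JSON artifacts for one band: the univariate table,
#' cluster assignments, PCA scores and explained variances per stage,
#' the consensus edge list (`band`, `region_1`, `region_2`), the ROC
#' curve, VIP scores, an `evaluation.json` (internal CV mean/SD,
#' support vectors, permutation p, AUC) and a `manifest.json` recording
#' the seed, configuration, package version and an MD5 checksum of every
#' file written. [verify_manifest()] re-checks the checksums.
#'
#' @param report a [run_band()] report.
#' @param dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_band_report <- function(report, dir) {
  stopifnot(inherits(report, "band_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put_csv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  put_json <- function(x, name) {
    path <- file.path(dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    files <<- c(files, name)
  }
  put_csv(as.data.frame(report$univariate), "univariate.csv")
  for (stage in c("all", "significant", "selected")) {
    cl <- report[[paste0("cluster_", stage)]]
    if (!is.null(cl)) {
      put_csv(data.frame(subject_id = names(cl$assignments),
                         cluster = unname(cl$assignments),
                         stringsAsFactors = FALSE),
              paste0("clusters_", stage, ".csv"))
    }
    pc <- report[[paste0("pca_", stage)]]
    if (!is.null(pc)) {
      put_csv(data.frame(subject_id = rownames(pc$scores), pc$scores),
              paste0("pca_scores_", stage, ".csv"))
      put_csv(data.frame(component = seq_along(pc$pct_variance),
                         pct_variance = pc$pct_variance),
              paste0("pca_variance_", stage, ".csv"))
    }
  }
  uni <- report$univariate
  cons <- report$pipeline$fs$consensus
  cons_rows <- uni[match(cons, uni$edge), ]
  put_csv(data.frame(band = report$band, region_1 = cons_rows$region_a,
                     region_2 = cons_rows$region_b),
          "consensus.csv")
  put_csv(report$pipeline$evaluation$roc, "roc.csv")
  if (!is.null(report$plsda)) put_csv(report$plsda$vip, "vip.csv")
  put_json(list(band = report$band,
                cv_mean = report$pipeline$fit$cv_mean,
                cv_sd = report$pipeline$fit$cv_sd,
                n_support_vectors = report$pipeline$fit$n_support_vectors,
                permutation_p = if (is.null(report$pipeline$permutation))
                  NULL else report$pipeline$permutation$p,
                auc = report$pipeline$evaluation$auc,
                no_signal = report$pipeline$fit$no_signal,
                plsda_cv_accuracy = if (is.null(report$plsda)) NULL
                  else report$plsda$cv$accuracy),
           "evaluation.json")
  manifest <- list(
    package = "megml",
    version = as.character(utils::packageVersion("megml")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    band = report$band, seed = report$seed,
    control = unclass(report$control),
    files = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Verify a band-report manifest
#'
#' Checks that every file listed in a report directory's
#' `manifest.json` exists and still matches its recorded MD5 checksum.
#'
#' @param dir a directory written by [write_band_report()].
#' @return `TRUE` invisibly; errors describe any missing or altered file.
#' @export
verify_manifest <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  for (f in names(manifest$files)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("manifest file missing: ", f)
    sum_now <- unname(tools::md5sum(path))
    if (!identical(sum_now, manifest$files[[f]]))
      stop("checksum mismatch for ", f)
  }
  invisible(TRUE)
}
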