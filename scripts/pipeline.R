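#!/usr/bin/env Rscript
# Thin command-line wrapper over the megml package.
#
#   Rscript scripts/pipeline.R simulate --spec spec.json --out <dir> [--seed <int>]
#   Rscript scripts/pipeline.R run --input edges.csv --config config.json \
#       --seed <int> --out <dir>
#   Rscript scripts/pipeline.R report --runs <dir>
#
# simulate: generate per-band synthetic edge-table CSVs (plus ground-truth
#   JSON) from a spec file holding synthetic_spec() arguments.
# run: run the full per-band analysis on an edge-table CSV and write the
#   report artifacts.
# report: collect evaluation.json files under a directory into one CSV.

suppressPackageStartupMessages(library(megml))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: pipeline.R <simulate|run|report> [options]")
cmd <- args[1]
opt <- list()
i <- 2
while (i < length(args) + 1) {
  if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
  opt[[substring(args[i], 3)]] <- args[i + 1]
  i <- i + 2
}

if (cmd == "simulate") {
  stopifnot(!is.null(opt$spec), !is.null(opt$out))
  spec_args <- jsonlite::read_json(opt$spec, simplifyVector = TRUE)
  if (!is.null(opt$seed)) spec_args$seed <- as.integer(opt$seed)
  if (!is.null(spec_args$bands)) spec_args$bands <- as.data.frame(spec_args$bands)
  spec <- do.call(synthetic_spec, spec_args)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  for (band in spec$bands$band) {
    ds <- generate_edge_dataset(spec, band)
    write_dataset(ds, file.path(opt$out, paste0(band, ".csv")),
                  "edge_table_csv")
  }
  jsonlite::write_json(ground_truth(spec),
                       file.path(opt$out, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cat("wrote", length(spec$bands$band), "band dataset(s) to", opt$out, "\n")
} else if (cmd == "run") {
  stopifnot(!is.null(opt$input), !is.null(opt$out))
  ctl <- if (is.null(opt$config)) pipeline_control()
         else read_pipeline_config(opt$config)
  seed <- if (is.null(opt$seed)) 1L else as.integer(opt$seed)
  labels <- if (is.null(opt$labels)) NULL
            else jsonlite::read_json(opt$labels, simplifyVector = TRUE)
  ds <- read_dataset(opt$input, "edge_table_csv", labels = labels)
  report <- run_band(ds, ctl, seed = seed)
  write_band_report(report, file.path(opt$out, ds$band))
  print(report)
} else if (cmd == "report") {
  stopifnot(!is.null(opt$runs))
  files <- list.files(opt$runs, pattern = "^evaluation\\.json$",
                      recursive = TRUE, full.names = TRUE)
  if (length(files) == 0) stop("no evaluation.json files under ", opt$runs)
  rows <- lapply(files, function(f) {
    as.data.frame(jsonlite::read_json(f, simplifyVector = TRUE))
  })
  tab <- do.call(rbind, rows)
  out <- file.path(opt$runs, "evaluation_summary.csv")
  utils::write.csv(tab, out, row.names = FALSE)
  print(tab, row.names = FALSE)
  cat("wrote", out, "\n")
} else {
  stop("unknown subcommand: ", cmd)
}
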