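#' Canonical MEG frequency bands
#'
#' @return Data frame with columns `band`, `f_low`, `f_high` (Hz) for
#'   Theta (4-7), Alpha (8-14), Beta (15-30), L.Gamma (30-80) and
#'   H.Gamma (80-150).
#' @export
default_bands <- function() {
  data.frame(band = c("Theta", "Alpha", "Beta", "L.Gamma", "H.Gamma"),
             f_low = c(4, 8, 15, 30, 80),
             f_high = c(7, 14, 30, 80, 150),
             stringsAsFactors = FALSE)
}

# Per-band planted-edge counts and increase/decrease splits used by
# default: the univariate screening profile of the study design this
# generator emulates (30/40/49/22/59 significant edges, mixed direction).
default_planted_counts <- function() {
  data.frame(band = c("Theta", "Alpha", "Beta", "L.Gamma", "H.Gamma"),
             n = c(30L, 40L, 49L, 22L, 59L),
             n_increase = c(15L, 22L, 30L, 7L, 26L),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic connectome study
#'
#' Defines the full design of a simulated two-group MEG connectome study:
#' group sizes, parcellation size, frequency bands, and per band a set of
#' planted discriminative edges, each with a direction (case group
#' increased or decreased relative to control) and an effect size `d` in
#' units of the between-subject SD. Defaults reproduce the emulated study
#' conditions: 23 case vs 21 control subjects, 90 regions (4005 edges),
#' five canonical bands, and per-band planted-edge counts of
#' 30/40/49/22/59 with mixed direction.
#'
#' Edge weights are drawn logit-normal: `logit(w) ~ N(logit(baseline),
#' edge_noise_sd)`, and the planted effect `d * edge_noise_sd` is added on
#' the logit scale, so increases and decreases stay monotone and the
#' `[0, 1]` support is respected without truncation.
#'
#' @param n_group1 number of case subjects (default 23).
#' @param n_group2 number of control subjects (default 21).
#' @param n_regions parcellation size (default 90).
#' @param bands data frame `band`, `f_low`, `f_high` (default
#'   [default_bands()]).
#' @param planted named list (one element per band) of data frames with
#'   columns `edge` (id), `direction` (`"increase"`/`"decrease"`) and `d`
#'   (effect size, SD units). `NULL` (default) draws planted sets from
#'   the seed with the default per-band counts and `d = effect_size`.
#' @param effect_size effect size used when auto-generating `planted`
#'   (default 1.2).
#' @param n_planted optional single count overriding the per-band default
#'   planted-edge counts (split half increase / half decrease).
#' @param baseline_edge_mean baseline mean edge weight in (0,1), default 0.3.
#' @param edge_noise_sd between-subject SD on the logit scale, default 0.4.
#' @param seed top-level integer seed.
#' @param mode `"direct_edges"` (default: draw edge weights directly) or
#'   `"timeseries"` (synthesise coupled oscillations, reduce via wPLI).
#' @param sampling_rate,n_epochs,epoch_length time-series mode parameters
#'   (Hz, count, seconds); defaults 600 Hz, 60 epochs of 2 s, enough to
#'   resolve H.Gamma to 150 Hz.
#' @param coupling_phase_lag phase lag (radians) injected between coupled
#'   regions, default pi / 4. Lags congruent to 0 mod pi are flagged with
#'   a warning because the wPLI estimator is blind to zero-lag coupling.
#' @param coupling_strength baseline coupling strength in `[0, 1]` for
#'   planted pairs in the control group, default 0.4.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_group1 = 23, n_group2 = 21, n_regions = 90,
                           bands = default_bands(), planted = NULL,
                           effect_size = 1.2, n_planted = NULL,
                           baseline_edge_mean = 0.3, edge_noise_sd = 0.4,
                           seed = 1, mode = c("direct_edges", "timeseries"),
                           sampling_rate = 600, n_epochs = 60,
                           epoch_length = 2, coupling_phase_lag = pi / 4,
                           coupling_strength = 0.4) {
  mode <- match.arg(mode)
  stopifnot(n_group1 >= 2, n_group2 >= 2, n_regions >= 2,
            baseline_edge_mean > 0, baseline_edge_mean < 1,
            edge_noise_sd > 0,
            coupling_strength >= 0, coupling_strength <= 1)
  if (any(bands$f_low >= bands$f_high)) stop("bands must have f_low < f_high")
  E <- edge_count(n_regions)
  if (is.null(planted)) {
    counts <- default_planted_counts()
    planted <- stats::setNames(vector("list", nrow(bands)), bands$band)
    for (b in seq_len(nrow(bands))) {
      bn <- bands$band[b]
      row <- counts[counts$band == bn, ]
      n_b <- if (!is.null(n_planted)) as.integer(n_planted)
             else if (nrow(row) == 1) row$n else 40L
      n_inc <- if (!is.null(n_planted)) n_b %/% 2L
               else if (nrow(row) == 1) row$n_increase else n_b %/% 2L
      n_b <- min(n_b, E)
      set.seed(derive_seed(seed, bn, "planted"))
      ids <- sort(sample.int(E, n_b))
      planted[[bn]] <- data.frame(
        edge = ids,
        direction = rep(c("increase", "decrease"), c(n_inc, n_b - n_inc)),
        d = rep(effect_size, n_b), stringsAsFactors = FALSE)
    }
  }
  for (bn in names(planted)) {
    p <- planted[[bn]]
    if (nrow(p) > 0) {
      if (any(p$edge < 1) || any(p$edge > E))
        stop("planted edge ids out of range for ", n_regions, " regions")
      if (!all(p$direction %in% c("increase", "decrease")))
        stop("direction must be 'increase' or 'decrease'")
      if (any(!is.finite(p$d))) stop("effect sizes must be finite")
    }
  }
  if (abs(coupling_phase_lag %% pi) < 1e-12)
    warning("coupling_phase_lag is congruent to 0 mod pi: wPLI cannot detect zero-lag coupling")
  structure(
    list(n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
         n_regions = as.integer(n_regions), bands = bands, planted = planted,
         baseline_edge_mean = baseline_edge_mean, edge_noise_sd = edge_noise_sd,
         seed = as.integer(seed), mode = mode,
         sampling_rate = sampling_rate, n_epochs = as.integer(n_epochs),
         epoch_length = epoch_length, coupling_phase_lag = coupling_phase_lag,
         coupling_strength = coupling_strength),
    class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d case + %d control, %d regions (%d edges), %d bands, mode %s, seed %d\n",
              x$n_group1, x$n_group2, x$n_regions, edge_count(x$n_regions),
              nrow(x$bands), x$mode, x$seed))
  invisible(x)
}

#' Ground truth of a synthetic spec
#'
#' The planted discriminative edges per band, with direction and effect
#' size. Used by tests to score recovery; the analysis pipeline itself
#' never sees it.
#'
#' @param spec a [synthetic_spec()].
#' @param band optional band name to extract a single band's table.
#' @return A data frame (or named list of them) with columns `edge`,
#'   `direction`, `d`.
#' @export
ground_truth <- function(spec, band = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(band)) return(spec$planted)
  if (!band %in% names(spec$planted)) stop("unknown band: ", band)
  spec$planted[[band]]
}

spec_labels <- function(spec) {
  factor(rep(c("case", "control"), c(spec$n_group1, spec$n_group2)),
         levels = c("control", "case"))
}

spec_subject_ids <- function(spec) {
  c(sprintf("case_%02d", seq_len(spec$n_group1)),
    sprintf("ctrl_%02d", seq_len(spec$n_group2)))
}

#' Generate an edge-level synthetic dataset for one band
#'
#' Draws subject-by-edge wPLI weights logit-normal around the baseline and
#' shifts the planted edges by `d * edge_noise_sd` on the logit scale for
#' the case group only (positive for `"increase"`, negative for
#' `"decrease"`). The bounded inverse-logit transform guarantees values in
#' `(0, 1)` without ever clipping a planted group difference away.
#'
#' @param spec a [synthetic_spec()].
#' @param band band name present in `spec$bands`.
#' @return A [connectome_dataset()], reproducible from `spec$seed`.
#' @export
generate_edge_dataset <- function(spec, band) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!band %in% spec$bands$band) stop("unknown band: ", band)
  E <- edge_count(spec$n_regions)
  n <- spec$n_group1 + spec$n_group2
  set.seed(derive_seed(spec$seed, band, "edges"))
  Z <- matrix(stats::rnorm(n * E, mean = stats::qlogis(spec$baseline_edge_mean),
                           sd = spec$edge_noise_sd), n, E)
  pl <- spec$planted[[band]]
  if (!is.null(pl) && nrow(pl) > 0) {
    shift <- ifelse(pl$direction == "increase", 1, -1) * pl$d * spec$edge_noise_sd
    Z[seq_len(spec$n_group1), pl$edge] <-
      sweep(Z[seq_len(spec$n_group1), pl$edge, drop = FALSE], 2, shift, `+`)
  }
  region_names <- if (spec$n_regions == 90) aal90_regions()
                  else paste0("R", seq_len(spec$n_regions))
  connectome_dataset(stats::plogis(Z), spec_labels(spec), band,
                     edge_index(spec$n_regions, region_names),
                     subject_ids = spec_subject_ids(spec))
}

# Case-group coupling strength for a planted pair: baseline shifted by
# 0.15 per unit effect size, clamped to [0, 1].
strength_for <- function(base, direction, d) {
  s <- base + ifelse(direction == "increase", 1, -1) * 0.15 * d
  pmin(1, pmax(0, s))
}

#' Generate coupled oscillatory time series for one band
#'
#' The physical-level counterpart of [generate_edge_dataset()]: per
#' subject, `n_regions` epoched signals in which each planted region pair
#' shares a band-centre sinusoidal carrier injected with a fixed phase lag
#' (`coupling_phase_lag`), mixed with independent band-limited noise. The
#' carrier weight is the pair's coupling strength: `coupling_strength` for
#' controls, shifted by `0.15 * d` in the planted direction for cases.
#' Epoch-wise carrier phases are random, so only the lag structure - not
#' the waveform - is shared across epochs, which is what wPLI measures.
#'
#' @param spec a [synthetic_spec()] (any mode; the time-series parameters
#'   of the spec are used).
#' @param band band name present in `spec$bands`.
#' @return An object of class `coupled_timeseries`: list with `subjects`
#'   (per subject an array `n_regions x samples x n_epochs`), `labels`,
#'   `sampling_rate`, `band`, `band_range` and `spec`.
#' @export
generate_coupled_timeseries <- function(spec, band) {
  stopifnot(inherits(spec, "synthetic_spec"))
  brow <- spec$bands[spec$bands$band == band, ]
  if (nrow(brow) != 1) stop("unknown band: ", band)
  if (brow$f_high > spec$sampling_rate / 2)
    stop("band exceeds the Nyquist frequency")
  if (abs(spec$coupling_phase_lag %% pi) < 1e-12)
    warning("coupling_phase_lag congruent to 0 mod pi: wPLI is blind to zero-lag coupling")
  S <- round(spec$sampling_rate * spec$epoch_length)
  tvec <- (seq_len(S) - 1) / spec$sampling_rate
  f0 <- (brow$f_low + brow$f_high) / 2
  # FIR band-pass for the noise floor so spectral content matches the band
  bp <- signal::fir1(64, c(brow$f_low, brow$f_high) / (spec$sampling_rate / 2),
                     type = "pass")
  pl <- spec$planted[[band]]
  if (is.null(pl)) pl <- data.frame(edge = integer(), direction = character(),
                                    d = numeric())
  idx <- edge_index(spec$n_regions)
  pl_regions <- c(idx$pairs$i[pl$edge], idx$pairs$j[pl$edge])
  if (anyDuplicated(pl_regions))
    warning("planted pairs share regions; later pairs overwrite earlier carrier assignments")
  labels <- spec_labels(spec)
  set.seed(derive_seed(spec$seed, band, "timeseries"))
  subjects <- vector("list", length(labels))
  for (s in seq_along(labels)) {
    arr <- array(0, dim = c(spec$n_regions, S, spec$n_epochs))
    strengths <- if (labels[s] == "case")
      strength_for(spec$coupling_strength, pl$direction, pl$d)
    else rep(spec$coupling_strength, nrow(pl))
    for (e in seq_len(spec$n_epochs)) {
      noise <- matrix(stats::rnorm(spec$n_regions * S), spec$n_regions, S)
      noise <- t(apply(noise, 1, function(x) signal::filtfilt(bp, x)))
      noise <- noise / pmax(apply(noise, 1, stats::sd), 1e-12)
      sig <- noise
      if (nrow(pl) > 0) {
        for (p in seq_len(nrow(pl))) {
          i <- idx$pairs$i[pl$edge[p]]; j <- idx$pairs$j[pl$edge[p]]
          phi <- stats::runif(1, 0, 2 * pi)
          cs <- strengths[p]
          carrier_i <- sqrt(2) * sin(2 * pi * f0 * tvec + phi)
          carrier_j <- sqrt(2) * sin(2 * pi * f0 * tvec + phi +
                                       spec$coupling_phase_lag)
          sig[i, ] <- cs * carrier_i + (1 - cs) * noise[i, ]
          sig[j, ] <- cs * carrier_j + (1 - cs) * noise[j, ]
        }
      }
      arr[, , e] <- sig
    }
    subjects[[s]] <- arr
  }
  structure(
    list(subjects = subjects, labels = labels,
         subject_ids = spec_subject_ids(spec),
         sampling_rate = spec$sampling_rate, band = band,
         band_range = c(brow$f_low, brow$f_high), spec = spec),
    class = "coupled_timeseries")
}

#' Reduce coupled time series to a wPLI connectome dataset
#'
#' Runs [compute_wpli()] on every region pair of every subject and
#' assembles the resulting edge weights into a [connectome_dataset()].
#'
#' @param ts a `coupled_timeseries` from [generate_coupled_timeseries()].
#' @return A [connectome_dataset()].
#' @export
dataset_from_timeseries <- function(ts) {
  stopifnot(inherits(ts, "coupled_timeseries"))
  spec <- ts$spec
  idx <- edge_index(spec$n_regions,
                    if (spec$n_regions == 90) aal90_regions() else NULL)
  X <- matrix(NA_real_, length(ts$subjects), length(idx))
  for (s in seq_along(ts$subjects)) {
    arr <- ts$subjects[[s]]
    for (k in seq_len(length(idx))) {
      i <- idx$pairs$i[k]; j <- idx$pairs$j[k]
      X[s, k] <- compute_wpli(t(arr[i, , ]), t(arr[j, , ]),
                              ts$sampling_rate, ts$band_range)
    }
  }
  connectome_dataset(X, ts$labels, ts$band, idx, subject_ids = ts$subject_ids)
}
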