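# Shared fixture builders. Everything is generated in code at test time;
# no stored data beyond the packaged AAL label list.

# Wrap an arbitrary [0,1] feature matrix as a connectome dataset, using the
# smallest parcellation whose edge count accommodates the columns.
toy_ds <- function(X, labels, band = "Alpha") {
  R <- 2
  while (edge_count(R) < ncol(X)) R <- R + 1
  connectome_dataset(X, labels, band, edge_index(R),
                     edge_ids = seq_len(ncol(X)))
}

toy_labels <- function(n1, n0) {
  factor(rep(c("case", "control"), c(n1, n0)), levels = c("control", "case"))
}

# Small planted-effect spec: n1+n0 subjects, R regions, n_planted edges at
# effect size d, single band.
small_spec <- function(seed, n1 = 12, n0 = 12, R = 20, n_planted = 10,
                       d = 2, band = "Alpha") {
  bands <- default_bands()
  synthetic_spec(n_group1 = n1, n_group2 = n0, n_regions = R,
                 bands = bands[bands$band == band, , drop = FALSE],
                 n_planted = n_planted, effect_size = d, seed = seed)
}

# A fast pipeline control for reduced-size simulations.
fast_control <- function(...) {
  args <- utils::modifyList(
    list(ntree = 200, B = 0, k_folds = 5, consensus_min = 3), list(...))
  do.call(pipeline_control, args)
}

# Fabricate a univariate_result carrying given per-direction significant
# counts (for summary arithmetic that only consumes the counts).
fake_uni_result <- function(band, n_increase, n_decrease, n_null = 5) {
  n <- n_increase + n_decrease + n_null
  res <- data.frame(
    edge = seq_len(n), region_a = "A", region_b = "B",
    mean_case = 0.5, mean_control = 0.5, t = 0, df = 10,
    p = c(rep(0.001, n_increase + n_decrease), rep(0.5, n_null)),
    direction = c(rep("increase", n_increase), rep("decrease", n_decrease),
                  rep("increase", n_null)),
    tie = FALSE,
    significant = c(rep(TRUE, n_increase + n_decrease), rep(FALSE, n_null)),
    stringsAsFactors = FALSE)
  structure(res, class = c("univariate_result", "data.frame"),
            alpha = 0.01, band = band, adjust = "none")
}

# Two pure sinusoid channels with a constant phase offset across epochs.
sinusoid_epochs <- function(freq, sfreq, n_epochs, duration = 1, lag = 0) {
  t <- seq(0, duration, length.out = sfreq * duration + 1)[-(sfreq * duration + 1)]
  list(x = replicate(n_epochs, sin(2 * pi * freq * t)),
       y = replicate(n_epochs, sin(2 * pi * freq * t + lag)))
}
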