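test_that("vectorised Welch test matches stats::t.test edge by edge", {
  set.seed(7)
  X <- matrix(runif(15 * 20), 15, 20)
  ds <- toy_ds(X, toy_labels(8, 7))
  res <- edge_ttest(ds, alpha = 0.05)
  for (j in seq_len(ncol(X))) {
    ref <- stats::t.test(X[1:8, j], X[9:15, j])
    expect_equal(res$t[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p[j], ref$p.value, tolerance = 1e-12)
    expect_equal(res$df[j], unname(ref$parameter), tolerance = 1e-10)
  }
  expect_identical(res$significant, res$p < 0.05)
  expect_identical(res$direction == "increase", res$mean_case >= res$mean_control)
})

test_that("degenerate edges are total and deterministic, never NaN", {
  X <- cbind(rep(0.5, 10), c(rep(0.2, 5), rep(0.8, 5)), runif(10))
  ds <- toy_ds(X, toy_labels(5, 5))
  res <- edge_ttest(ds)
  # identical values in both groups: t = 0, p = 1, tie labelled increase
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  expect_true(res$tie[1])
  expect_identical(res$direction[1], "increase")
  # zero variance but a real difference: maximal evidence, not NaN
  expect_true(is.infinite(res$t[2]))
  expect_equal(res$p[2], 0)
  expect_false(anyNA(res$p))
})

test_that("a planted d = 3 edge is significant in nearly all replicates", {
  hits <- 0L
  bands <- default_bands()[2, , drop = FALSE]
  for (r in 1:100) {
    sp <- synthetic_spec(n_group1 = 22, n_group2 = 22, n_regions = 10,
                         bands = bands,
                         planted = list(Alpha = data.frame(
                           edge = 7, direction = "decrease", d = 3)),
                         seed = 2000 + r)
    ut <- edge_ttest(generate_edge_dataset(sp, "Alpha"), alpha = 0.01)
    hits <- hits + (ut$significant[ut$edge == 7] &&
                      ut$direction[ut$edge == 7] == "decrease")
  }
  expect_gte(hits, 99)
})

test_that("across-band summary arithmetic uses the sample SD", {
  results <- list(fake_uni_result("Theta", 15, 15),
                  fake_uni_result("Alpha", 22, 18),
                  fake_uni_result("Beta", 30, 19),
                  fake_uni_result("L.Gamma", 7, 15),
                  fake_uni_result("H.Gamma", 26, 33))
  bs <- summarize_bands(results)
  expect_equal(bs$table$n_significant, c(30, 40, 49, 22, 59))
  expect_equal(bs$table$n_significant,
               bs$table$n_increase + bs$table$n_decrease)
  expect_equal(bs$mean_significant, 40)
  expect_equal(round(bs$sd_significant), 15)
  # the population-SD convention would round to 13, not 15
  expect_equal(round(sqrt(mean((bs$table$n_significant - 40)^2))), 13)

  single <- summarize_bands(list(fake_uni_result("Theta", 4, 3)))
  expect_equal(single$mean_significant, 7)
  expect_equal(single$sd_significant, 0)
  expect_false(single$sd_defined)
})

test_that("significance filtering preserves edge identities and signals emptiness", {
  sp <- small_spec(seed = 44, n_planted = 8, d = 2.5)
  ds <- generate_edge_dataset(sp, "Alpha")
  res <- edge_ttest(ds, alpha = 0.01)
  filt <- filter_significant(ds, res)
  expect_s3_class(filt, "connectome_dataset")
  expect_identical(filt$edge_ids, res$edge[res$significant])
  # recall of planted edges matches a direct recomputation
  gt <- ground_truth(sp, "Alpha")
  direct <- res$edge[res$p < 0.01]
  expect_identical(sum(gt$edge %in% filt$edge_ids), sum(gt$edge %in% direct))

  # alpha = 1 keeps every non-degenerate edge (identity filter)
  res_all <- edge_ttest(ds, alpha = 1)
  expect_identical(filter_significant(ds, res_all)$edge_ids, ds$edge_ids)

  # impossible threshold: explicit empty-selection signal, not a crash
  res_none <- edge_ttest(ds, alpha = 1e-300)
  empty <- filter_significant(ds, res_none)
  expect_s3_class(empty, "empty_selection")
  expect_equal(empty$n_selected, 0L)
})

test_that("optional BH adjustment tightens the selection", {
  sp <- small_spec(seed = 45, n_planted = 5, d = 1)
  ds <- generate_edge_dataset(sp, "Alpha")
  raw <- edge_ttest(ds, alpha = 0.05)
  bh <- edge_ttest(ds, alpha = 0.05, adjust = "BH")
  expect_lte(sum(bh$significant), sum(raw$significant))
  expect_equal(bh$p_adjusted, stats::p.adjust(raw$p, "BH"))
})
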