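test_that("stratified split preserves class proportions and totals", {
  sp <- synthetic_spec(seed = 2, n_regions = 10,
                       planted = list(Alpha = data.frame(
                         edge = 1, direction = "increase", d = 1)))
  ds <- generate_edge_dataset(sp, "Alpha")
  split <- stratified_split(ds, 0.2, seed = 3)
  expect_length(split$train_ids, 35)
  expect_length(split$test_ids, 9)
  test_labs <- ds$labels[match(split$test_ids, ds$subject_ids)]
  expect_equal(sum(test_labs == "case"), 5)
  expect_equal(sum(test_labs == "control"), 4)
  expect_length(intersect(split$train_ids, split$test_ids), 0)
  # determinism
  expect_identical(stratified_split(ds, 0.2, seed = 3), split)
  expect_false(identical(stratified_split(ds, 0.2, seed = 4)$test_ids,
                         split$test_ids))

  small <- toy_ds(matrix(runif(30), 10, 3), toy_labels(5, 5))
  s2 <- stratified_split(small, 0.2, seed = 1)
  expect_length(s2$test_ids, 2)
  expect_setequal(as.character(small$labels[match(s2$test_ids,
                                                  small$subject_ids)]),
                  c("case", "control"))
})

test_that("stratified folds always keep both classes in every training portion", {
  for (s in 1:10) {
    y <- toy_labels(7, 5)
    fold <- megml:::make_stratified_folds(y, 4, seed = s)
    for (f in 1:4) {
      expect_equal(nlevels(droplevels(y[fold != f])), 2)
    }
  }
  expect_error(megml:::make_stratified_folds(toy_labels(2, 2), 1), ">= 2")
})

test_that("recursive RF elimination ranks planted features above noise", {
  # with 5 planted features (d = 3) among 95 nulls the elimination path
  # must (i) retain exactly the planted set at its size-5 point and
  # (ii) select an almost purely planted subset at the OOB minimum
  # (ties go to the smallest set, so the selection may be a subset of
  # the planted features rather than all of them)
  ctl <- fast_control(ntree = 300)
  exact_at_5 <- 0L
  purity <- numeric(25)
  for (r in 1:25) {
    set.seed(3000 + r)
    n <- 36
    X <- matrix(rnorm(n * 100), n, 100)
    y <- toy_labels(18, 18)
    X[y == "case", 1:5] <- X[y == "case", 1:5] + 3
    fs <- rrf_fs(X, y, ctl, seed = 3000 + r)
    sizes <- vapply(fs$features_by_round, length, 0L)
    k5 <- which(sizes == 5)
    exact_at_5 <- exact_at_5 +
      (length(k5) == 1 && setequal(fs$features_by_round[[k5]], 1:5))
    purity[r] <- mean(fs$selected %in% 1:5)
    expect_true(all(diff(fs$path$n_features) < 0))
    expect_equal(fs$path$n_features[nrow(fs$path)], 2)
    expect_equal(min(fs$path$oob_error),
                 fs$path$oob_error[fs$path$n_features == length(fs$selected)])
  }
  expect_gte(exact_at_5, 23)
  expect_gte(mean(purity), 0.9)
})

test_that("an uninformative constant feature is never selected alone", {
  set.seed(4)
  X <- cbind(info = c(rnorm(10, 2), rnorm(10, -2)), flat = rep(1, 20))
  fs <- rrf_fs(X, toy_labels(10, 10), fast_control(ntree = 200), seed = 4)
  expect_true(1 %in% fs$selected)
})

test_that("CV-SVM-rRF-FS consensus is dominated by planted edges at study scale", {
  # the minimal-OOB selection rule deliberately returns compact fold-level
  # sets, so the consensus is a small high-precision signature rather
  # than an exhaustive recovery of every planted edge
  ctl <- pipeline_control(ntree = 500, B = 0)
  precision <- numeric(5)
  n_consensus <- integer(5)
  for (s in 1:5) {
    sp <- synthetic_spec(n_planted = 40, effect_size = 1.5, seed = 900 + s)
    ds <- generate_edge_dataset(sp, "Alpha")
    split <- stratified_split(ds, 0.2, seed = 900 + s)
    train <- subset_subjects(ds, split$train_ids)
    fs <- cv_svm_rrf_fs(train, ctl, seed = 900 + s)
    gt <- ground_truth(sp, "Alpha")$edge
    n_consensus[s] <- length(fs$consensus)
    precision[s] <- if (length(fs$consensus))
      sum(fs$consensus %in% gt) / length(fs$consensus) else 0
    # structural invariants of the selection result
    expect_true(all(fs$consensus %in% unlist(fs$fold_selected)))
    expect_true(all(fs$frequency$n_folds >= 1 & fs$frequency$n_folds <= 10))
  }
  expect_true(all(n_consensus >= 1))
  expect_gte(median(precision), 0.6)
})

test_that("final SVM separates a separable toy and bounds its support vectors", {
  set.seed(12)
  X <- matrix(runif(24 * 2, 0.4, 0.6), 24, 2)
  y <- toy_labels(12, 12)
  X[y == "case", 1] <- X[y == "case", 1] + 0.35
  ds <- toy_ds(X, y)
  fit <- train_final_svm(ds, ds$edge_ids, fast_control(k_folds = 4), seed = 1)
  expect_equal(fit$cv_mean, 1)
  expect_lte(fit$n_support_vectors, nrow(X))
  expect_length(fit$cv_fold_accuracy, 4)

  # empty consensus: explicit no-signal result, chance-level evaluation
  ns <- train_final_svm(ds, integer(0), fast_control(), seed = 1)
  expect_true(ns$no_signal)
  ev <- evaluate_test(ns, ds)
  expect_equal(ev$auc, 0.5)
})

test_that("label-shuffled training data scores at chance internally", {
  accs <- numeric(5)
  for (s in 1:5) {
    set.seed(5000 + s)
    X <- matrix(runif(30 * 4), 30, 4)
    y <- sample(toy_labels(15, 15))
    fit <- train_final_svm(toy_ds(X, y), 1:4,
                           fast_control(k_folds = 5), seed = s)
    accs[s] <- fit$cv_mean
  }
  expect_lt(abs(mean(accs) - 0.5), 0.2)
})

test_that("permutation p-value follows the add-one formula at its extremes", {
  # the reported p is exactly the add-one transform of the returned null
  # accuracies and can never undercut the attainable floor
  set.seed(2)
  X <- matrix(runif(16 * 2), 16, 2)
  ds <- toy_ds(X, toy_labels(8, 8))
  ctl <- fast_control(k_folds = 4, B = 19)
  fit <- train_final_svm(ds, ds$edge_ids, ctl, seed = 2)
  perm <- permutation_test(ds, ds$edge_ids, fit, ctl, seed = 2)
  expect_equal(perm$p,
               (1 + sum(perm$null_accuracy >= perm$observed)) / (19 + 1))
  expect_gte(perm$p, 1 / 20)
  expect_lte(perm$p, 1)

  # strongly separable data beats every permutation: p = 1 / (B + 1)
  set.seed(3)
  Xs <- matrix(runif(20 * 2, 0.3, 0.45), 20, 2)
  y <- toy_labels(10, 10)
  Xs[y == "case", ] <- Xs[y == "case", ] + 0.4
  dss <- toy_ds(Xs, y)
  ctl9 <- fast_control(k_folds = 4, B = 9)
  fit9 <- train_final_svm(dss, dss$edge_ids, ctl9, seed = 3)
  perm9 <- permutation_test(dss, dss$edge_ids, fit9, ctl9, seed = 3)
  expect_equal(perm9$p, 0.1)
  expect_length(perm9$null_accuracy, 9)
})

test_that("permutation p-values are super-uniform under the null", {
  # a single-configuration grid isolates the permutation machinery from
  # the (mildly optimistic) hyperparameter selection step
  ctl <- fast_control(k_folds = 4, B = 19, cost_grid = 1, gamma_grid = 0.5)
  ps <- numeric(100)
  for (r in 1:100) {
    set.seed(6000 + r)
    X <- matrix(runif(16 * 2), 16, 2)
    ds <- toy_ds(X, toy_labels(8, 8))
    fit <- train_final_svm(ds, ds$edge_ids, ctl, seed = r)
    ps[r] <- permutation_test(ds, ds$edge_ids, fit, ctl, seed = r)$p
  }
  for (alpha in c(0.1, 0.2, 0.5)) {
    expect_lte(mean(ps <= alpha), alpha + 0.1)
  }
})

test_that("rank-based AUC equals brute-force pair enumeration and pROC", {
  scores <- c(5, 4, 3, 2, 1)
  labs <- c("case", "case", "control", "case", "control")
  expect_equal(auc_mw(scores, labs), 5 / 6)
  expect_equal(auc_mw(rep(1, 5), labs), 0.5)  # all ties
  expect_equal(auc_mw(c(3, 2, 9), c("case", "control", "case")), 1)

  set.seed(17)
  for (r in 1:50) {
    n1 <- sample(2:5, 1); n0 <- sample(2:5, 1)
    s <- round(runif(n1 + n0), 1)  # force ties regularly
    labs <- rep(c("case", "control"), c(n1, n0))
    pos <- s[seq_len(n1)]; neg <- s[n1 + seq_len(n0)]
    oracle <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
      (n1 * n0)
    expect_equal(auc_mw(s, labs), oracle)
    roc <- roc_points(s, labs)
    expect_equal(megml:::trapezoid_auc(roc), oracle)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = labs, predictor = s, levels = c("control", "case"),
      direction = "<")))
    expect_equal(auc_mw(s, labs), as.numeric(ref))
  }
})

test_that("the full pipeline is deterministic for a fixed seed", {
  sp <- small_spec(seed = 61, n_planted = 8, d = 2)
  ds <- generate_edge_dataset(sp, "Alpha")
  ctl <- fast_control(B = 9)
  a <- run_pipeline(ds, ctl, seed = 13)
  b <- run_pipeline(ds, ctl, seed = 13)
  expect_identical(a$fs$consensus, b$fs$consensus)
  expect_identical(a$fit$cv_fold_accuracy, b$fit$cv_fold_accuracy)
  expect_identical(a$evaluation$auc, b$evaluation$auc)
  expect_identical(a$permutation$p, b$permutation$p)
})
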