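test_that("the first PLS direction is the dominant cross-covariance direction", {
  set.seed(23)
  X <- matrix(rnorm(10 * 6), 10, 6)
  y <- toy_labels(5, 5)
  fit <- fit_plsda(X, y, A = 2)
  # oracle: w1 is the dominant eigenvector of X' y y' X on the scaled data
  Xs <- scale(X)
  yc <- ifelse(y == "case", 1, -1); yc <- yc - mean(yc)
  M <- tcrossprod(crossprod(Xs, yc))
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  cosine <- abs(sum(fit$weights[, 1] * v))
  expect_equal(cosine, 1, tolerance = 1e-8)
  expect_true(all(fit$converged))
})

test_that("an exact predictor absorbs the first component weight", {
  # column 3 is the class coding; all others are pair-matched across the
  # groups, hence exactly orthogonal to the centred response
  set.seed(27)
  X <- matrix(rnorm(12 * 6), 12, 6)
  X[7:12, ] <- X[1:6, ]              # matched pairs: zero covariance with y
  y <- toy_labels(6, 6)
  X[, 3] <- ifelse(y == "case", 1, -1)
  fit <- fit_plsda(X, y, A = 1)
  w <- abs(fit$weights[, 1])
  expect_equal(unname(w[3]), 1, tolerance = 1e-6)
  expect_lt(max(w[-3]), 1e-6)
})

test_that("scores are orthogonal and the residual is deflated out", {
  set.seed(29)
  X <- matrix(rnorm(14 * 8), 14, 8)
  fit <- fit_plsda(X, toy_labels(7, 7), A = 3)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_lt(max(abs(crossprod(fit$residual_X, fit$scores))), 1e-8)
  expect_true(all(fit$ssy >= 0))
})

test_that("VIP matches a literal transcription of its formula and normalises", {
  set.seed(31)
  X <- matrix(rnorm(10 * 6), 10, 6)
  fit <- fit_plsda(X, toy_labels(5, 5), A = 2)
  v <- vip_scores(fit)
  # independent transcription: VIP_j = sqrt(p sum_a SSY_a (w_aj/||w_a||)^2 / sum_a SSY_a)
  p <- 6
  oracle <- sapply(seq_len(p), function(j) {
    num <- sum(fit$ssy * (fit$weights[j, ] /
                            sqrt(colSums(fit$weights^2)))^2)
    sqrt(p * num / sum(fit$ssy))
  })
  expect_equal(v$vip, unname(oracle), tolerance = 1e-10)
  expect_equal(sum(v$vip^2), p, tolerance = 1e-8)

  # VIP normalisation holds for every fit (algebraic identity)
  for (s in 1:5) {
    set.seed(40 + s)
    n <- sample(8:16, 1); pp <- sample(3:7, 1)
    f <- fit_plsda(matrix(rnorm(n * pp), n, pp),
                   toy_labels(ceiling(n / 2), floor(n / 2)),
                   A = min(2, pp))
    expect_equal(sum(vip_scores(f)$vip^2), pp, tolerance = 1e-8)
  }
})

test_that("VIP degenerate symmetries give unit scores", {
  y <- toy_labels(5, 5)
  x1 <- ifelse(y == "case", 1, -1) + rnorm(10, sd = 0.1)
  f1 <- fit_plsda(matrix(x1, 10, 1), y, A = 1)
  expect_equal(vip_scores(f1)$vip, 1, tolerance = 1e-10)

  # p identical predictors share the weight equally: all VIP = 1
  Xeq <- matrix(rep(x1, 4), 10, 4)
  feq <- fit_plsda(Xeq, y, A = 1)
  expect_equal(vip_scores(feq)$vip, rep(1, 4), tolerance = 1e-8)
})

test_that("planted edges carry higher VIP than null edges", {
  higher <- 0L
  for (s in 1:10) {
    sp <- small_spec(seed = 7000 + s, n_planted = 6, d = 1.5, R = 10)
    ds <- generate_edge_dataset(sp, "Alpha")
    gt <- ground_truth(sp, "Alpha")$edge
    fit <- fit_plsda(ds$X, ds$labels, A = 2)
    v <- vip_scores(fit)$vip
    higher <- higher + (mean(v[gt]) > mean(v[-gt]))
  }
  expect_gte(higher, 9)
})

test_that("PLS-DA cross-validated accuracy tracks the data difficulty", {
  set.seed(37)
  X <- matrix(runif(24 * 3, 0.3, 0.5), 24, 3)
  y <- toy_labels(12, 12)
  X[y == "case", ] <- X[y == "case", ] + 0.4
  expect_equal(plsda_cv_performance(X, y, A = 2, k = 4, seed = 1)$accuracy, 1)

  accs <- vapply(1:5, function(s) {
    set.seed(8000 + s)
    plsda_cv_performance(matrix(rnorm(24 * 3), 24, 3), sample(y),
                         A = 2, k = 4, seed = s)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.2)
})

test_that("SVM and PLS-DA agree on strongly discriminative consensus edges", {
  gaps <- numeric(10)
  for (s in 1:10) {
    sp <- small_spec(seed = 9000 + s, n_planted = 8, d = 2.5, R = 12)
    ds <- generate_edge_dataset(sp, "Alpha")
    gt <- ground_truth(sp, "Alpha")$edge
    sel <- subset_edges(ds, gt)
    fit <- train_final_svm(sel, sel$edge_ids, fast_control(k_folds = 5),
                           seed = s)
    pls <- plsda_cv_performance(sel$X, sel$labels, A = 2, k = 5, seed = s)
    gaps[s] <- abs(fit$cv_mean - pls$accuracy)
  }
  expect_lte(median(gaps), 0.15)
})

test_that("PLS-DA rejects designs it cannot fit", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_plsda(X, toy_labels(5, 5), A = 5), "exceed")
  expect_error(fit_plsda(cbind(X, 1), toy_labels(5, 5), A = 1), "constant")
  expect_error(fit_plsda(X, rep("case", 10), A = 1), "both classes")
})
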