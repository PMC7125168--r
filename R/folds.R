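#' Stratified train/test split by participant
#'
#' Holds out `round(test_fraction * n)` participants, allocated per class
#' by largest-remainder rounding so class proportions are preserved and
#' the total is exact. With 23 case and 21 control subjects at the
#' default fraction this yields a 35-subject training set and a 9-subject
#' test set (5 case, 4 control). Both classes are guaranteed in both
#' parts.
#'
#' @param dataset a [connectome_dataset()] with >= 2 subjects per class.
#' @param test_fraction held-out fraction, default 0.2.
#' @param seed integer seed; the same seed always yields the same split.
#' @return A list of class `split_spec` with `train_ids`, `test_ids`,
#'   `test_fraction`, `seed`.
#' @export
stratified_split <- function(dataset, test_fraction = 0.2, seed = 1) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  y <- dataset$labels
  if (min(table(y)) < 2) stop("each class needs at least 2 subjects")
  n <- length(y)
  n_test <- round(test_fraction * n)
  per_class <- table(y) * test_fraction
  base <- floor(per_class)
  rem <- n_test - sum(base)
  if (rem > 0) {
    order_frac <- order(per_class - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  if (any(base < 1) || any(base >= table(y)))
    stop("a class is too small to appear in both the test and training set")
  set.seed(derive_seed(seed, "split"))
  test_ids <- character(0)
  for (cl in names(base)) {
    ids_cl <- dataset$subject_ids[y == cl]
    test_ids <- c(test_ids, sample(ids_cl, base[[cl]]))
  }
  test_ids <- dataset$subject_ids[dataset$subject_ids %in% test_ids]
  structure(
    list(train_ids = setdiff(dataset$subject_ids, test_ids),
         test_ids = test_ids, test_fraction = test_fraction,
         seed = as.integer(seed)),
    class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$test_fraction, x$seed))
  invisible(x)
}

# Stratified k-fold assignment. Each class is shuffled and dealt
# round-robin across folds; draws where some fold's *training* portion
# would lose a class are re-drawn with an incremented sub-seed.
make_stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  if (k < 2) stop("k must be >= 2")
  if (k > length(y)) stop("k cannot exceed the number of subjects")
  for (try in 0:99) {
    set.seed(derive_seed(seed, "folds", try))
    fold <- integer(length(y))
    offset <- 0
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- ((seq_along(idx) - 1 + offset) %% k) + 1
      offset <- offset + length(idx)
    }
    ok <- all(vapply(seq_len(k), function(f)
      nlevels(droplevels(y[fold != f])) == nlevels(droplevels(y)), TRUE))
    if (ok) {
      attr(fold, "redraws") <- try
      return(fold)
    }
  }
  stop("could not build stratified folds keeping both classes in every training portion")
}
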