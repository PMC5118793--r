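make_clouds <- function(n_per, d = 4, sep = 6, classes = 2, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(classes), function(c) {
    matrix(rnorm(n_per * d, mean = sep * c), n_per, d)
  }))
  list(X = X, y = rep(letters[seq_len(classes)], each = n_per))
}

test_that("separable clouds classify perfectly with zero spread", {
  cl <- make_clouds(30)
  for (clf in c("max_margin", "nearest_neighbour")) {
    cv <- cross_validate(cl$X, cl$y, classifier = clf, folds = 5,
                         repetitions = 3, seed = 2)
    expect_equal(cv$mean_accuracy, 100)
    expect_equal(cv$sd_accuracy, 0)
    expect_equal(sum(cv$confusion), 3 * 60)
  }
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(3)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- sample(rep(c("a", "b", "c", "d"), each = 50))
  cv <- cross_validate(X, y, folds = 5, repetitions = 10, seed = 4)
  # permutation null: 25% within 3 sds of the repetition spread + binomial se
  se <- sqrt(25 * 75 / 200)
  expect_lt(abs(cv$mean_accuracy - 25), 3 * max(cv$sd_accuracy, se))
})

test_that("cross-validation is deterministic given the seed", {
  cl <- make_clouds(20, sep = 1.5)
  a <- cross_validate(cl$X, cl$y, folds = 4, repetitions = 5, seed = 7)
  b <- cross_validate(cl$X, cl$y, folds = 4, repetitions = 5, seed = 7)
  expect_equal(a$accuracies, b$accuracies)
  expect_equal(a$confusion, b$confusion)
})

test_that("fold assignment is a stratified partition", {
  y <- factor(rep(c("a", "b"), times = c(40, 20)))
  set.seed(1)
  fold <- llna:::stratified_folds(y, 4)
  expect_equal(sort(unique(fold)), 1:4)
  expect_equal(as.vector(table(fold[y == "a"])), rep(10, 4))
  expect_equal(as.vector(table(fold[y == "b"])), rep(5, 4))
})

test_that("degenerate class sizes are rejected", {
  X <- matrix(rnorm(12), 6)
  expect_error(cross_validate(X, rep("a", 6), folds = 2), "2 classes")
  expect_error(cross_validate(X, c("a", "a", "a", "a", "a", "b"), folds = 3),
               "fewer samples than folds")
})

test_that("resampled validation balances classes and aggregates draws", {
  cl <- make_clouds(40, sep = 6)
  idx <- c(1:40, 41:55)  # unbalanced: 40 vs 15
  cv <- resampled_validate(cl$X[idx, ], cl$y[idx], folds = 3,
                           configurations = 20, seed = 5)
  expect_length(cv$accuracies, 20)
  expect_equal(cv$mean_accuracy, 100)
  # each configuration classifies 2 * 15 balanced samples
  expect_equal(sum(cv$confusion), 20 * 30)
})

test_that("tidy and glance return tibble summaries", {
  cl <- make_clouds(15)
  cv <- cross_validate(cl$X, cl$y, folds = 3, repetitions = 2, seed = 6)
  td <- generics::tidy(cv)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$class, c("a", "b"))
  gl <- generics::glance(cv)
  expect_equal(gl$mean_accuracy, cv$mean_accuracy)
  expect_equal(gl$folds, 3)
})

test_that("empty rule yields chance-level rule-scan accuracy; ranking sorted", {
  ds <- build_dataset(synthetic_dataset_spec(mean_degrees = 8, Ns = 60,
                                             replicates = 6), master_seed = 3)
  scan <- rule_scan(c("B/S", "B135678/S03456", "B3/S23"), ds, t = 40,
                    folds = 3, repetitions = 2, seed = 8)
  expect_equal(nrow(scan), 3)
  expect_true(!is.unsorted(rev(scan$accuracy)))
  # all-dead dynamics carry no signal: B/S near 25% on 4 balanced classes
  expect_lt(scan$accuracy[scan$rule == "B/S"], 60)
})

test_that("run_experiment wires dataset -> features -> CV end to end", {
  ds <- build_dataset(synthetic_dataset_spec(mean_degrees = 8, Ns = 80,
                                             replicates = 8), master_seed = 4)
  cv <- run_experiment(ds, rule = "B135678/S03456", t = 60, folds = 4,
                       repetitions = 2, seed = 9)
  expect_s3_class(cv, "llna_cv")
  expect_gt(cv$mean_accuracy, 50)  # 4 balanced classes, chance 25%
  feats <- attr(cv, "features")
  expect_equal(nrow(feats), nrow(ds))
  cvs <- run_experiment(ds, feature = "structural", folds = 4,
                        repetitions = 2, seed = 9)
  expect_s3_class(cvs, "llna_cv")
})
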