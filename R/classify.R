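#' Repeated stratified cross-validation
#'
#' Evaluates a classifier on a feature matrix by stratified n-fold
#' cross-validation, re-randomizing the fold assignment on every
#' repetition. The reported standard deviation is over repetitions (each
#' repetition's accuracy is the pooled accuracy of its folds), matching the
#' convention that the spread reflects run-to-run fold variation.
#'
#' @param features A data frame or matrix of numeric features (non-numeric
#'   and `label` columns are dropped from the predictors).
#' @param labels Class labels (coerced to factor).
#' @param classifier `"max_margin"` (support vector machine with RBF
#'   kernel, the default library settings) or `"nearest_neighbour"`
#'   (k-nearest neighbours, `k = 1` by default).
#' @param folds Number of folds (default 10).
#' @param repetitions Number of repeated CV runs (default 10).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param k Neighbour count for the nearest-neighbour classifier.
#' @param cost Soft-margin cost of the max-margin classifier.
#' @param gamma RBF kernel width; default is the median heuristic
#'   (1 / median squared pairwise training distance, recomputed per fold
#'   on the standardized features).
#' @return An `llna_cv` object: list with `accuracies` (% per repetition),
#'   `mean_accuracy`, `sd_accuracy`, `confusion` (matrix pooled over all
#'   repetitions, rows = true class), `per_class_accuracy`, and the run
#'   settings. Use [generics::tidy()] / [generics::glance()] for tibble
#'   views.
#' @examples
#' x <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60, 3), 30))
#' cv <- cross_validate(x, rep(c("a", "b"), each = 30), folds = 5, seed = 1)
#' glance(cv)
#' @export
cross_validate <- function(features, labels,
                           classifier = c("max_margin", "nearest_neighbour"),
                           folds = 10, repetitions = 10, seed = NULL, k = 1,
                           cost = 100, gamma = NULL) {
  classifier <- match.arg(classifier)
  X <- predictor_matrix(features)
  y <- factor(labels)
  stopifnot(nrow(X) == length(y))
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (min(table(y)) < folds) {
    stop("smallest class (", min(table(y)), ") has fewer samples than folds (",
         folds, ")", call. = FALSE)
  }
  with_seed(seed, {
    acc <- numeric(repetitions)
    conf <- matrix(0, nlevels(y), nlevels(y),
                   dimnames = list(true = levels(y), predicted = levels(y)))
    for (r in seq_len(repetitions)) {
      fold <- stratified_folds(y, folds)
      pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
      for (f in seq_len(folds)) {
        test <- fold == f
        pred[test] <- fit_predict(classifier, X[!test, , drop = FALSE],
                                  y[!test], X[test, , drop = FALSE], k,
                                  cost, gamma)
      }
      acc[r] <- 100 * mean(pred == y)
      conf <- conf + table(y, pred)
    }
    new_llna_cv(acc, conf, classifier, folds, repetitions)
  })
}

predictor_matrix <- function(features) {
  df <- as.data.frame(features)
  df <- df[vapply(df, is.numeric, logical(1))]
  df$label <- NULL
  as.matrix(df)
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(sample.int(folds), length(idx)))
  }
  fold
}

# Both routes standardize features with training-fold statistics
# (zero-variance columns left untouched) so heterogeneous-scale descriptors
# - e.g. the [muS, muW, muL] averages - do not drown the metric. The RBF
# bandwidth follows the median heuristic (gamma = 1 / median squared
# pairwise distance of the training samples) and the default cost is 100;
# library-default cost and bandwidth underfit concatenated histogram
# descriptors to near-chance.
fit_predict <- function(classifier, X_train, y_train, X_test, k = 1,
                        cost = 100, gamma = NULL) {
  mu <- colMeans(X_train)
  sd_ <- apply(X_train, 2, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  Xtr <- scale(X_train, mu, sd_)
  Xte <- scale(X_test, mu, sd_)
  if (classifier == "max_margin") {
    if (is.null(gamma)) {
      d2 <- stats::dist(if (nrow(Xtr) > 400) Xtr[sample.int(nrow(Xtr), 400), ,
                                                 drop = FALSE] else Xtr)^2
      med <- stats::median(as.vector(d2))
      gamma <- if (is.finite(med) && med > 0) 1 / med else 1 / ncol(Xtr)
    }
    fit <- e1071::svm(Xtr, y_train, kernel = "radial", scale = FALSE,
                      cost = cost, gamma = gamma)
    stats::predict(fit, Xte)
  } else {
    class::knn(Xtr, Xte, y_train, k = k)
  }
}

new_llna_cv <- function(acc, conf, classifier, folds, repetitions) {
  per_class <- diag(conf) / pmax(rowSums(conf), 1)
  structure(
    list(
      accuracies = acc,
      mean_accuracy = mean(acc),
      sd_accuracy = stats::sd(acc),
      confusion = conf,
      per_class_accuracy = 100 * per_class,
      classifier = classifier,
      folds = folds,
      repetitions = repetitions
    ),
    class = "llna_cv"
  )
}

#' @export
print.llna_cv <- function(x, ...) {
  cat("<llna_cv> ", x$classifier, ", ", x$folds, "-fold x ", x$repetitions,
      " repetitions\n", sep = "")
  cat(sprintf("  accuracy: %.2f +- %.2f %%\n", x$mean_accuracy,
              if (is.na(x$sd_accuracy)) 0 else x$sd_accuracy))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.llna_cv <- function(x, ...) {
  tibble::tibble(
    class = names(x$per_class_accuracy),
    accuracy = unname(x$per_class_accuracy),
    n = unname(rowSums(x$confusion))
  )
}

#' @export
glance.llna_cv <- function(x, ...) {
  tibble::tibble(
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = x$sd_accuracy,
    classifier = x$classifier,
    folds = x$folds,
    repetitions = x$repetitions
  )
}

#' Resampled validation for unbalanced classes
#'
#' Each configuration subsamples every class to the smallest class size,
#' runs one stratified `folds`-fold CV on the balanced subset, and the
#' accuracies are aggregated over configurations.
#'
#' @inheritParams cross_validate
#' @param folds Fold count (default 3).
#' @param configurations Number of random balanced subsamples (default 100).
#' @return An `llna_cv` object (one accuracy per configuration).
#' @export
resampled_validate <- function(features, labels,
                               classifier = c("max_margin",
                                              "nearest_neighbour"),
                               folds = 3, configurations = 100, seed = NULL,
                               k = 1, cost = 100, gamma = NULL) {
  classifier <- match.arg(classifier)
  X <- predictor_matrix(features)
  y <- factor(labels)
  n_min <- min(table(y))
  if (n_min < folds) {
    stop("smallest class has fewer samples than folds", call. = FALSE)
  }
  with_seed(seed, {
    acc <- numeric(configurations)
    conf <- matrix(0, nlevels(y), nlevels(y),
                   dimnames = list(true = levels(y), predicted = levels(y)))
    for (cfg in seq_len(configurations)) {
      keep <- unlist(lapply(levels(y), function(cl) {
        sample(which(y == cl), n_min)
      }))
      ycfg <- droplevels(y[keep])
      fold <- stratified_folds(ycfg, folds)
      pred <- factor(rep(NA_character_, length(keep)), levels = levels(y))
      for (f in seq_len(folds)) {
        test <- fold == f
        pred[test] <- fit_predict(classifier, X[keep[!test], , drop = FALSE],
                                  ycfg[!test], X[keep[test], , drop = FALSE],
                                  k, cost, gamma)
      }
      acc[cfg] <- 100 * mean(pred == ycfg)
      conf <- conf + table(factor(ycfg, levels = levels(y)), pred)
    }
    new_llna_cv(acc, conf, classifier, folds, configurations)
  })
}

#' Evolve a dataset and build its feature matrix
#'
#' Runs the automaton on every network of a dataset manifest and assembles
#' the descriptor matrix; the workhorse behind the experiments.
#'
#' @param dataset A tibble from [build_dataset()].
#' @param rule Life-like rule.
#' @param t Evolution steps (default 350).
#' @param sigma Initial alive fraction (default 0.5).
#' @param include_initial Include the initial row in measured series.
#' @return The dataset tibble with the 63 feature columns appended.
#' @export
dataset_features <- function(dataset, rule, t = 350, sigma = 0.5,
                             include_initial = TRUE) {
  rule <- llna_rule(rule)
  measures <- purrr::map2(dataset$graph, dataset$seed, function(g, s) {
    # evolution seed offset from the generation seed keeps the two draws
    # distinct but paired across rules
    d <- llna_evolve(g, rule, t = t, sigma = sigma,
                     seed = (s + 1013904223) %% 2147483629)
    measure_diagram(d, include_initial = include_initial)
  })
  feats <- feature_matrix(measures)
  dplyr::bind_cols(dplyr::select(dataset, -"graph"), feats)
}

#' Rule-selection scan
#'
#' Evaluates candidate Life-like rules on a labeled rule-selection dataset:
#' every network is evolved once per rule (with a per-network seed reused
#' across rules, so rule comparisons are paired), the chosen descriptor is
#' extracted, and the rule's cross-validated accuracy recorded. Returns the
#' ranking in descending accuracy with ties broken by canonical rule order.
#'
#' @param rules Character vector of rule names (a subset of the 262144-rule
#'   space; the full scan is the same call with all names).
#' @param dataset A tibble from [build_dataset()].
#' @param feature Descriptor variant: `"hS"` (entropy histogram, the scan
#'   default), `"hW"`, `"hL"`, `"combined"` or `"averages"`.
#' @param classifier Classifier for the scan (nearest neighbour default).
#' @param t,sigma Automaton parameters.
#' @param folds,repetitions CV settings per rule.
#' @param seed Integer seed.
#' @return A tibble `rule`, `accuracy`, `sd`, sorted best-first.
#' @export
rule_scan <- function(rules, dataset,
                      feature = c("hS", "hW", "hL", "combined", "averages"),
                      classifier = c("nearest_neighbour", "max_margin"),
                      t = 350, sigma = 0.5, folds = 10, repetitions = 3,
                      seed = 1) {
  feature <- match.arg(feature)
  classifier <- match.arg(classifier)
  stopifnot(length(rules) >= 1)
  rows <- purrr::imap(rules, function(rl, i) {
    feats <- dataset_features(dataset, rl, t = t, sigma = sigma)
    cv <- cross_validate(feats[feature_columns(feature)], feats$model,
                         classifier = classifier, folds = folds,
                         repetitions = repetitions,
                         seed = (seed + 7 * i) %% 2147483629)
    tibble::tibble(rule = llna_rule(rl)$name, accuracy = cv$mean_accuracy,
                   sd = cv$sd_accuracy)
  })
  out <- dplyr::bind_rows(rows)
  out$rule_order <- vapply(out$rule, rule_id, numeric(1))
  out <- dplyr::arrange(out, dplyr::desc(.data$accuracy), .data$rule_order)
  out$rule_order <- NULL
  out
}

#' Run an end-to-end classification experiment
#'
#' Generates (or accepts) a labeled dataset, evolves the automaton with one
#' rule, extracts a descriptor variant, and cross-validates a classifier.
#'
#' @param dataset A tibble from [build_dataset()].
#' @param rule Life-like rule.
#' @param feature Descriptor variant (see [rule_scan()]), or
#'   `"structural"` for the structural-measure baseline.
#' @param labels Either a column name of the dataset or a vector of class
#'   labels; default the `model` column. Use e.g.
#'   `interaction(dataset$model, dataset$mean_degree)` for the 28-class
#'   task.
#' @param classifier,folds,repetitions,seed CV settings.
#' @param t,sigma Automaton parameters.
#' @param include_mean_degree For `feature = "structural"`: keep mean degree
#'   as a predictor (drop it when mean degree partly defines the classes).
#' @return An `llna_cv` with the feature matrix attached as attribute
#'   `features`.
#' @export
run_experiment <- function(dataset, rule = "B135678/S03456",
                           feature = "combined", labels = "model",
                           classifier = "max_margin", folds = 10,
                           repetitions = 10, seed = 1, t = 350, sigma = 0.5,
                           include_mean_degree = FALSE) {
  y <- if (is.character(labels) && length(labels) == 1) dataset[[labels]]
       else labels
  if (identical(feature, "structural")) {
    feats <- structural_feature_matrix(
      dataset, include_mean_degree = include_mean_degree)
    X <- feats[setdiff(names(feats), grep("^spec_", names(feats), value = TRUE))]
  } else {
    feats <- dataset_features(dataset, rule, t = t, sigma = sigma)
    X <- feats[feature_columns(feature)]
  }
  cv <- cross_validate(X, y, classifier = classifier, folds = folds,
                       repetitions = repetitions, seed = seed)
  attr(cv, "features") <- feats
  cv
}
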