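# ---- freshness grading and classification ----------------------------------

#' Default Haugh-unit grade cutoffs
#'
#' USDA-convention interior-quality cutoffs: AA for HU >= 72, A for
#' HU >= 60, B for HU >= 31, C below. Boundaries belong to the higher
#' grade. The cutoffs are configuration-exposed throughout.
#'
#' @return Named numeric vector `c(AA = 72, A = 60, B = 31)`.
#' @export
hu_grade_cutoffs <- function() c(AA = 72, A = 60, B = 31)

#' Grade labels from Haugh units
#'
#' @param hu Numeric vector of Haugh units.
#' @param cutoffs Strictly decreasing named cutoffs, see
#'   [hu_grade_cutoffs()]. A value equal to a cutoff takes the higher
#'   grade.
#' @return Factor with levels `AA`, `A`, `B`, `C`.
#' @export
grade_from_hu <- function(hu, cutoffs = hu_grade_cutoffs()) {
  if (any(!is.finite(hu))) abort("HU values must be finite")
  if (length(cutoffs) != 3 || any(diff(cutoffs) >= 0)) {
    abort("cutoffs must be three strictly decreasing values (AA, A, B)")
  }
  lv <- c("AA", "A", "B", "C")
  idx <- 4L - (hu >= cutoffs[1]) - (hu >= cutoffs[2]) - (hu >= cutoffs[3])
  factor(lv[idx], levels = lv)
}

#' Min-max feature normalization
#'
#' Scales each feature column to `[0, 1]` using per-column minima and
#' maxima fitted on the supplied rows; pass the returned `params` back in
#' to apply a training-set scaling to new rows (values outside the
#' training range then fall outside `[0, 1]`, which is allowed). Constant
#' columns map to 0 with a warning.
#'
#' @param data Data frame; all numeric columns are scaled.
#' @param params Optional tibble from a previous call (`column`, `min`,
#'   `max`).
#' @return List with `data` (scaled tibble) and `params`.
#' @export
normalize_features <- function(data, params = NULL) {
  stopifnot(is.data.frame(data))
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (is.null(params)) {
    if (nrow(data) < 2) abort("normalization requires at least 2 rows")
    if (any(vapply(data[num_cols], function(x) any(is.na(x)), logical(1)))) {
      abort("normalization input contains NA")
    }
    params <- tibble(
      column = num_cols,
      min = unname(vapply(data[num_cols], min, numeric(1))),
      max = unname(vapply(data[num_cols], max, numeric(1)))
    )
    if (any(params$min == params$max)) {
      warn(sprintf("constant feature column(s) mapped to 0: %s",
                   paste(params$column[params$min == params$max], collapse = ", ")))
    }
  }
  out <- data
  for (r in seq_len(nrow(params))) {
    cl <- params$column[r]
    if (!cl %in% names(out)) next
    rngw <- params$max[r] - params$min[r]
    out[[cl]] <- if (rngw == 0) rep(0, nrow(out)) else (out[[cl]] - params$min[r]) / rngw
  }
  list(data = as_tibble(out), params = params)
}

#' Classifier configuration
#'
#' Hyperparameters for the five freshness classifiers: Gaussian naive
#' Bayes (`nbm`), k-nearest neighbours with Euclidean distance (`knn`,
#' default `k = 3`), CART decision tree (`tree`), random forest (`rf`,
#' 100 trees, minimum leaf size 5) and C-SVC support vector machine
#' (`svm`, RBF kernel, `C = 111.4305`, `gamma = 0.5743`, one-vs-one
#' multi-class).
#'
#' @param model One of `"nbm"`, `"knn"`, `"tree"`, `"rf"`, `"svm"`.
#' @param knn_k Neighbours for `knn`.
#' @param rf_trees,rf_min_leaf Random-forest size and minimum leaf size.
#' @param svm_cost,svm_gamma,svm_kernel SVM penalty, RBF width and kernel
#'   (`"linear"`, `"polynomial"`, `"rbf"`).
#' @param seed Seed for stochastic fits.
#' @return A list of class `model_config`.
#' @export
model_config <- function(model = c("rf", "nbm", "knn", "tree", "svm"),
                         knn_k = 3, rf_trees = 100, rf_min_leaf = 5,
                         svm_cost = 111.4305, svm_gamma = 0.5743,
                         svm_kernel = c("rbf", "linear", "polynomial"),
                         seed = 1L) {
  model <- match.arg(model)
  svm_kernel <- match.arg(svm_kernel)
  stopifnot(knn_k >= 1, rf_trees >= 1, rf_min_leaf >= 1,
            svm_cost > 0, svm_gamma > 0)
  structure(list(model = model, knn_k = as.integer(knn_k),
                 rf_trees = as.integer(rf_trees),
                 rf_min_leaf = as.integer(rf_min_leaf),
                 svm_cost = svm_cost, svm_gamma = svm_gamma,
                 svm_kernel = svm_kernel, seed = as.integer(seed)),
            class = "model_config")
}

.feature_matrix <- function(data, grade_col, feature_names = NULL) {
  if (is.null(feature_names)) {
    feature_names <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                             c(grade_col, "hu"))
  }
  missing <- setdiff(feature_names, names(data))
  if (length(missing)) {
    abort(sprintf("missing feature column(s): %s", paste(missing, collapse = ", ")))
  }
  as.matrix(data[feature_names])
}

#' Fit a freshness classifier
#'
#' Features (all numeric columns except the grade and any `hu` column) are
#' min-max normalized with parameters fitted on the training rows; the
#' normalization is stored in the model and re-applied at prediction time.
#'
#' @param data Data frame of features plus a grade column.
#' @param config A [model_config()].
#' @param grade_col Name of the grade column (factor or character).
#' @return An object of class `freshness_model`.
#' @export
fit_freshness_model <- function(data, config = model_config(),
                                grade_col = "grade") {
  stopifnot(is.data.frame(data), inherits(config, "model_config"))
  if (!grade_col %in% names(data)) abort(sprintf("no column '%s'", grade_col))
  y <- data[[grade_col]]
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) abort("training data must contain at least 2 classes")
  feature_names <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                           c(grade_col, "hu"))
  norm <- normalize_features(data[feature_names])
  X <- as.matrix(norm$data)
  fit <- withr::with_seed(config$seed, switch(config$model,
    nbm = e1071::naiveBayes(X, y),
    knn = list(train = X, cl = y),
    tree = {
      df <- as.data.frame(X)
      df$.grade <- y
      rpart::rpart(.grade ~ ., data = df, method = "class")
    },
    rf = randomForest::randomForest(X, y, ntree = config$rf_trees,
                                    nodesize = config$rf_min_leaf),
    svm = e1071::svm(X, y, type = "C-classification",
                     kernel = switch(config$svm_kernel, rbf = "radial",
                                     linear = "linear",
                                     polynomial = "polynomial"),
                     cost = config$svm_cost, gamma = config$svm_gamma,
                     scale = FALSE)
  ))
  structure(list(config = config, fit = fit, norm_params = norm$params,
                 feature_names = feature_names, levels = levels(y),
                 n_train = nrow(data)),
            class = "freshness_model")
}

#' @method print freshness_model
#' @export
print.freshness_model <- function(x, ...) {
  cat(sprintf("<freshness_model:%s> %d features, %d training rows, grades %s\n",
              x$config$model, length(x$feature_names), x$n_train,
              paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Predict freshness grades
#'
#' @param object A [fit_freshness_model()] result.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted grades with the training levels.
#' @export
predict.freshness_model <- function(object, newdata, ...) {
  X <- .feature_matrix(newdata, grade_col = NULL,
                       feature_names = object$feature_names)
  X <- as.matrix(normalize_features(as.data.frame(X),
                                    params = object$norm_params)$data)
  cfg <- object$config
  pred <- withr::with_seed(cfg$seed, switch(cfg$model,
    nbm = predict(object$fit, X),
    knn = class::knn(object$fit$train, X, object$fit$cl, k = cfg$knn_k),
    tree = {
      cls <- predict(object$fit, as.data.frame(X), type = "class")
      cls
    },
    rf = predict(object$fit, X),
    svm = predict(object$fit, X)
  ))
  factor(as.character(pred), levels = object$levels)
}

#' Choose k for the KNN model by cross-validation
#'
#' Stratified `folds`-fold cross-validation over the candidate neighbour
#' counts; returns the k with the highest mean validation accuracy, ties
#' resolving to the smallest k.
#'
#' @param data Data frame of features plus grade column.
#' @param ks Candidate neighbour counts.
#' @param folds Number of folds (>= 2).
#' @param grade_col Grade column name.
#' @param seed Seed for the fold assignment.
#' @return The selected k (integer).
#' @export
select_k_cv <- function(data, ks = c(1, 3, 5, 7, 9), folds = 5,
                        grade_col = "grade", seed = 1L) {
  stopifnot(folds >= 2, length(ks) >= 1)
  y <- factor(data[[grade_col]])
  if (min(table(y)) < folds) {
    abort("each class needs at least `folds` members for stratified CV")
  }
  feature_names <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                           c(grade_col, "hu"))
  X <- as.matrix(normalize_features(data[feature_names])$data)
  # the whole CV runs under the seed: class::knn breaks distance ties randomly
  acc <- withr::with_seed(as.integer(seed), {
    fold_id <- integer(nrow(data))
    for (lv in levels(y)) {
      rows <- which(y == lv)
      fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    vapply(ks, function(k) {
      mean(vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        pred <- class::knn(X[tr, , drop = FALSE], X[!tr, , drop = FALSE],
                           y[tr], k = k)
        mean(pred == y[!tr])
      }, numeric(1)))
    }, numeric(1))
  })
  ks[which.max(acc)]   # which.max takes the first (smallest k) on ties
}

#' Confusion report from per-grade counts
#'
#' @param sizes Named or ordered per-grade sample sizes.
#' @param correct Per-grade correctly classified counts.
#' @param grades Grade labels (default AA/A/B/C).
#' @return A tibble of class `confusion_report` with columns `grade`, `n`,
#'   `correct`; the overall accuracy is available via [overall_accuracy()]
#'   or `glance()`.
#' @export
confusion_report <- function(sizes, correct, grades = c("AA", "A", "B", "C")) {
  stopifnot(length(sizes) == length(correct), length(sizes) == length(grades))
  if (any(correct > sizes) || any(correct < 0) || any(sizes < 0)) {
    abort("need 0 <= correct <= sample size per grade")
  }
  out <- tibble(grade = factor(grades, levels = grades),
                n = as.integer(sizes), correct = as.integer(correct))
  class(out) <- c("confusion_report", class(out))
  out
}

#' Overall accuracy of a confusion report, in percent
#'
#' `100 * sum(correct) / sum(n)`.
#'
#' @param report A [confusion_report()].
#' @return Percentage in `[0, 100]`.
#' @export
overall_accuracy <- function(report) {
  stopifnot(inherits(report, "confusion_report"))
  100 * sum(report$correct) / sum(report$n)
}

#' @method print confusion_report
#' @export
print.confusion_report <- function(x, ...) {
  NextMethod()
  cat(sprintf("overall accuracy: %.2f%%\n", overall_accuracy(x)))
  invisible(x)
}

#' Evaluate a fitted model on labeled data
#'
#' @param model A [fit_freshness_model()] result.
#' @param data Data frame with the feature columns and true grades.
#' @param grade_col Grade column name.
#' @return A [confusion_report()] over the model's grade levels.
#' @export
evaluate_model <- function(model, data, grade_col = "grade") {
  stopifnot(inherits(model, "freshness_model"))
  y <- factor(data[[grade_col]])
  unseen <- setdiff(levels(droplevels(y)), model$levels)
  if (length(unseen)) {
    abort(sprintf("unseen grade label(s): %s", paste(unseen, collapse = ", ")))
  }
  y <- factor(as.character(y), levels = model$levels)
  pred <- predict(model, data)
  sizes <- as.integer(table(y))
  correct <- vapply(model$levels, function(lv) {
    sum(y == lv & pred == lv)
  }, numeric(1))
  confusion_report(sizes, correct, grades = model$levels)
}

#' Stratified train/validation split
#'
#' @param data Data frame with a grade column.
#' @param train_frac Fraction of rows per grade assigned to training
#'   (0.75 reproduces a 3:1 split, 0.8 a 4:1 split).
#' @param grade_col Grade column name.
#' @param seed Split seed.
#' @return List with `train` and `validation` tibbles.
#' @export
split_dataset <- function(data, train_frac = 0.75, grade_col = "grade",
                          seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  y <- factor(data[[grade_col]])
  if (any(table(y) < 2)) {
    warn("grade(s) with fewer than 2 rows: stratification degraded")
  }
  tr_rows <- withr::with_seed(as.integer(seed), {
    unlist(lapply(levels(y), function(lv) {
      rows <- which(y == lv)
      n_tr <- max(1L, min(length(rows) - 1L, round(train_frac * length(rows))))
      if (length(rows) == 1) return(rows)   # degraded: keep in train
      sample(rows, n_tr)
    }))
  })
  list(train = as_tibble(data[sort(tr_rows), , drop = FALSE]),
       validation = as_tibble(data[setdiff(seq_len(nrow(data)), tr_rows), ,
                                   drop = FALSE]))
}
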