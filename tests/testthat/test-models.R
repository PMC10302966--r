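# grading, normalization, classifiers, confusion reports

test_that("grade boundaries belong to the higher grade", {
  expect_equal(as.character(grade_from_hu(c(80, 72, 71.9, 60, 59, 31, 20))),
               c("AA", "AA", "A", "A", "B", "B", "C"))
  expect_error(grade_from_hu(50, cutoffs = c(AA = 60, A = 60, B = 31)),
               "decreasing")
  expect_error(grade_from_hu(NA_real_), "finite")
})

test_that("min-max normalization scales and transfers", {
  out <- normalize_features(tibble::tibble(a = c(2, 4, 6)))
  expect_equal(out$data$a, c(0, 0.5, 1))

  # train params applied to out-of-range test values may leave [0, 1]
  test <- normalize_features(tibble::tibble(a = 8), params = out$params)
  expect_equal(test$data$a, 1.5)

  expect_warning(normalize_features(tibble::tibble(a = c(3, 3, 3))),
                 "constant")
  suppressWarnings({
    const <- normalize_features(tibble::tibble(a = c(3, 3, 3)))
  })
  expect_equal(const$data$a, c(0, 0, 0))
  expect_error(normalize_features(tibble::tibble(a = 1)), "2 rows")
  expect_error(normalize_features(tibble::tibble(a = c(1, NA))), "NA")
})

test_that("separable synthetic classes are learned almost perfectly", {
  tab <- sample_feature_table(50, 6, seed = 9)
  sp <- split_dataset(tab, 0.75, seed = 9)
  for (mdl in c("rf", "svm")) {
    fm <- fit_freshness_model(sp$train, model_config(mdl, seed = 9))
    acc <- overall_accuracy(evaluate_model(fm, sp$validation))
    expect_gte(acc, 95)
  }
})

test_that("zero separation yields chance-level accuracy", {
  tab <- sample_feature_table(60, 0, seed = 10)
  sp <- split_dataset(tab, 0.75, seed = 10)
  fm <- fit_freshness_model(sp$train, model_config("rf", seed = 10))
  acc <- overall_accuracy(evaluate_model(fm, sp$validation))
  # binomial band around 25% for n = 60 held-out rows
  expect_gt(acc, 8)
  expect_lt(acc, 45)
})

test_that("fits are deterministic and reject degenerate input", {
  tab <- sample_feature_table(30, 5, seed = 11)
  f1 <- fit_freshness_model(tab, model_config("rf", seed = 3))
  f2 <- fit_freshness_model(tab, model_config("rf", seed = 3))
  expect_identical(predict(f1, tab), predict(f2, tab))

  single <- tab[tab$grade == "AA", ]
  expect_error(fit_freshness_model(single, model_config("nbm")),
               "2 classes")
})

test_that("KNN and naive Bayes ignore training-row order", {
  tab <- sample_feature_table(30, 4, seed = 12)
  perm <- withr::with_seed(1, sample(nrow(tab)))
  for (mdl in c("knn", "nbm")) {
    f1 <- fit_freshness_model(tab, model_config(mdl, seed = 5))
    f2 <- fit_freshness_model(tab[perm, ], model_config(mdl, seed = 5))
    expect_identical(predict(f1, tab), predict(f2, tab))
  }
})

test_that("cross-validated k selection applies its tie rule", {
  tab <- sample_feature_table(25, 5, seed = 14)
  expect_equal(select_k_cv(tab, ks = 7), 7)
  # separable data: every k ties at 100%, the smallest candidate wins
  expect_equal(select_k_cv(tab, ks = c(3, 5, 7)), 3)
  expect_error(select_k_cv(sample_feature_table(3, 5, seed = 1), folds = 5),
               "at least")
})

test_that("noisy class overlap favors k = 3 over k = 1", {
  # overlapping 1D clusters: 1-NN chases label noise, 3-NN averages it out
  withr::with_seed(42, {
    n <- 60
    tab <- tibble::tibble(
      f1 = c(rnorm(n, 0, 1.1), rnorm(n, 1.5, 1.1),
             rnorm(n, 3, 1.1), rnorm(n, 4.5, 1.1)),
      f2 = rnorm(4 * n),
      grade = factor(rep(c("AA", "A", "B", "C"), each = n),
                     levels = c("AA", "A", "B", "C"))
    )
  })
  expect_equal(select_k_cv(tab, ks = c(1, 3), seed = 2), 3)
})

test_that("confusion reports reproduce printed-table arithmetic", {
  t4 <- confusion_report(c(62, 54, 19, 11), c(58, 51, 16, 9))
  expect_equal(round(overall_accuracy(t4), 2), 91.78)
  t6 <- confusion_report(c(62, 54, 18, 12), c(60, 51, 16, 11))
  expect_equal(round(overall_accuracy(t6), 2), 94.52)

  # self-consistency on random counts
  withr::with_seed(3, {
    for (rep in 1:20) {
      n <- sample(5:80, 4)
      k <- vapply(n, function(m) sample(0:m, 1), integer(1))
      cr <- confusion_report(n, k)
      expect_equal(overall_accuracy(cr), 100 * sum(k) / sum(n))
      g <- generics::glance(cr)
      expect_equal(g$accuracy_pct, overall_accuracy(cr))
    }
  })
  expect_error(confusion_report(c(10, 10, 10, 10), c(11, 0, 0, 0)),
               "correct <= sample size")
})

test_that("evaluation counts per-grade hits and flags unseen labels", {
  tab <- sample_feature_table(20, 6, seed = 15)
  fm <- fit_freshness_model(tab, model_config("rf", seed = 15))
  rep_all <- evaluate_model(fm, tab)
  expect_equal(sum(rep_all$n), nrow(tab))
  expect_true(all(rep_all$correct <= rep_all$n))

  bad <- tab
  levels(bad$grade) <- c(levels(bad$grade), "ZZ")
  bad$grade[1] <- "ZZ"
  expect_error(evaluate_model(fm, bad), "unseen")
})

test_that("stratified splits honor ratio, seed and stratification", {
  tab <- sample_feature_table(50, 6, seed = 16)
  sp <- split_dataset(tab, 0.75, seed = 16)
  # 50 per grade at 3:1 rounds to 38 training rows per grade
  expect_equal(as.integer(table(sp$train$grade)), rep(38L, 4))
  expect_equal(nrow(sp$train) + nrow(sp$validation), 200)
  expect_lte(abs(nrow(sp$train) - 150), 4)   # stratification rounding
  sp2 <- split_dataset(tab, 0.75, seed = 16)
  expect_identical(sp$train, sp2$train)

  sp81 <- split_dataset(tab, 0.8, seed = 16)
  expect_equal(nrow(sp81$train), 160)
  expect_warning(split_dataset(tab[c(1, 51, 101, 151), ], 0.75, seed = 1),
                 "fewer than 2")
})
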