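test_that("macro accuracy is the mean per-class recall", {
  expect_equal(macro_avg_accuracy(c(1, 1, 2, 2), c(1, 2, 1, 2), 2), 50)
  expect_equal(macro_avg_accuracy(1:3, 1:3, 3), 100)
  # constant predictor: exactly 100/k whatever the imbalance
  y <- rep(c(1L, 2L, 3L), c(45, 10, 8))
  expect_equal(macro_avg_accuracy(y, rep(1L, 63), 3), 100 / 3)
  # only class 1 occurs in y_true: its recall 1/2 is the whole macro mean
  expect_warning(v <- macro_avg_accuracy(c(1, 1), c(1, 2), 3), "absent")
  expect_equal(v, 50)
  expect_error(macro_avg_accuracy(integer(), integer(), 2), "empty")
})

test_that("micro accuracy is the overall fraction correct", {
  expect_equal(micro_avg_accuracy(c(1, 2, 3), c(1, 2, 1)), 100 * 2 / 3)
  y <- rep(c(1L, 2L, 3L), c(45, 10, 8))
  expect_equal(micro_avg_accuracy(y, rep(1L, 63)), 100 * 45 / 63)
})

test_that("macro F1 uses the zero convention and averages all k classes", {
  f <- macro_f1(c(1, 1, 2, 3), c(1, 1, 3, 3), 3)
  # class 1 perfect; class 2 never predicted -> 0; class 3: p=1/2, r=1
  expect_equal(f$per_class_f1, c(100, 0, 100 * 2 / 3))
  expect_equal(f$macro_f1, mean(f$per_class_f1))
  perfect <- macro_f1(1:3, 1:3, 3)
  expect_equal(perfect$macro_f1, 100)
  expect_equal(perfect$per_class_f1, rep(100, 3))
})

test_that("all three criteria are invariant under simultaneous label permutation", {
  set.seed(10)
  y_true <- sample(1:3, 60, replace = TRUE)
  y_pred <- sample(1:3, 60, replace = TRUE)
  perm <- c(3L, 1L, 2L)
  expect_equal(macro_avg_accuracy(perm[y_true], perm[y_pred], 3),
               macro_avg_accuracy(y_true, y_pred, 3))
  expect_equal(micro_avg_accuracy(perm[y_true], perm[y_pred]),
               micro_avg_accuracy(y_true, y_pred))
  expect_equal(macro_f1(perm[y_true], perm[y_pred], 3)$macro_f1,
               macro_f1(y_true, y_pred, 3)$macro_f1)
})

test_that("the metrics report bundles criteria and a consistent confusion matrix", {
  rep_ <- metrics_report(c(1, 1, 2, 3), c(1, 2, 2, 3), 3,
                         class_names = c("a", "b", "c"))
  expect_equal(sum(rep_$confusion), 4)
  expect_equal(unname(diag(rep_$confusion)), c(1, 1, 1))
  expect_true(all(c(rep_$macro_avg_acc, rep_$micro_avg_acc,
                    rep_$macro_f1) >= 0))
  expect_true(all(rep_$per_class_f1 <= 100))
})

test_that("stratified folds balance every class to within one member", {
  y <- rep(c(1L, 2L, 3L), c(45, 10, 8))
  folds <- stratified_folds(y, 5, seed = 42)
  expect_equal(sort(unique(folds)), 1:5)
  for (c in 1:3) {
    per_fold <- tabulate(folds[y == c], nbins = 5)
    expect_lte(diff(range(per_fold)), 1L)
  }
  # class 1 has 45 members: exactly 9 per fold
  expect_equal(tabulate(folds[y == 1], nbins = 5), rep(9L, 5))
  expect_identical(folds, stratified_folds(y, 5, seed = 42))
  expect_false(identical(folds,
                         suppressWarnings(stratified_folds(y, 5, seed = 43))))
  # a class with fewer members than folds is allowed but flagged
  expect_warning(stratified_folds(c(1L, 1L, 1L, 2L), 3, seed = 1),
                 "some folds will lack")
})

test_that("cross-validation comparison is reproducible and handles baselines analytically", {
  ds <- gen_cases(case_gen_spec(seed = 6))
  algs <- list(majority = alg_majority(), majority2 = alg_majority(),
               random = alg_random())
  ct <- suppressWarnings(
    cross_validate_compare(ds, algs, n_folds = 5, seed = 9))
  # constant-majority macro accuracy is pinned near 100/k
  expect_equal(unname(ct$mean["macro_avg_acc", "majority"]), 100 / 3,
               tolerance = 0.05)
  # identical algorithms give identical columns
  expect_equal(ct$fold_values[, "majority", ], ct$fold_values[, "majority2", ])
  ct2 <- suppressWarnings(
    cross_validate_compare(ds, algs, n_folds = 5, seed = 9))
  expect_identical(ct$mean, ct2$mean)
  expect_identical(ct$fold_values, ct2$fold_values)
})

test_that("an algorithm failing on a fold leaves missing cells and the run continues", {
  ds <- gen_cases(case_gen_spec(seed = 6))
  broken <- function(x_train, y_train, k) stop("boom")
  warns <- character()
  ct <- withCallingHandlers(
    cross_validate_compare(ds, list(ok = alg_majority(), bad = broken),
                           n_folds = 3, seed = 2),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("boom", warns)))
  expect_true(all(is.na(ct$fold_values[, "bad", ])))
  expect_true(all(!is.na(ct$fold_values["micro_avg_acc", "ok", ])))
})
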