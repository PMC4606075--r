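#' Macro-averaged accuracy (mean per-class recall)
#'
#' The unweighted mean over classes of the per-class recall, in percent.
#' Weighing every class equally makes this the criterion that exposes
#' majority-class-only behaviour: a constant predictor scores exactly
#' `100/k` regardless of the imbalance. Classes absent from `y_true` are
#' excluded from the mean with a warning.
#'
#' @param y_true,y_pred Integer class indices in `1..k`.
#' @param k Number of classes.
#' @return Percent in `[0, 100]`.
#' @export
macro_avg_accuracy <- function(y_true, y_pred, k) {
  check_labels(y_true, y_pred, k)
  recalls <- vapply(seq_len(k), function(c) {
    nc <- sum(y_true == c)
    if (nc == 0L) return(NA_real_)
    sum(y_true == c & y_pred == c) / nc
  }, numeric(1))
  if (anyNA(recalls))
    warning(sprintf("%d class(es) absent from y_true excluded from the macro mean",
                    sum(is.na(recalls))), call. = FALSE)
  100 * mean(recalls, na.rm = TRUE)
}

#' Micro-averaged accuracy (overall fraction correct)
#'
#' `100 * (number correct) / n`: every example weighs equally, so on
#' imbalanced data this criterion is dominated by the majority class.
#'
#' @inheritParams macro_avg_accuracy
#' @return Percent in `[0, 100]`.
#' @export
micro_avg_accuracy <- function(y_true, y_pred, k = max(y_true, y_pred)) {
  check_labels(y_true, y_pred, k)
  100 * mean(y_true == y_pred)
}

#' Macro-averaged F1 measure
#'
#' Per-class F1 = 2 * precision * recall / (precision + recall), with the
#' convention F1 = 0 when the denominator is 0 (a class never predicted
#' and/or never true); the macro F1 is the unweighted mean over all k
#' classes.
#'
#' @inheritParams macro_avg_accuracy
#' @return List with `macro_f1` (percent) and `per_class_f1` (k percents).
#' @export
macro_f1 <- function(y_true, y_pred, k) {
  check_labels(y_true, y_pred, k)
  f1 <- vapply(seq_len(k), function(c) {
    tp <- sum(y_true == c & y_pred == c)
    denom <- sum(y_true == c) + sum(y_pred == c)  # = 2tp + fp + fn
    if (denom == 0L) 0 else 2 * tp / denom
  }, numeric(1))
  list(macro_f1 = 100 * mean(f1), per_class_f1 = 100 * f1)
}

check_labels <- function(y_true, y_pred, k) {
  if (!length(y_true)) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  if (any(y_true < 1L | y_true > k) || any(y_pred < 1L | y_pred > k))
    stop("labels must be integers in 1..k", call. = FALSE)
  invisible(TRUE)
}

#' Full evaluation report for one set of predictions
#'
#' Bundles the three criteria (macro accuracy, micro accuracy, macro F1),
#' the per-class F1 vector, and the k x k confusion matrix.
#'
#' @inheritParams macro_avg_accuracy
#' @param class_names Optional class names for the confusion matrix.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(y_true, y_pred, k, class_names = NULL) {
  check_labels(y_true, y_pred, k)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(k))
  conf <- table(true = factor(y_true, levels = seq_len(k)),
                pred = factor(y_pred, levels = seq_len(k)))
  dimnames(conf) <- list(true = class_names, pred = class_names)
  f1 <- macro_f1(y_true, y_pred, k)
  structure(
    list(macro_avg_acc = suppressWarnings(macro_avg_accuracy(y_true, y_pred, k)),
         micro_avg_acc = micro_avg_accuracy(y_true, y_pred, k),
         macro_f1 = f1$macro_f1,
         per_class_f1 = stats::setNames(f1$per_class_f1, class_names),
         confusion = unclass(conf), n = length(y_true)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Macro avg accuracy: %6.2f%%\n", x$macro_avg_acc))
  cat(sprintf("Micro avg accuracy: %6.2f%%\n", x$micro_avg_acc))
  cat(sprintf("Macro F1:           %6.2f%%\n", x$macro_f1))
  cat("Per-class F1 (%):\n")
  print(round(x$per_class_f1, 2))
  cat("Confusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Stratified fold assignment for cross-validation
#'
#' Assigns each sample to one of `n_folds` folds so that within every
#' class the fold counts differ by at most 1. The assignment is a
#' deterministic function of `(y, n_folds, seed)`. A class with fewer
#' members than folds is allowed (some folds then lack the class) with a
#' warning.
#'
#' @param y Integer class labels.
#' @param n_folds Number of folds, at least 2.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(y, n_folds = 5L, seed = NULL) {
  n_folds <- stopifnot_scalar_count(n_folds, "n_folds")
  if (n_folds < 2L) stop("'n_folds' must be at least 2", call. = FALSE)
  assign_folds <- function() {
    folds <- integer(length(y))
    offset <- 0L
    for (c in sort(unique(y))) {
      idx <- which(y == c)
      if (length(idx) < n_folds)
        warning(sprintf(
          "class %s has %d member(s) for %d folds; some folds will lack it",
          c, length(idx), n_folds), call. = FALSE)
      idx <- idx[sample.int(length(idx))]
      # rotate the start fold per class so overall fold sizes stay balanced
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
    folds
  }
  if (is.null(seed)) assign_folds() else with_seed(seed, assign_folds())
}

#' Cross-validated comparison of classification algorithms
#'
#' Runs seeded stratified k-fold cross-validation for a named list of
#' algorithms on one dataset and reports the three criteria as
#' mean +/- standard deviation across folds — the comparison-grid layout
#' used to judge classifiers on syndrome-classification tasks. An
#' algorithm that fails on a fold yields missing cells (with a warning);
#' the run continues.
#'
#' @param dataset A [feature_dataset()].
#' @param algorithms Named list of algorithm constructors such as
#'   [alg_maplsc()]: each is `function(x_train, y_train, k)` returning a
#'   prediction `function(x_test)` that emits integer labels.
#' @param n_folds Folds (default 5).
#' @param seed Integer seed controlling fold assignment and any algorithm
#'   randomness.
#' @return An object of class `comparison_table`: matrices `mean` and
#'   `sd` (metrics x algorithms, percents), the per-fold values
#'   `fold_values`, and `pooled` out-of-fold predictions per algorithm.
#' @export
cross_validate_compare <- function(dataset, algorithms, n_folds = 5L,
                                   seed = 1L) {
  stopifnot(inherits(dataset, "feature_dataset"))
  if (!length(algorithms) || is.null(names(algorithms)))
    stop("'algorithms' must be a nonempty named list", call. = FALSE)
  k <- length(dataset$class_names)
  metrics <- c("macro_avg_acc", "micro_avg_acc", "macro_f1")
  n_alg <- length(algorithms)
  vals <- array(NA_real_, dim = c(length(metrics), n_alg, n_folds),
                dimnames = list(metrics, names(algorithms), NULL))
  pooled <- lapply(algorithms, function(.) list(y_true = integer(),
                                                y_pred = integer()))
  with_seed(seed, {
    folds <- stratified_folds(dataset$y, n_folds)
    for (fold in seq_len(n_folds)) {
      test <- folds == fold
      xtr <- dataset$x[!test, , drop = FALSE]; ytr <- dataset$y[!test]
      xte <- dataset$x[test, , drop = FALSE];  yte <- dataset$y[test]
      for (a in seq_len(n_alg)) {
        pred_fun <- tryCatch(algorithms[[a]](xtr, ytr, k), error = identity)
        yp <- if (inherits(pred_fun, "error")) pred_fun
              else tryCatch(pred_fun(xte), error = identity)
        if (inherits(yp, "error")) {
          warning(sprintf("algorithm '%s' failed on fold %d: %s",
                          names(algorithms)[a], fold,
                          conditionMessage(yp)), call. = FALSE)
          next
        }
        yp <- as.integer(yp)
        vals["macro_avg_acc", a, fold] <-
          suppressWarnings(macro_avg_accuracy(yte, yp, k))
        vals["micro_avg_acc", a, fold] <- micro_avg_accuracy(yte, yp, k)
        vals["macro_f1", a, fold] <- macro_f1(yte, yp, k)$macro_f1
        pooled[[a]]$y_true <- c(pooled[[a]]$y_true, yte)
        pooled[[a]]$y_pred <- c(pooled[[a]]$y_pred, yp)
      }
    }
  })
  structure(
    list(mean = apply(vals, c(1, 2), mean, na.rm = TRUE),
         sd = apply(vals, c(1, 2), stats::sd, na.rm = TRUE),
         fold_values = vals, pooled = pooled,
         n_folds = n_folds, seed = seed,
         class_names = dataset$class_names),
    class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, digits = 2, ...) {
  cat(sprintf("Stratified %d-fold cross-validation (seed %s); mean ± sd in %%\n",
              x$n_folds, format(x$seed)))
  cells <- matrix(fmt_pm(x$mean, x$sd, digits),
                  nrow = nrow(x$mean), dimnames = dimnames(x$mean))
  print(as.data.frame(cells), right = TRUE)
  invisible(x)
}

#' @export
as.data.frame.comparison_table <- function(x, ...) {
  cells <- matrix(fmt_pm(x$mean, x$sd), nrow = nrow(x$mean),
                  dimnames = dimnames(x$mean))
  data.frame(metric = rownames(cells), as.data.frame(cells),
             check.names = FALSE, row.names = NULL)
}

#' Algorithm constructors for the comparison harness
#'
#' Each constructor returns `function(x_train, y_train, k)` producing a
#' prediction `function(x_test)` with integer labels, the interface
#' [cross_validate_compare()] expects.
#'
#' * `alg_maplsc()`: the calibrated one-vs-one ensemble with pairwise
#'   coupling.
#' * `alg_aplsc_vote()`: the same one-vs-one asymmetric classifiers with a
#'   hard majority vote instead of coupling (ties to the smallest index).
#' * `alg_majority()`: the constant predictor at the most frequent
#'   training class — the imbalance floor every method must beat on macro
#'   criteria.
#' * `alg_random()`: uniform-random labels (uses the harness RNG stream).
#'
#' @param ncomp PLS components for the PLS-based algorithms.
#' @return An algorithm closure.
#' @export
alg_maplsc <- function(ncomp = 3L) {
  function(x_train, y_train, k) {
    fit <- maplsc.default(x_train, sprintf("c%06d", y_train), ncomp = ncomp)
    function(x_test)
      as.integer(sub("^c0*", "", as.character(predict(fit, x_test))))
  }
}

#' @rdname alg_maplsc
#' @export
alg_aplsc_vote <- function(ncomp = 3L) {
  function(x_train, y_train, k) {
    classes <- sort(unique(y_train))
    pairs <- list()
    for (a in seq_along(classes)[-length(classes)]) {
      for (b in seq.int(a + 1L, length(classes))) {
        i <- classes[a]; j <- classes[b]
        rows <- y_train %in% c(i, j)
        clf <- aplsc_fit(x_train[rows, , drop = FALSE],
                         ifelse(y_train[rows] == i, "pos", "neg"),
                         ncomp = ncomp, positive = "pos")
        pairs[[length(pairs) + 1L]] <- list(i = i, j = j, clf = clf)
      }
    }
    function(x_test) {
      votes <- matrix(0L, nrow(x_test), max(classes))
      for (pr in pairs) {
        f <- aplsc_score(pr$clf, x_test)
        win <- ifelse(f > 0, pr$i, pr$j)
        for (r in seq_along(win))
          votes[r, win[r]] <- votes[r, win[r]] + 1L
      }
      apply(votes, 1L, which.max)
    }
  }
}

#' @rdname alg_maplsc
#' @export
alg_majority <- function() {
  function(x_train, y_train, k) {
    tab <- tabulate(y_train, nbins = k)
    maj <- which.max(tab)
    function(x_test) rep(maj, nrow(x_test))
  }
}

#' @rdname alg_maplsc
#' @export
alg_random <- function() {
  function(x_train, y_train, k) {
    function(x_test) sample.int(k, nrow(x_test), replace = TRUE)
  }
}
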