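#' Multiclass asymmetric PLS classification (MAPLSC)
#'
#' Fits the MAPLSC model for imbalanced multiclass problems: one
#' asymmetric PLS binary classifier per unordered class pair (k(k-1)/2 in
#' all), each calibrated to a pairwise posterior by a sigmoid
#' `r = 1/(1 + exp(A*f + B))` fitted on that pair's training scores, and
#' combined at prediction time by the simplified pairwise-coupling rule
#' \deqn{\tilde p_i = \frac{2 \sum_{j \ne i} r_{ij}}{k (k - 1)},}
#' with the predicted class the argmax of the coupled probabilities.
#'
#' Within each pair the index-smaller class is the positive (+1) class, so
#' orientation is deterministic. Calibration is fit by resubstitution on
#' the pair's own training scores. A class with a single example is
#' handled by flooring its score dispersion in the boundary formula.
#'
#' @param x A numeric feature matrix, a [feature_dataset()], or a formula.
#' @param ... Passed on to methods.
#' @return An object of class `maplsc` with elements `k`, `class_names`,
#'   `ncomp`, `feature_names`, and `pairs` (one calibrated pairwise
#'   classifier per unordered class pair: the `aplsc` fit plus its sigmoid
#'   parameters `a`, `b`).
#' @seealso [predict.maplsc()], [pairwise_posteriors()], [couple()]
#' @examples
#' set.seed(1)
#' ds <- gen_cases(case_gen_spec(seed = 1))
#' fit <- maplsc(ds, ncomp = 3)
#' print(fit)
#' predict(fit, ds$x[1:3, ])
#' @export
maplsc <- function(x, ...) UseMethod("maplsc")

#' @rdname maplsc
#' @param y Class labels (factor, character, or integer indices).
#' @param ncomp Latent PLS components per pairwise classifier.
#' @export
maplsc.default <- function(x, y, ncomp = 3L, ...) {
  x <- as.matrix(x)
  if (is.numeric(y) && !is.factor(y)) y <- paste0("class", as.integer(y))
  y <- as.character(y)
  class_names <- unique(y)
  k <- length(class_names)
  if (k < 2L) stop("at least two classes are required", call. = FALSE)
  counts <- table(factor(y, levels = class_names))
  if (any(counts == 0L))
    stop(sprintf("class '%s' has no examples",
                 names(counts)[which(counts == 0L)[1L]]), call. = FALSE)
  yi <- match(y, class_names)

  pairs <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      rows <- yi == i | yi == j
      sub_y <- ifelse(yi[rows] == i, 1, -1)
      clf <- aplsc_fit(x[rows, , drop = FALSE],
                       ifelse(sub_y > 0, class_names[i], class_names[j]),
                       ncomp = ncomp, positive = class_names[i])
      f <- aplsc_score(clf, x[rows, , drop = FALSE])
      cal <- platt_fit(f, sub_y)
      pairs[[length(pairs) + 1L]] <-
        list(i = i, j = j, classifier = clf, a = cal$a, b = cal$b)
    }
  }
  structure(
    list(k = k, class_names = class_names, ncomp = ncomp,
         feature_names = colnames(x), n = nrow(x),
         class_counts = as.integer(counts), pairs = pairs,
         call = match.call()),
    class = "maplsc")
}

#' @rdname maplsc
#' @export
maplsc.feature_dataset <- function(x, ncomp = 3L, ...) {
  fit <- maplsc.default(x$x, x$class_names[x$y], ncomp = ncomp)
  fit$call <- match.call()
  fit
}

#' @rdname maplsc
#' @param data A data frame when `x` is a formula (`class ~ .` style).
#' @export
maplsc.formula <- function(x, data, ncomp = 3L, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  xm <- stats::model.matrix(attr(mf, "terms"), mf)
  xm <- xm[, colnames(xm) != "(Intercept)", drop = FALSE]
  fit <- maplsc.default(xm, y, ncomp = ncomp)
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit
}

#' @export
print.maplsc <- function(x, ...) {
  cat("Multiclass asymmetric PLS classifier (one-vs-one, coupled)\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  %d classes, %d calibrated pairwise classifier(s), %d PLS component(s)\n",
              x$k, length(x$pairs), x$ncomp))
  cat("  classes:",
      paste(sprintf("%s (n=%d)", x$class_names, x$class_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.maplsc <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$pairs, function(pr) {
    data.frame(
      pair = sprintf("%s vs %s", object$class_names[pr$i],
                     object$class_names[pr$j]),
      boundary = pr$classifier$boundary,
      A = pr$a, B = pr$b,
      mean_pos = unname(pr$classifier$score_means["positive"]),
      mean_neg = unname(pr$classifier$score_means["negative"]))
  }))
  structure(list(model = object, pairs = tab), class = "summary.maplsc")
}

#' @export
print.summary.maplsc <- function(x, ...) {
  print(x$model)
  cat("\nPairwise classifiers and sigmoid calibration:\n")
  print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.maplsc <- function(object, ...) {
  out <- lapply(object$pairs, function(pr) coef(pr$classifier$pls))
  names(out) <- vapply(object$pairs, function(pr)
    paste(object$class_names[pr$i], object$class_names[pr$j], sep = ":"),
    character(1))
  out
}

#' Pairwise posterior matrix for one sample
#'
#' Evaluates every calibrated pairwise classifier at `x` and returns the
#' k x k matrix with `r[i, j] = Prob(class i | x, class in {i, j})` for
#' `i < j` and the completion `r[j, i] = 1 - r[i, j]`. The diagonal is
#' `NA` (unused).
#'
#' @param object A fitted [maplsc()] model.
#' @param x A single length-p feature vector.
#' @return A k x k numeric matrix.
#' @export
pairwise_posteriors <- function(object, x) {
  stopifnot(inherits(object, "maplsc"))
  if (!is.null(dim(x))) {
    if (nrow(x) != 1L)
      stop("'x' must be a single sample; use predict() for batches",
           call. = FALSE)
    x <- drop(x)
  }
  r <- matrix(NA_real_, object$k, object$k,
              dimnames = list(object$class_names, object$class_names))
  for (pr in object$pairs) {
    f <- aplsc_score(pr$classifier, x)
    rij <- sigmoid_posterior(pr$a, pr$b, f)
    r[pr$i, pr$j] <- rij
    r[pr$j, pr$i] <- 1 - rij
  }
  r
}

#' Simplified pairwise coupling of posterior estimates
#'
#' Combines a matrix of pairwise posteriors `r[i, j]` (with
#' `r[i, j] + r[j, i] = 1`) into one k-class probability vector by the
#' closed-form rule `p_i = 2 * sum_{j != i} r[i, j] / (k * (k - 1))`. The
#' components always sum to 1 because every pair contributes exactly 1 to
#' the double sum.
#'
#' @param r k x k matrix of pairwise posteriors; the diagonal is ignored.
#' @return Numeric probability vector of length k summing to 1.
#' @export
couple <- function(r) {
  r <- as.matrix(r)
  k <- nrow(r)
  if (k < 2L || ncol(r) != k)
    stop("'r' must be a square matrix with k >= 2", call. = FALSE)
  off <- !diag(k)
  if (any(abs(r[off] + t(r)[off] - 1) > 1e-6))
    stop("'r' must satisfy r[i,j] + r[j,i] = 1 off the diagonal",
         call. = FALSE)
  diag(r) <- 0
  p <- 2 * rowSums(r) / (k * (k - 1))
  stats::setNames(p, rownames(r))
}

# Internal batch predictor: n x k coupled probability matrix.
maplsc_prob_matrix <- function(object, x) {
  x <- as.matrix(x)
  if (!is.null(object$feature_names) && !is.null(colnames(x)) &&
      all(object$feature_names %in% colnames(x)))
    x <- x[, object$feature_names, drop = FALSE]
  if (ncol(x) != length(object$pairs[[1L]]$classifier$pls$coefficients))
    stop("newdata has the wrong number of feature columns", call. = FALSE)
  n <- nrow(x); k <- object$k
  rsum <- matrix(0, n, k)
  for (pr in object$pairs) {
    f <- aplsc_score(pr$classifier, x)
    rij <- sigmoid_posterior(pr$a, pr$b, f)
    rsum[, pr$i] <- rsum[, pr$i] + rij
    rsum[, pr$j] <- rsum[, pr$j] + (1 - rij)
  }
  p <- 2 * rsum / (k * (k - 1))
  colnames(p) <- object$class_names
  p
}

#' Predict syndrome classes or coupled probabilities
#'
#' @param object A fitted [maplsc()] model.
#' @param newdata Feature matrix (n x p), a single length-p vector, a
#'   [feature_dataset()], or a data frame for formula fits.
#' @param type `"class"` for predicted labels (a factor with the model's
#'   class levels), `"prob"` for the n x k matrix of coupled
#'   probabilities.
#' @param ... Unused.
#' @details Ties at the argmax are broken toward the smallest class index,
#'   deterministically.
#' @export
predict.maplsc <- function(object, newdata,
                           type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_dataset")) newdata <- newdata$x
  if (is.data.frame(newdata) && !is.null(object$terms)) {
    mm <- stats::model.matrix(stats::delete.response(object$terms), newdata)
    newdata <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  p <- maplsc_prob_matrix(object, newdata)
  if (type == "prob") return(p)
  idx <- apply(p, 1L, which.max)  # first maximum: smallest-index tie-break
  factor(object$class_names[idx], levels = object$class_names)
}

#' Save and load a fitted MAPLSC model as JSON text
#'
#' A documented plain-text serialization of every pairwise classifier
#' (PLS coefficients, boundary, sigmoid parameters). `maplsc_load`
#' reconstructs a model whose predictions are identical to the original's.
#'
#' @param object A fitted [maplsc()] model.
#' @param path File path.
#' @return `maplsc_save` returns `path` invisibly; `maplsc_load` returns a
#'   `maplsc` object.
#' @export
maplsc_save <- function(object, path) {
  stopifnot(inherits(object, "maplsc"))
  ser <- list(
    format = "maplsc-model-1",
    k = object$k, class_names = object$class_names,
    ncomp = object$ncomp, n = object$n,
    class_counts = object$class_counts,
    feature_names = object$feature_names,
    pairs = lapply(object$pairs, function(pr) {
      clf <- pr$classifier
      list(i = pr$i, j = pr$j, a = pr$a, b = pr$b,
           positive = clf$positive, negative = clf$negative,
           boundary = clf$boundary,
           score_means = unname(clf$score_means),
           score_sds = unname(clf$score_sds),
           pls = list(ncomp = clf$pls$ncomp,
                      x_means = unname(clf$pls$x_means),
                      y_mean = clf$pls$y_mean,
                      coefficients = unname(clf$pls$coefficients)))
    }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname maplsc_save
#' @export
maplsc_load <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(ser$format, "maplsc-model-1"))
    stop("not a recognised maplsc model file", call. = FALSE)
  pairs <- lapply(ser$pairs, function(pr) {
    pls <- structure(
      list(ncomp = pr$pls$ncomp,
           x_means = as.numeric(pr$pls$x_means),
           y_mean = pr$pls$y_mean,
           coefficients = as.numeric(pr$pls$coefficients)),
      class = "pls_fit")
    clf <- structure(
      list(pls = pls, boundary = pr$boundary,
           positive = pr$positive, negative = pr$negative,
           score_means = stats::setNames(as.numeric(pr$score_means),
                                         c("positive", "negative")),
           score_sds = stats::setNames(as.numeric(pr$score_sds),
                                       c("positive", "negative"))),
      class = "aplsc")
    list(i = pr$i, j = pr$j, classifier = clf, a = pr$a, b = pr$b)
  })
  structure(
    list(k = ser$k, class_names = as.character(ser$class_names),
         ncomp = ser$ncomp,
         feature_names = if (length(ser$feature_names))
           as.character(ser$feature_names) else NULL,
         n = ser$n, class_counts = as.integer(ser$class_counts),
         pairs = pairs, call = NULL),
    class = "maplsc")
}
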