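#' Fit a single-response partial least squares regression by NIPALS
#'
#' Extracts up to `ncomp` orthogonal latent components from the centered
#' feature matrix by the NIPALS algorithm with single-response deflation,
#' and folds them into one vector of regression coefficients. Used with a
#' +1/-1 coded response this is the PLS classifier underlying the
#' asymmetric pairwise classifiers.
#'
#' @param x Numeric matrix, n x p.
#' @param y Numeric response of length n (class code +1/-1 for
#'   classification use).
#' @param ncomp Number of latent components to extract; clamped to
#'   `min(p, n - 1)` and to the numerical rank of the centered `x` (with a
#'   warning when the request exceeds it). At full rank the coefficients
#'   coincide with the least-squares solution.
#' @return An object of class `pls_fit`: `ncomp` (components actually
#'   extracted), `x_means`, `y_mean`, `weights` (p x A), `loadings`
#'   (p x A), `y_loadings` (A), and `coefficients` (p), so that the fitted
#'   value at `x0` is `y_mean + (x0 - x_means) %*% coefficients`.
#' @seealso [pls_predict()]
#' @export
pls_fit <- function(x, y, ncomp = 3L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (n < 2L) stop("at least 2 samples are required", call. = FALSE)
  ncomp <- stopifnot_scalar_count(ncomp, "ncomp")
  amax <- min(p, n - 1L)
  ncomp <- min(ncomp, amax)

  x_means <- colMeans(x)
  y_mean <- mean(y)
  e <- sweep(x, 2L, x_means)
  f <- y - y_mean
  xscale <- sqrt(sum(e^2))
  if (xscale == 0)
    stop("feature matrix has zero variance after centering", call. = FALSE)
  tol <- 1e-12 * xscale

  w_mat <- matrix(0, p, ncomp)
  p_mat <- matrix(0, p, ncomp)
  q_vec <- numeric(ncomp)
  scores <- matrix(0, n, ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(e, f)              # p x 1: covariance direction
    nw <- sqrt(sum(w^2))
    if (nw <= tol) break              # residual response uncorrelated with x
    w <- w / nw
    t_a <- drop(e %*% w)
    tt <- sum(t_a^2)
    if (tt <= tol^2) break
    p_a <- drop(crossprod(e, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    e <- e - tcrossprod(t_a, p_a)
    f <- f - t_a * q_a
    w_mat[, a] <- w; p_mat[, a] <- p_a; q_vec[a] <- q_a
    scores[, a] <- t_a
    a_used <- a
  }
  if (a_used == 0L)
    stop("response has no covariance with the features; no component extractable",
         call. = FALSE)
  if (a_used < ncomp) {
    warning(sprintf(
      "requested %d components but the data support only %d; clamped",
      ncomp, a_used), call. = FALSE)
    w_mat <- w_mat[, seq_len(a_used), drop = FALSE]
    p_mat <- p_mat[, seq_len(a_used), drop = FALSE]
    q_vec <- q_vec[seq_len(a_used)]
    scores <- scores[, seq_len(a_used), drop = FALSE]
  }
  # B = W (P'W)^{-1} q folds the sequence of deflations into one linear map
  coefs <- drop(w_mat %*% solve(crossprod(p_mat, w_mat), q_vec))
  structure(
    list(ncomp = a_used, x_means = x_means, y_mean = y_mean,
         weights = w_mat, loadings = p_mat, y_loadings = q_vec,
         coefficients = stats::setNames(coefs, colnames(x)),
         scores = scores),
    class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d latent component(s), p=%d\n",
              x$ncomp, length(x$coefficients)))
  invisible(x)
}

#' @export
coef.pls_fit <- function(object, ...) object$coefficients

#' Continuous prediction from a fitted PLS model
#'
#' Evaluates the affine map `g(x) = y_mean + (x - x_means) . coefficients`.
#' At the training feature means the prediction equals the response mean.
#'
#' @param model A [pls_fit()] object.
#' @param x A length-p vector or an n x p matrix.
#' @return A numeric scalar (vector input) or vector (matrix input).
#' @export
pls_predict <- function(model, x) {
  stopifnot(inherits(model, "pls_fit"))
  p <- length(model$coefficients)
  if (is.null(dim(x))) {
    if (length(x) != p)
      stop(sprintf("input has length %d but the model expects %d features",
                   length(x), p), call. = FALSE)
    x <- matrix(as.numeric(x), 1L, p)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != p)
      stop(sprintf("input has %d columns but the model expects %d features",
                   ncol(x), p), call. = FALSE)
  }
  drop(model$y_mean + sweep(x, 2L, model$x_means) %*% model$coefficients)
}
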