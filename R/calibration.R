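#' Sigmoid posterior probability
#'
#' Evaluates `r = 1 / (1 + exp(A*f + B))`, the sigmoid map from a
#' classifier's continuous output `f` to a posterior probability. The
#' exponent is clamped to avoid overflow and the result is bounded strictly
#' inside (0, 1). `r` is monotone in `f` with direction opposite to the
#' sign of `A` (fitted `A` is negative when larger scores indicate the
#' positive class).
#'
#' @param a,b Sigmoid parameters.
#' @param f Classifier score(s).
#' @return Posterior probability in (0, 1), vectorised over `f`.
#' @seealso [platt_fit()]
#' @export
sigmoid_posterior <- function(a, b, f) {
  stopifnot(is.finite(a), is.finite(b))
  z <- pmin(pmax(a * f + b, -500), 500)
  r <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
  eps <- .Machine$double.eps
  pmin(pmax(r, eps), 1 - eps)
}

#' Fit sigmoid calibration parameters by penalised maximum likelihood
#'
#' Platt's procedure: fit `(A, B)` of `r(f) = 1/(1 + exp(A*f + B))` by
#' maximising the likelihood of the smoothed targets
#' `t+ = (N+ + 1)/(N+ + 2)` and `t- = 1/(N- + 2)` (which keep the fit away
#' from degenerate 0/1 probabilities on separable data), using Newton
#' iterations with backtracking line search, initialised at `A = 0`,
#' `B = ln((N- + 1)/(N+ + 1))`.
#'
#' @param scores Numeric vector of classifier outputs `f`.
#' @param labels Vector of class codes, +1 for the positive class and -1
#'   for the negative class.
#' @param max_iter Maximum Newton iterations.
#' @return List with elements `a`, `b`, `converged`, `iterations`.
#' @export
platt_fit <- function(scores, labels, max_iter = 100L) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  if (length(scores) != length(labels) || !length(scores))
    stop("'scores' and 'labels' must be nonempty and of equal length",
         call. = FALSE)
  if (!all(labels %in% c(-1, 1)))
    stop("'labels' must be coded +1 / -1", call. = FALSE)
  n_pos <- sum(labels > 0); n_neg <- sum(labels < 0)
  if (n_pos == 0L || n_neg == 0L) {
    warning("only one class present; returning the smoothed base-rate sigmoid",
            call. = FALSE)
    return(list(a = 0,
                b = log((n_neg + 1) / (n_pos + 1)),
                converged = TRUE, iterations = 0L))
  }
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(labels > 0, hi, lo)

  # penalised negative log-likelihood, computed in overflow-safe form
  nll <- function(a, b) {
    z <- a * scores + b
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }

  sigma <- 1e-12   # Hessian ridge
  a <- 0
  b <- log((n_neg + 1) / (n_pos + 1))
  fval <- nll(a, b)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    z <- a * scores + b
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    d1 <- t - p                          # dF/dz per point
    d2 <- p * (1 - p)
    g_a <- sum(scores * d1); g_b <- sum(d1)
    if (abs(g_a) < 1e-5 && abs(g_b) < 1e-5) { converged <- TRUE; break }
    h11 <- sum(scores^2 * d2) + sigma
    h22 <- sum(d2) + sigma
    h12 <- sum(scores * d2)
    det <- h11 * h22 - h12^2
    da <- -(h22 * g_a - h12 * g_b) / det
    db <- -(h11 * g_b - h12 * g_a) / det
    gd <- g_a * da + g_b * db            # directional derivative (< 0)
    step <- 1
    repeat {
      a_new <- a + step * da; b_new <- b + step * db
      f_new <- nll(a_new, b_new)
      if (f_new <= fval + 1e-4 * step * gd) {
        a <- a_new; b <- b_new; fval <- f_new
        break
      }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break              # line search failed; keep best iterate
  }
  if (!converged)
    warning("sigmoid calibration did not fully converge; returning best iterate",
            call. = FALSE)
  list(a = a, b = b, converged = converged, iterations = it)
}
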