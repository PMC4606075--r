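#' Fit an asymmetric PLS binary classifier
#'
#' A PLS classifier whose decision boundary is shifted to counter class
#' imbalance: with per-class means and standard deviations (m+, s+) and
#' (m-, s-) of the continuous PLS output g on the training data, the
#' boundary is the dispersion-weighted point
#' \deqn{b = (s^- m^+ + s^+ m^-) / (s^+ + s^-),}
#' which sits farther from the class with the larger score spread. The
#' classifier output is `f(x) = g(x) - b`, oriented so `f > 0` favors the
#' positive class whenever the positive class has the larger mean score.
#'
#' By convention the index-smaller (first-named) class of the pair is coded
#' +1, giving a deterministic orientation.
#'
#' @param x Numeric matrix, n x p.
#' @param y Labels with exactly two distinct values (character, factor or
#'   integer).
#' @param ncomp Latent components for the underlying PLS fit.
#' @param positive Which label is the positive (+1) class; default the
#'   first distinct value of `y` in first-appearance order.
#' @return An object of class `aplsc`: the `pls` fit, `boundary`,
#'   `positive`/`negative` labels, and per-class score summaries
#'   `score_means`, `score_sds`.
#' @seealso [aplsc_score()]
#' @export
aplsc_fit <- function(x, y, ncomp = 3L, positive = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2L)
    stop(sprintf("exactly two classes are required, got %d",
                 length(classes)), call. = FALSE)
  if (is.null(positive)) positive <- classes[1L]
  positive <- as.character(positive)
  if (!(positive %in% classes))
    stop(sprintf("positive class '%s' not present in 'y'", positive),
         call. = FALSE)
  negative <- setdiff(classes, positive)
  code <- ifelse(y == positive, 1, -1)
  pls <- pls_fit(x, code, ncomp = ncomp)
  g <- pls_predict(pls, x)

  sd_floor <- 1e-9  # single-member class: fall back toward the midpoint
  m_pos <- mean(g[code == 1]);  m_neg <- mean(g[code == -1])
  s_pos <- stats::sd(g[code == 1]);  s_neg <- stats::sd(g[code == -1])
  if (is.na(s_pos) || s_pos < sd_floor) s_pos <- sd_floor
  if (is.na(s_neg) || s_neg < sd_floor) s_neg <- sd_floor
  if (isTRUE(all.equal(m_pos, m_neg)))
    warning("class score means coincide; separation is degenerate",
            call. = FALSE)
  b <- (s_neg * m_pos + s_pos * m_neg) / (s_pos + s_neg)
  structure(
    list(pls = pls, boundary = b,
         positive = positive, negative = negative,
         score_means = c(positive = m_pos, negative = m_neg),
         score_sds = c(positive = s_pos, negative = s_neg)),
    class = "aplsc")
}

#' @export
print.aplsc <- function(x, ...) {
  cat(sprintf("<aplsc> %s (+) vs %s (-), boundary %.4g, %d component(s)\n",
              x$positive, x$negative, x$boundary, x$pls$ncomp))
  invisible(x)
}

#' Continuous score of an asymmetric PLS classifier
#'
#' `f(x) = g(x) - b`; the sign of `f` is the hard binary decision, positive
#' favoring the positive class. A point exactly on the boundary scores 0.
#'
#' @param model An [aplsc_fit()] object.
#' @param x A length-p vector or an n x p matrix.
#' @return Numeric score(s).
#' @export
aplsc_score <- function(model, x) {
  stopifnot(inherits(model, "aplsc"))
  pls_predict(model$pls, x) - model$boundary
}

#' @export
predict.aplsc <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  f <- aplsc_score(object, newdata)
  if (type == "score") return(f)
  ifelse(f > 0, object$positive, object$negative)
}
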