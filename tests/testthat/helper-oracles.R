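# Independent oracles used across the suite.

# Brute-force frequent-itemset enumeration over a vocabulary of <= 12
# items, via bitmask subset counting. Returns a named integer vector:
# "item1,item2" (sorted items) -> support, for all itemsets with
# support >= min_support.
brute_force_frequent <- function(transactions, min_support) {
  vocab <- sort(unique(unlist(transactions)))
  v <- length(vocab)
  stopifnot(v <= 12L)
  tmask <- vapply(transactions, function(tr)
    sum(bitwShiftL(1L, match(tr, vocab) - 1L)), integer(1))
  out <- stats::setNames(integer(0), character(0))
  for (mask in seq_len(bitwShiftL(1L, v) - 1L)) {
    sup <- sum(bitwAnd(tmask, mask) == mask)
    if (sup >= min_support) {
      items <- vocab[bitwAnd(bitwShiftL(1L, seq_len(v) - 1L), mask) != 0L]
      out[paste(items, collapse = ",")] <- sup
    }
  }
  out
}

# apriori() result as the same named support vector for comparison.
apriori_as_map <- function(freq) {
  stats::setNames(freq$support,
                  vapply(freq$items, function(s)
                    paste(sort(s), collapse = ","), character(1)))
}

# Random transaction set for property tests (vocabulary <= 12, n <= 50).
random_transactions <- function(n, v, max_items = 6L) {
  vocab <- letters[seq_len(v)]
  transaction_set(lapply(seq_len(n), function(i)
    sample(vocab, sample.int(min(max_items, v), 1L))))
}

# Ordinary least squares on centered data: the full-rank PLS oracle.
ls_coefficients <- function(x, y) {
  xc <- sweep(x, 2L, colMeans(x))
  yc <- y - mean(y)
  drop(solve(crossprod(xc), crossprod(xc, yc)))
}

# Generic maximum-likelihood sigmoid fit by Nelder-Mead over (A, B),
# independent of the Newton implementation under test.
sigmoid_ml_oracle <- function(scores, labels) {
  n_pos <- sum(labels > 0); n_neg <- sum(labels < 0)
  t <- ifelse(labels > 0, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(par) {
    z <- par[1] * scores + par[2]
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  fit <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  list(a = fit$par[1], b = fit$par[2], value = fit$value, nll = nll)
}

# Imbalanced two-class Gaussian fixture.
make_two_class <- function(seed = 1, n1 = 30, n2 = 10, shift = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * 3), n1, 3),
             matrix(rnorm(n2 * 3, mean = shift), n2, 3))
  list(x = x, y = c(rep("A", n1), rep("B", n2)))
}

# Imbalanced three-class Gaussian fixture with well-separated centers.
make_gaussian3 <- function(seed = 1, n = c(40, 15, 10), shift = 4) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(shift, 0), c(0, shift))
  x <- do.call(rbind, lapply(1:3, function(c)
    matrix(rnorm(n[c] * 2, mean = rep(centers[c, ], each = n[c])), n[c], 2)))
  list(x = x, y = rep(c("s1", "s2", "s3"), n))
}

# Small 3-class case-record fixture for retrieval tests.
make_case_records <- function() {
  list(
    case_record("c1", "zhang", "fl",
                symptoms = list(Nausea = 1, Thirsty = 0, Tongue = "red"),
                syndrome = "B", prescription = c("salvia", "hawthorn")),
    case_record("c2", "zhang", "fl",
                symptoms = list(Nausea = 0, Thirsty = 1, Tongue = "pale"),
                syndrome = "A"),
    case_record("c3", "zhang", "fl",
                symptoms = list(Nausea = 1, Thirsty = 1, Tongue = "red"),
                syndrome = "B", visit_index = 2),
    case_record("c4", "li", "fl",
                symptoms = list(Nausea = 1, Thirsty = 0, Tongue = "red"),
                syndrome = "A"))
}
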